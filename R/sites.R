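#' Parameter bundle for site processing
#'
#' Collects every numeric threshold of the pipeline in one place. Defaults
#' follow the values used throughout the analyses: sites are kept at
#' LFC >= 1; the stricter context-set filter uses maximum length 80, minimum
#' LFC 3 and maximum p-value 0.01; a site counts as exonic at >= 90% exon
#' overlap; "near border" means <= 50 nt from an exon border; pair sites
#' require < 10 nt from both inner ends to the adjacent exon borders; nearby
#' sites closer than 10 nt are merged; context extension is 80 nt up- and
#' downstream of the site center (161 nt total).
#'
#' @param min_lfc Minimum log2 fold change (inclusive); `-Inf` disables.
#' @param max_len Maximum site length in nt (inclusive); `Inf` disables.
#' @param max_pvalue Maximum p-value (inclusive); `NA` disables.
#' @param exon_overlap_frac Fraction of site bases that must be exonic.
#' @param border_dist Near-border distance threshold in nt (inclusive).
#' @param pair_dist Pair-site border distance in nt (strict `<`).
#' @param merge_dist Merge sites whose gap is `< merge_dist` nt.
#' @param ext Context extension in nt on each side of the center.
#' @return A list of class `txclip_thresholds`.
#' @export
thresholds <- function(min_lfc = 1, max_len = Inf, max_pvalue = NA,
                       exon_overlap_frac = 0.9, border_dist = 50L,
                       pair_dist = 10L, merge_dist = 10L, ext = 80L) {
  stopifnot(exon_overlap_frac > 0, exon_overlap_frac <= 1,
            border_dist >= 0, pair_dist >= 0, merge_dist >= 0, ext >= 0)
  structure(list(min_lfc = min_lfc, max_len = max_len,
                 max_pvalue = max_pvalue,
                 exon_overlap_frac = exon_overlap_frac,
                 border_dist = as.integer(border_dist),
                 pair_dist = as.integer(pair_dist),
                 merge_dist = as.integer(merge_dist), ext = as.integer(ext)),
            class = "txclip_thresholds")
}

#' Read binding sites from a BED file
#'
#' Expects BED6 or BED6+ (tab-separated, 0-based half-open); the score column
#' carries the log2 fold change and an optional extra column carries a
#' p-value. Coordinates are converted to the 1-based closed GenomicRanges
#' convention. Missing or empty names are replaced by unique ids.
#'
#' @param path BED file path.
#' @param score_col,pvalue_col 1-based column indices of the LFC score and
#'   the optional p-value (`NA` = no p-value column; default 7 when present).
#' @return A [GenomicRanges::GRanges] with metadata columns `id`, `score`
#'   and (when present) `pvalue`.
#' @export
read_bed <- function(path, score_col = 5L, pvalue_col = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(id = character(), score = numeric()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 6L)) {
    stop("BED line ", which(ncol < 6L)[1L], " in ", path,
         " has fewer than 6 columns")
  }
  get_col <- function(j) vapply(f, `[[`, "", j)
  start0 <- suppressWarnings(as.integer(get_col(2L)))
  end0 <- suppressWarnings(as.integer(get_col(3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0L | start0 >= end0)
  if (length(bad)) {
    stop("invalid coordinates on BED line ", bad[1L], " in ", path)
  }
  if (is.null(pvalue_col) && min(ncol) >= 7L) pvalue_col <- 7L
  ids <- get_col(4L)
  blank <- !nzchar(ids) | ids == "."
  ids[blank] <- paste0("site", which(blank))
  gr <- GenomicRanges::GRanges(
    get_col(1L), IRanges::IRanges(start0 + 1L, end0), strand = get_col(6L),
    id = ids, score = suppressWarnings(as.numeric(get_col(score_col))))
  if (!is.null(pvalue_col) && !is.na(pvalue_col)) {
    if (any(ncol < pvalue_col)) {
      stop("p-value column ", pvalue_col, " absent on BED line ",
           which(ncol < pvalue_col)[1L], " in ", path)
    }
    gr$pvalue <- suppressWarnings(as.numeric(get_col(pvalue_col)))
  }
  names(gr) <- gr$id
  gr
}

#' Write sites to a BED file
#'
#' BED6, plus a 7th p-value column when `sites$pvalue` exists; 1-based closed
#' internal coordinates are converted back to BED's 0-based half-open.
#'
#' @param sites A [GenomicRanges::GRanges] with `id` and `score` columns.
#' @param path Output path.
#' @export
write_bed <- function(sites, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites) - 1L,
    end = GenomicRanges::end(sites),
    name = if (!is.null(sites$id)) sites$id else paste0("site", seq_along(sites)),
    score = if (!is.null(sites$score)) sites$score else 0,
    strand = as.character(GenomicRanges::strand(sites)),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  if (!is.null(sites$pvalue)) df$pvalue <- sites$pvalue
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter sites by length, score and p-value
#'
#' Keeps sites with length <= `max_len`, LFC >= `min_lfc` and (when a
#' p-value column exists and `max_pvalue` is set) p-value <= `max_pvalue`.
#' All bounds are inclusive; each criterion can be disabled individually
#' (`max_len = Inf`, `min_lfc = -Inf`, `max_pvalue = NA`).
#'
#' @param sites A [GenomicRanges::GRanges] as from [read_bed()].
#' @param thr A [thresholds()] object.
#' @return The filtered GRanges.
#' @export
filter_sites <- function(sites, thr = thresholds()) {
  keep <- GenomicRanges::width(sites) <= thr$max_len &
    sites$score >= thr$min_lfc
  if (!is.null(sites$pvalue) && !is.na(thr$max_pvalue)) {
    keep <- keep & sites$pvalue <= thr$max_pvalue
  }
  sites[keep]
}

# Pick one winner per connected component of sites: highest score, ties
# broken by longer site, then lower start, then id.
component_winners <- function(sites, min_gapwidth) {
  if (length(sites) == 0L) return(sites)
  # process strands separately so "*" never bridges +/- components
  strands <- as.character(GenomicRanges::strand(sites))
  parts <- lapply(unique(strands), function(st) {
    ss <- sites[strands == st]
    comp <- GenomicRanges::reduce(ss, min.gapwidth = min_gapwidth)
    # every site is contained in exactly one reduced component
    h <- GenomicRanges::findOverlaps(ss, comp, type = "within")
    grp <- rep(NA_integer_, length(ss))
    grp[S4Vectors::queryHits(h)] <- S4Vectors::subjectHits(h)
    o <- order(grp, -ss$score, -GenomicRanges::width(ss),
               GenomicRanges::start(ss), ss$id, method = "radix")
    ss[o[!duplicated(grp[o])]]
  })
  sort(do.call(c, parts))
}

#' Merge replicate site sets, keeping the highest-LFC site per overlap
#'
#' All sites from both replicates that overlap (>= 1 nt, same strand),
#' directly or transitively, form a component; only the single site with the
#' maximal log2 fold change survives, with its original coordinates.
#' Non-overlapping sites pass through unchanged.
#'
#' @param a,b [GenomicRanges::GRanges] site sets (replicates).
#' @return The merged GRanges, sorted.
#' @export
merge_replicates <- function(a, b) {
  component_winners(suppressWarnings(c(a, b)), min_gapwidth = 0L)
}

#' Merge nearby sites, keeping the highest-LFC site per cluster
#'
#' Sites that overlap or whose end-to-start gap is smaller than `merge_dist`
#' nt form a cluster; the highest-LFC site per cluster survives with its
#' original coordinates (ties: longer site, then lower start).
#'
#' @param sites A [GenomicRanges::GRanges] site set.
#' @param merge_dist Merge sites with gap `< merge_dist` nt.
#' @return The merged GRanges, sorted.
#' @export
merge_nearby <- function(sites, merge_dist = 10L) {
  component_winners(sites, min_gapwidth = as.integer(merge_dist))
}

#' Classify sites as exonic by overlap fraction
#'
#' The overlap fraction of a site is (exonic bases of the site) / (site
#' length), computed against the merged exon union (strand-matched; strand
#' `"*"` sites match both strands). A site is exonic iff its fraction is
#' >= `frac` — the same fraction-of-query semantics as `intersectBed -f`.
#'
#' @param sites A [GenomicRanges::GRanges] site set.
#' @param exons Exon union [GenomicRanges::GRanges] (see [exon_union()]).
#' @param frac Required fraction, default 0.90.
#' @return A data.frame with `id`, `overlap_fraction`, `exonic`.
#' @export
classify_exonic <- function(sites, exons, frac = 0.9) {
  n <- length(sites)
  ovfrac <- numeric(n)
  if (n > 0L && length(exons) > 0L) {
    exons <- GenomicRanges::reduce(exons)
    h <- GenomicRanges::findOverlaps(sites, exons)
    if (length(h) > 0L) {
      w <- IRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(sites)[S4Vectors::queryHits(h)],
        GenomicRanges::ranges(exons)[S4Vectors::subjectHits(h)]))
      tot <- tapply(w, S4Vectors::queryHits(h), sum)
      ovfrac[as.integer(names(tot))] <- as.numeric(tot)
    }
  }
  ovfrac <- ovfrac / GenomicRanges::width(sites)
  data.frame(id = if (!is.null(sites$id)) sites$id else as.character(seq_len(n)),
             overlap_fraction = as.numeric(ovfrac),
             exonic = as.numeric(ovfrac) >= frac,
             stringsAsFactors = FALSE)
}

# Index (genomic order) of the exon containing genomic position pos, NA if
# intronic/outside.
containing_exon <- function(pos, model) {
  k <- which(pos >= IRanges::start(model$exons) &
               pos <= IRanges::end(model$exons))
  if (length(k) == 0L) NA_integer_ else k[1L]
}

#' Distances of site ends to the borders of their containing exon
#'
#' For each end of an exonic site, the distance in nt to the matching border
#' of the exon containing it (0 = flush with the border), oriented along the
#' transcript: `dist5` is the distance from the site's 5' end to its exon's
#' 5' border, `dist3` from the 3' end to its exon's 3' border. A site is
#' "near-border" at threshold d iff `min(dist5, dist3) <= d`.
#'
#' With `clip = TRUE`, site ends falling outside the exon union (possible for
#' sites classified exonic at fractional overlap) are clipped to the
#' containing exon before measuring; with `clip = FALSE` such ends raise an
#' error, as callers are expected to pre-classify.
#'
#' @param site A length-1 [GenomicRanges::GRanges].
#' @param model The assigned [transcript_model()].
#' @param clip Clip intron-overhanging ends to the exon (default FALSE).
#' @return A list: `dist5`, `dist3`, `exon5`, `exon3` (1-based 5'->3' exon
#'   indices of the exons containing each end).
#' @export
border_distance <- function(site, model, clip = FALSE) {
  stopifnot(length(site) == 1L)
  s <- GenomicRanges::start(site); e <- GenomicRanges::end(site)
  if (clip) {
    ex <- IRanges::intersect(IRanges::IRanges(s, e), model$exons)
    if (length(ex) == 0L) stop("site has no exonic overlap with ",
                               model$transcript_id)
    s <- min(IRanges::start(ex)); e <- max(IRanges::end(ex))
  }
  ks <- containing_exon(s, model)
  ke <- containing_exon(e, model)
  if (is.na(ks) || is.na(ke)) {
    stop("site end in an intron of ", model$transcript_id,
         "; pre-classify or use clip = TRUE")
  }
  nex <- length(model$exons)
  dl <- s - IRanges::start(model$exons)[ks]   # left end to left border
  dr <- IRanges::end(model$exons)[ke] - e     # right end to right border
  if (model$strand == "+") {
    list(dist5 = dl, dist3 = dr, exon5 = ks, exon3 = ke)
  } else {
    list(dist5 = dr, dist3 = dl, exon5 = nex - ke + 1L, exon3 = nex - ks + 1L)
  }
}

#' Detect pair sites at adjacent exon borders
#'
#' Two exonic sites form a pair when one site's 3' end lies strictly within
#' `pair_dist` nt of the 3' border of exon i and the other site's 5' end lies
#' strictly within `pair_dist` nt of the 5' border of exon i+1 of the same
#' transcript model — the signature of a single binding site split across a
#' splice junction in genomic coordinates. Each site joins at most one pair;
#' candidate pairs are accepted greedily by exon adjacency, then by summed
#' LFC.
#'
#' @param sites Exonic [GenomicRanges::GRanges] sites.
#' @param assigned Character vector of transcript ids parallel to `sites`
#'   (see [assign_sites()]).
#' @param models Named list of [transcript_model()] (names = transcript ids
#'   or any list searchable by transcript id).
#' @param pair_dist Strict upper bound on border distances (default 10).
#' @return A data.frame with columns `id1`, `id2`, `transcript_id`, `intron`
#'   (5'->3' index of the junction), `dist1`, `dist3`... one row per pair.
#' @export
detect_pairs <- function(sites, assigned, models, pair_dist = 10L) {
  by_tid <- stats::setNames(models,
                            vapply(models, `[[`, "", "transcript_id"))
  empty <- data.frame(id1 = character(), id2 = character(),
                      transcript_id = character(), intron = integer(),
                      dist1 = integer(), dist2 = integer(),
                      stringsAsFactors = FALSE)
  if (length(sites) == 0L) return(empty)
  donors <- list(); acceptors <- list()
  for (i in seq_along(sites)) {
    tid <- assigned[i]
    if (is.na(tid) || is.null(by_tid[[tid]])) next
    m <- by_tid[[tid]]
    bd <- tryCatch(border_distance(sites[i], m, clip = TRUE),
                   error = function(e) NULL)
    if (is.null(bd)) next
    nex <- length(m$exons)
    # 3' site end near the 3' border of exon i (i < n): upstream pair member
    if (bd$exon3 < nex && bd$dist3 < pair_dist) {
      donors[[length(donors) + 1L]] <- list(
        i = i, tid = tid, intron = bd$exon3, d = bd$dist3,
        lfc = sites$score[i])
    }
    # 5' site end near the 5' border of exon i (i > 1): downstream member
    if (bd$exon5 > 1L && bd$dist5 < pair_dist) {
      acceptors[[length(acceptors) + 1L]] <- list(
        i = i, tid = tid, intron = bd$exon5 - 1L, d = bd$dist5,
        lfc = sites$score[i])
    }
  }
  if (length(donors) == 0L || length(acceptors) == 0L) return(empty)
  cand <- list()
  for (d in donors) for (a in acceptors) {
    if (d$tid == a$tid && d$intron == a$intron && d$i != a$i) {
      cand[[length(cand) + 1L]] <- data.frame(
        i1 = d$i, i2 = a$i, tid = d$tid, intron = d$intron,
        d1 = d$d, d2 = a$d, lfc = d$lfc + a$lfc, stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$tid, cand$intron, -cand$lfc), ]
  used <- logical(length(sites))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used[cand$i1[r]] && !used[cand$i2[r]]) {
      keep[r] <- TRUE
      used[cand$i1[r]] <- TRUE
      used[cand$i2[r]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(id1 = sites$id[cand$i1], id2 = sites$id[cand$i2],
             transcript_id = cand$tid, intron = cand$intron,
             dist1 = cand$d1, dist2 = cand$d2, stringsAsFactors = FALSE)
}
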