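IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  # motif N matches any base including a masked (N) sequence position;
  # every other code matches only unmasked bases
  N = c("A", "C", "G", "T", "N"))

#' Parse a motif definition string
#'
#' The grammar covers plain IUPAC motifs and compound motifs of several
#' sequence blocks separated by bounded-length unspecified spacers:
#'
#' * IUPAC letters (RNA `U` accepted, normalised to `T`), e.g. `"UGUANAUA"`
#'   — the PUM2 Pumilio Response Element;
#' * bounded gaps `N{a-b}` (or fixed `N{a}`) between blocks;
#' * repeat shorthand `[XY]k` = `XY` repeated k times;
#' * optional `-` separators between tokens.
#'
#' Example: the IGF2BP3 compound motif
#' `"GGC-N{15-25}-CA-N{7-20}-CA-N{15-25}-GGC-N{2-8}-[CA]4"`.
#'
#' @param spec Motif string.
#' @param motif_id Identifier (defaults to the spec string).
#' @return A list of class `rbp_motif` with `motif_id`, `spec`, `blocks`
#'   (DNA IUPAC strings), and `gap_min`/`gap_max` (the gap *preceding* each
#'   block; 0,0 for the first).
#' @export
parse_motif <- function(spec, motif_id = spec) {
  s <- toupper(gsub("\\s", "", spec))
  pos <- 1L
  blocks <- character(); gmin <- integer(); gmax <- integer()
  pending_min <- 0L; pending_max <- 0L; have_gap <- FALSE
  err <- function(msg) stop("motif parse error at position ", pos, " in '",
                            spec, "': ", msg)
  while (pos <= nchar(s)) {
    rest <- substr(s, pos, nchar(s))
    if (substr(rest, 1, 1) == "-") { pos <- pos + 1L; next }
    m <- regmatches(rest, regexec("^N\\{(\\d+)(?:[-,](\\d+))?\\}", rest))[[1]]
    if (length(m)) {
      a <- as.integer(m[2])
      b <- if (nzchar(m[3])) as.integer(m[3]) else a
      if (a > b) err(paste0("gap bounds ", a, " > ", b))
      if (have_gap) err("two consecutive gaps")
      if (length(blocks) == 0L) err("motif cannot start with a gap")
      pending_min <- a; pending_max <- b; have_gap <- TRUE
      pos <- pos + nchar(m[1]); next
    }
    m <- regmatches(rest, regexec("^\\[([A-Z]+)\\](\\d+)", rest))[[1]]
    if (length(m)) {
      unit <- chartr("U", "T", m[2])
      if (!all(strsplit(unit, "")[[1]] %in% names(IUPAC_SETS))) {
        err(paste0("unknown letter in repeat unit '", m[2], "'"))
      }
      blk <- strrep(unit, as.integer(m[3]))
      if (!nzchar(blk)) err("zero-length repeat")
      blocks <- c(blocks, blk)
      gmin <- c(gmin, pending_min); gmax <- c(gmax, pending_max)
      pending_min <- pending_max <- 0L; have_gap <- FALSE
      pos <- pos + nchar(m[1]); next
    }
    m <- regmatches(rest, regexec("^([A-Z]+?)(?=\\{|$|-|\\[)", rest,
                                  perl = TRUE))[[1]]
    if (length(m) && nzchar(m[2])) {
      blk <- m[2]
      # a trailing N followed by '{' belongs to a gap token
      while (substr(s, pos + nchar(blk), pos + nchar(blk)) == "{" &&
             substr(blk, nchar(blk), nchar(blk)) == "N") {
        blk <- substr(blk, 1, nchar(blk) - 1L)
      }
      if (!nzchar(blk)) err("zero-length block")
      blk <- chartr("U", "T", blk)
      if (!all(strsplit(blk, "")[[1]] %in% names(IUPAC_SETS))) {
        err(paste0("unknown letter in block '", m[2], "'"))
      }
      blocks <- c(blocks, blk)
      gmin <- c(gmin, pending_min); gmax <- c(gmax, pending_max)
      pending_min <- pending_max <- 0L; have_gap <- FALSE
      pos <- pos + nchar(blk); next
    }
    err("unrecognised token")
  }
  if (length(blocks) == 0L) stop("motif '", spec, "' has no blocks")
  if (have_gap) stop("motif '", spec, "' ends with a gap")
  structure(list(motif_id = motif_id, spec = spec, blocks = blocks,
                 gap_min = gmin, gap_max = gmax),
            class = "rbp_motif")
}

#' @export
print.rbp_motif <- function(x, ...) {
  cat("rbp_motif", x$motif_id, "\n")
  for (i in seq_along(x$blocks)) {
    if (i > 1L) cat(sprintf("  gap %d-%d\n", x$gap_min[i], x$gap_max[i]))
    cat(" ", x$blocks[i], "\n")
  }
  invisible(x)
}

#' Bundled reference motifs
#'
#' The PUM2 Pumilio Response Element (PRE, `UGUANAUA`) and the IGF2BP3
#' compound motif (`GGC-N{15-25}-CA-N{7-20}-CA-N{15-25}-GGC-N{2-8}-[CA]4`),
#' the two motifs used for split-motif genome mapping.
#'
#' @return A named list of [parse_motif()] objects.
#' @export
known_motifs <- function() {
  list(
    PUM2_PRE = parse_motif("UGUANAUA", motif_id = "PUM2_PRE"),
    IGF2BP3 = parse_motif("GGC-N{15-25}-CA-N{7-20}-CA-N{15-25}-GGC-N{2-8}-[CA]4",
                          motif_id = "IGF2BP3"))
}

# Logical vector: does `block` (IUPAC) match `chars` starting at each
# position 1..(n-L+1)?
block_match_vector <- function(chars, block) {
  n <- length(chars)
  L <- nchar(block)
  if (L > n) return(logical(0))
  letters_b <- strsplit(block, "")[[1]]
  ok <- chars %in% IUPAC_SETS[[letters_b[1]]]
  m <- ok[seq_len(n - L + 1L)]
  if (L > 1L) for (j in 2:L) {
    ok <- chars %in% IUPAC_SETS[[letters_b[j]]]
    m <- m & ok[j:(n - L + j)]
  }
  m
}

# Best (minimal total gap, then lexicographically smallest from the left)
# gap assignment for blocks k..K starting at position p. Returns the gap
# vector or NULL.
best_assignment <- function(match_at, blens, gmin, gmax, k, p) {
  K <- length(blens)
  if (k > K) return(integer(0))
  best <- NULL; best_total <- Inf
  for (g in gmin[k]:gmax[k]) {
    start <- p + g
    mv <- match_at[[k]]
    if (start > length(mv) || !mv[start]) next
    tail_gaps <- best_assignment(match_at, blens, gmin, gmax, k + 1L,
                                 start + blens[k])
    if (is.null(tail_gaps)) next
    total <- g + sum(tail_gaps)
    if (total < best_total) {
      best <- c(g, tail_gaps); best_total <- total
    }
    # gaps are tried in increasing order, so the first assignment achieving
    # a given total is already lexicographically smallest from the left
  }
  best
}

#' Scan a sequence for motif hits
#'
#' Reports one hit per start position that admits at least one gap-length
#' assignment; among multiple assignments for the same start, the minimal
#' total-gap (then leftmost-smallest) assignment determines the reported
#' match, so assignment multiplicity never inflates hit counts. Overlapping
#' hits at different starts are all reported. `N` in the sequence matches
#' only motif `N`.
#'
#' @param sequence A character scalar over `A,C,G,T,N` (case-insensitive).
#' @param motif An [parse_motif()] object.
#' @return A data.frame with `motif_id`, `start`, `end` (1-based closed
#'   within the sequence) and `matched` (the matched substring, gaps
#'   included).
#' @export
scan_motif <- function(sequence, motif) {
  seq <- toupper(sequence)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  empty <- data.frame(motif_id = character(), start = integer(),
                      end = integer(), matched = character(),
                      stringsAsFactors = FALSE)
  blens <- nchar(motif$blocks)
  min_len <- sum(blens) + sum(motif$gap_min)
  if (n < min_len) return(empty)
  match_at <- lapply(motif$blocks, block_match_vector, chars = chars)
  starts <- which(match_at[[1L]])
  if (length(starts) == 0L) return(empty)
  K <- length(blens)
  res_start <- integer(); res_end <- integer()
  for (p in starts) {
    gaps <- best_assignment(match_at, blens, motif$gap_min, motif$gap_max,
                            2L, p + blens[1L])
    if (is.null(gaps) && K > 1L) next
    end <- p + sum(blens) + (if (K > 1L) sum(gaps) else 0L) - 1L
    if (end > n) next
    res_start <- c(res_start, p); res_end <- c(res_end, end)
  }
  if (length(res_start) == 0L) return(empty)
  data.frame(motif_id = motif$motif_id, start = res_start, end = res_end,
             matched = substring(seq, res_start, res_end),
             stringsAsFactors = FALSE)
}

#' Scan a context set for a list of motifs
#'
#' Runs [scan_motif()] over every context sequence and resolves each hit to
#' absolute coordinates in its space: genomic hits to chromosome positions
#' (strand-aware: contexts of minus-strand sites are reverse-complemented,
#' so hit coordinates are mapped back to the genome's forward strand),
#' transcript hits to spliced-transcript positions.
#'
#' @param contexts A context data.frame ([extract_genomic_context()] /
#'   [extract_transcript_context()]).
#' @param motifs A list of [parse_motif()] objects (or a single one).
#' @return A data.frame of hits: `motif_id`, `site_id`, `space`, `target`,
#'   `strand`, `start`, `end` (absolute, 1-based closed), `ctx_start`,
#'   `ctx_end` (within the context sequence), `matched`.
#' @export
scan_contexts <- function(contexts, motifs) {
  if (methods::is(motifs, "rbp_motif")) motifs <- list(motifs)
  rows <- list()
  for (i in seq_len(nrow(contexts))) {
    for (mo in motifs) {
      h <- scan_motif(contexts$sequence[i], mo)
      if (nrow(h) == 0L) next
      minus <- contexts$strand[i] == "-"
      if (minus) {
        abs_start <- contexts$win_end[i] - h$end + 1L
        abs_end <- contexts$win_end[i] - h$start + 1L
      } else {
        abs_start <- contexts$win_start[i] + h$start - 1L
        abs_end <- contexts$win_start[i] + h$end - 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = h$motif_id, site_id = contexts$site_id[i],
        space = contexts$space[i], target = contexts$target[i],
        strand = contexts$strand[i], start = abs_start, end = abs_end,
        ctx_start = h$start, ctx_end = h$end, matched = h$matched,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(motif_id = character(), site_id = character(),
                      space = character(), target = character(),
                      strand = character(), start = integer(),
                      end = integer(), ctx_start = integer(),
                      ctx_end = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Deduplicate motif hits at identical absolute positions
#'
#' Hits at the same genomic or transcript position are counted only once:
#' unique on (space, target, strand, start, end, motif id), keeping the
#' first occurrence. This makes hit counts invariant to overlapping context
#' windows covering the same position.
#'
#' @param hits A hits data.frame from [scan_contexts()].
#' @return The deduplicated data.frame.
#' @export
dedupe_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$space, hits$target, hits$strand, hits$start, hits$end,
               hits$motif_id, sep = "\r")
  hits[!duplicated(key), , drop = FALSE]
}

#' Map a transcript-space motif hit to genomic blocks
#'
#' Applies [transcript_to_genome()] to the hit interval. A hit is *split*
#' iff it maps to two or more genomic blocks, i.e. it straddles at least one
#' splice junction.
#'
#' @param hit One row of a transcript-space hits data.frame.
#' @param model The hit's [transcript_model()].
#' @return A list: `hit` (the input row), `blocks`
#'   ([GenomicRanges::GRanges]), `split` (logical).
#' @export
map_hit_to_genome <- function(hit, model) {
  stopifnot(hit$space == "transcript")
  blocks <- transcript_to_genome(hit$start, hit$end, model)
  list(hit = hit, blocks = blocks, split = length(blocks) >= 2L)
}

#' Compare length-normalised motif frequencies between context sets
#'
#' Densities are hits per nt of total context set length; the percent change
#' of transcript over genomic density is `100 * (density_t/density_g - 1)`.
#' With zero genomic hits the change is undefined and flagged.
#'
#' @param hits_t,hits_g Deduplicated hit counts in transcript / genomic
#'   context sets.
#' @param len_t,len_g Total context set lengths in nt (> 0).
#' @return A list: `density_t`, `density_g`, `percent_change`, `undefined`.
#' @export
compare_frequencies <- function(hits_t, len_t, hits_g, len_g) {
  if (len_t <= 0 || len_g <= 0) stop("context set lengths must be > 0")
  dt <- hits_t / len_t
  dg <- hits_g / len_g
  if (hits_g == 0) {
    list(density_t = dt, density_g = dg, percent_change = NA_real_,
         undefined = TRUE)
  } else {
    list(density_t = dt, density_g = dg,
         percent_change = 100 * (dt / dg - 1), undefined = FALSE)
  }
}

#' Write motif hits as BED (BED6 unsplit, BED12 for split hits)
#'
#' Genomic-space (or genome-mapped) hits only. Hits with a single block are
#' written as BED6; hits with >= 2 blocks as BED12 with
#' blockCount/blockSizes/blockStarts describing the splice-junction split.
#'
#' @param mapped A list of [map_hit_to_genome()] results, or a genomic hits
#'   data.frame (treated as unsplit single blocks).
#' @param path Output path.
#' @export
write_hits_bed <- function(mapped, path) {
  lines <- character()
  if (is.data.frame(mapped)) {
    mapped <- lapply(seq_len(nrow(mapped)), function(i) {
      h <- mapped[i, ]
      list(hit = h,
           blocks = GenomicRanges::GRanges(
             h$target, IRanges::IRanges(h$start, h$end), strand = h$strand),
           split = FALSE)
    })
  }
  for (m in mapped) {
    b <- m$blocks
    chrom <- as.character(GenomicRanges::seqnames(b))[1]
    s0 <- min(GenomicRanges::start(b)) - 1L
    e0 <- max(GenomicRanges::end(b))
    name <- paste0(m$hit$motif_id, "@", m$hit$site_id)
    strand <- as.character(GenomicRanges::strand(b))[1]
    if (strand == "*") strand <- "."
    if (length(b) == 1L) {
      lines <- c(lines, paste(chrom, s0, e0, name, 0, strand, sep = "\t"))
    } else {
      sizes <- paste0(paste(GenomicRanges::width(b), collapse = ","), ",")
      starts <- paste0(paste(GenomicRanges::start(b) - 1L - s0,
                             collapse = ","), ",")
      lines <- c(lines, paste(chrom, s0, e0, name, 0, strand, s0, e0,
                              "0,0,0", length(b), sizes, starts, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
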