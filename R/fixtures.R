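rand_int <- function(lo, hi) if (lo >= hi) as.integer(lo) else
  sample(seq.int(lo, hi), 1L)

complement_chars <- function(x) chartr("ACGTN", "TGCAN", x)

site_truth_row <- function(site_rows, id) {
  site_rows[[which(vapply(site_rows, function(x) x$id, "") == id)[1L]]]
}

# Concrete realisation of a motif: IUPAC letters resolved to random concrete
# bases, gap bases random. Gap lengths are realised at their minima so the
# planted assignment is the unique minimal-total-gap one — the scanner then
# reports exactly the planted span (random longer spacers can by chance
# contain a shorter complete assignment starting at the same position).
realize_motif <- function(motif) {
  out <- character()
  for (i in seq_along(motif$blocks)) {
    if (i > 1L) {
      g <- motif$gap_min[i]
      if (g > 0L) out <- c(out, sample(c("A", "C", "G", "T"), g,
                                       replace = TRUE))
    }
    for (ch in strsplit(motif$blocks[i], "")[[1]]) {
      allowed <- setdiff(IUPAC_SETS[[ch]], "N")
      out <- c(out, if (length(allowed) == 1L) allowed
               else sample(allowed, 1L))
    }
  }
  paste(out, collapse = "")
}

# Genomic position (1-based) of every transcript position, in 5'->3' order.
tx_to_genomic_positions <- function(model) {
  exons <- tx_order_exons(model)
  unlist(lapply(seq_along(exons), function(k) {
    if (model$strand == "+") {
      seq.int(IRanges::start(exons)[k], IRanges::end(exons)[k])
    } else {
      seq.int(IRanges::end(exons)[k], IRanges::start(exons)[k])
    }
  }), use.names = FALSE)
}

#' Generate a deterministic synthetic test fixture
#'
#' Builds a toy genome (i.i.d. uniform bases), a multi-gene Ensembl-style
#' annotation with APPRIS/TSL/basic labels, a BED set of peak sites planted
#' per category, and optionally motif instances written into the genome at
#' chosen spliced positions — including instances straddling splice
#' junctions, whose spliced image is split across the flanking exon ends.
#' Every planted object is recorded in machine-readable truth tables, and
#' identical seeds give byte-identical output files.
#'
#' Layout guarantees: gene 1 is single-exon, roughly 40% of genes are on the
#' minus strand, and genes are spread over up to three chromosomes. When
#' `decoys = TRUE`, multi-exon genes receive a second isoform with strictly
#' worse selection labels (worse APPRIS, worse TSL, or missing labels), plus
#' one extra gene whose only isoform lacks a TSL label and must therefore be
#' excluded by [select_most_prominent()]; the expected winner per gene is
#' recorded in the truth.
#'
#' Site categories (all on the expected most-prominent isoforms):
#' `exonic` (deep inside an exon, > `border_margin` nt from both borders),
#' `near_border` (10..`border_margin` nt from an intron-facing exon border,
#' far enough to never form a pair), `pair` (site pairs flanking an unused
#' splice junction, both inner ends < 10 nt from the adjacent borders),
#' `intronic` (fully inside an intron), and `transcript_end` (short exonic
#' sites whose center lies k < 80 nt from a transcript end; the truth
#' records k). Motif instances additionally get one site each, centered on
#' the instance.
#'
#' @param out_dir Directory for the emitted files (created if needed);
#'   `NULL` generates in-memory only.
#' @param n_genes Number of labelled genes.
#' @param exons_per_gene Integer range (length-2) of exon counts for genes
#'   2..n (gene 1 is single-exon).
#' @param exon_len,intron_len Integer ranges of exon/intron lengths in nt.
#' @param n_sites Named list of category counts: `exonic`, `near_border`,
#'   `pair` (number of sites, even), `intronic`, `transcript_end`.
#' @param site_len Integer range of planted site lengths.
#' @param motifs List of plant requests, each a list with `motif` (an
#'   [parse_motif()] object or spec string), `n` (instances) and `split`
#'   (straddle a junction?).
#' @param border_margin Deep/near-border placement margin in nt (default 50,
#'   the near-border threshold).
#' @param decoys Add decoy isoforms and an unlabelled gene (default TRUE).
#' @param seed Integer seed; fixes all randomness.
#' @return A list: `genome` ([Biostrings::DNAStringSet]), `models` (all
#'   isoforms), `expected_prominent` (named character, gene -> transcript),
#'   `sites` (GRanges with `category` column), `site_truth` (data.frame),
#'   `motif_truth` (data.frame: motif, transcript, spliced coordinates,
#'   split flag, genomic blocks, instance string, associated site id),
#'   `paths` (written files, or NULL).
#' @export
make_fixture <- function(out_dir = NULL, n_genes = 10,
                         exons_per_gene = c(3, 5),
                         exon_len = c(140, 250), intron_len = c(60, 200),
                         n_sites = list(exonic = 10, near_border = 6,
                                        pair = 4, intronic = 8,
                                        transcript_end = 0),
                         site_len = c(15, 30), motifs = list(),
                         border_margin = 50L, decoys = TRUE, seed = 1L) {
  stopifnot(n_genes >= 2L, exon_len[1] >= 2L * border_margin + site_len[2],
            (n_sites$pair %||% 0L) %% 2L == 0L)
  set.seed(seed)
  chroms <- paste0("chr", c("A", "B", "C"))[seq_len(min(3L, n_genes))]
  cursor <- stats::setNames(rep(201L, length(chroms)), chroms)

  ## --- gene structures -----------------------------------------------
  models <- list()
  expected <- character()
  minus_genes <- sample(seq_len(n_genes), max(1L, round(0.4 * n_genes)))
  for (g in seq_len(n_genes)) {
    chrom <- chroms[(g - 1L) %% length(chroms) + 1L]
    strand <- if (g %in% minus_genes) "-" else "+"
    n_ex <- if (g == 1L) 1L else rand_int(exons_per_gene[1],
                                          exons_per_gene[2])
    ws <- vapply(seq_len(n_ex), function(i)
      rand_int(exon_len[1], exon_len[2]), integer(1))
    gaps <- if (n_ex > 1L) vapply(seq_len(n_ex - 1L), function(i)
      rand_int(intron_len[1], intron_len[2]), integer(1)) else integer()
    starts <- cursor[[chrom]] + c(0L, cumsum(ws[-n_ex] + gaps))
    ends <- starts + ws - 1L
    cursor[[chrom]] <- max(ends) + 300L
    tid <- sprintf("t%02d", g); gid <- sprintf("g%02d", g)
    appris <- sample(paste0("principal", 1:3), 1L)
    tsl <- rand_int(1L, 3L)
    m <- transcript_model(tid, gid, chrom, strand,
                          IRanges::IRanges(starts, ends),
                          gene_name = toupper(gid), appris = appris,
                          tsl = tsl, basic = TRUE,
                          biotype = "protein_coding")
    models[[tid]] <- m
    expected[gid] <- tid
    if (decoys && n_ex >= 2L && g %% 2L == 0L) {
      dtid <- paste0(tid, "d")
      scheme <- sample(c("worse_appris", "worse_tsl", "unlabelled"), 1L)
      d_appris <- appris; d_tsl <- tsl; d_basic <- TRUE
      if (scheme == "worse_appris") {
        d_appris <- sample(c("principal5", "alternative1"), 1L)
        d_tsl <- 1L                       # better TSL must not win
      } else if (scheme == "worse_tsl") {
        d_tsl <- min(5L, tsl + rand_int(1L, 2L))
      } else {
        d_tsl <- NA_integer_; d_appris <- "none"
      }
      models[[dtid]] <- transcript_model(
        dtid, gid, chrom, strand, IRanges::IRanges(starts, ends)[-n_ex],
        gene_name = toupper(gid), appris = d_appris, tsl = d_tsl,
        basic = d_basic, biotype = "protein_coding")
    }
  }
  if (decoys) {
    # a gene whose only isoform lacks a TSL label: excluded from selection
    chrom <- chroms[1L]
    s <- cursor[[chrom]]
    models[["tUn"]] <- transcript_model(
      "tUn", "gUn", chrom, "+", IRanges::IRanges(s, s + exon_len[1] - 1L),
      gene_name = "GUN", appris = "principal1", tsl = NA_integer_,
      basic = TRUE, biotype = "lincRNA")
    cursor[[chrom]] <- s + exon_len[1] + 300L
  }
  prominent <- models[unname(expected)]
  names(prominent) <- unname(expected)

  ## --- genome --------------------------------------------------------
  genome_chars <- lapply(chroms, function(ch) {
    sample(c("A", "C", "G", "T"), cursor[[ch]] + 200L, replace = TRUE)
  })
  names(genome_chars) <- chroms

  ## --- motif planting ------------------------------------------------
  occupied <- lapply(stats::setNames(nm = names(prominent)),
                     function(x) IRanges::IRanges())
  reserve <- function(tid, a, b) {
    occupied[[tid]] <<- c(occupied[[tid]], IRanges::IRanges(a, b))
  }
  is_free <- function(tid, a, b) {
    !IRanges::overlapsAny(IRanges::IRanges(a, b), occupied[[tid]])
  }
  gpos_cache <- lapply(prominent, tx_to_genomic_positions)
  motif_truth <- list()
  site_rows <- list()
  protected <- lapply(stats::setNames(nm = chroms),
                      function(x) logical(0))
  mark_protected <- function(chrom, pos) {
    v <- protected[[chrom]]
    if (length(v) < length(genome_chars[[chrom]])) {
      v <- c(v, rep(FALSE, length(genome_chars[[chrom]]) - length(v)))
    }
    v[pos] <- TRUE
    protected[[chrom]] <<- v
  }
  ms_counter <- 0L
  parsed_requests <- lapply(motifs, function(req) {
    mo <- req$motif
    if (is.character(mo)) mo <- parse_motif(mo)
    list(motif = mo, n = req$n, split = isTRUE(req$split))
  })
  for (req in parsed_requests) {
    mo <- req$motif
    for (inst in seq_len(req$n)) {
      instance <- realize_motif(mo)
      L <- nchar(instance)
      placed <- FALSE
      for (try in 1:200) {
        if (req$split) {
          elig <- names(prominent)[vapply(prominent, function(m)
            length(m$exons) >= 2L, logical(1))]
          tid <- if (length(elig) == 1L) elig else sample(elig, 1L)
          m <- prominent[[tid]]
          exw <- IRanges::width(tx_order_exons(m))
          j <- rand_int(1L, length(exw) - 1L)
          J <- sum(exw[seq_len(j)])          # tx position of exon j 3' base
          sl <- sum(exw)
          # keep both genomic runs shorter than the motif's minimal match
          # length, so no complete match can sit on one side of the junction
          minlen <- sum(nchar(mo$blocks)) + sum(mo$gap_min)
          u_lo <- max(1L, L - (sl - J), L - minlen + 1L)
          u_hi <- min(L - 1L, J, minlen - 1L)
          if (u_lo > u_hi) next
          u <- rand_int(u_lo, u_hi)          # bases of instance in exon j
          a <- J - u + 1L; b <- a + L - 1L
        } else {
          tid <- sample(names(prominent), 1L)
          m <- prominent[[tid]]
          exw <- IRanges::width(tx_order_exons(m))
          ok_ex <- which(exw >= L + 4L)
          if (length(ok_ex) == 0L) next
          k <- if (length(ok_ex) == 1L) ok_ex else sample(ok_ex, 1L)
          off <- sum(exw[seq_len(k - 1L)])
          a <- off + rand_int(1L, exw[k] - L + 1L); b <- a + L - 1L
        }
        if (!is_free(tid, max(1L, a - 1L), min(sum(exw), b + 1L))) next
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place ", mo$motif_id, " instance ", inst,
             " (motif may exceed the containing exon pair)")
      }
      reserve(tid, a, b)
      m <- prominent[[tid]]
      gpos <- gpos_cache[[tid]][a:b]
      inst_chars <- strsplit(instance, "")[[1]]
      gc <- if (m$strand == "-") complement_chars(inst_chars) else inst_chars
      genome_chars[[m$chrom]][gpos] <- gc
      mark_protected(m$chrom, gpos)
      # contiguous genomic runs = split blocks
      brk <- which(abs(diff(gpos)) != 1L)
      run_start <- c(1L, brk + 1L); run_end <- c(brk, length(gpos))
      blocks <- vapply(seq_along(run_start), function(r) {
        p <- gpos[run_start[r]:run_end[r]]
        sprintf("%s:%d-%d", m$chrom, min(p), max(p))
      }, "")
      # one short contiguous exonic site near the instance midpoint; shifted
      # within its exon so it never straddles the junction itself, while the
      # +/-80 nt transcript window around its center still spans the whole
      # instance (instance length < 155 nt guaranteed by the grammar used)
      ms_counter <- ms_counter + 1L
      sid <- sprintf("ms%02d", ms_counter)
      c_tx <- a + (L - 1L) %/% 2L
      exw2 <- IRanges::width(tx_order_exons(m))
      cumw <- cumsum(exw2)
      kx <- which(cumw >= c_tx)[1L]
      lo_tx <- c(0L, cumw)[kx] + 1L; hi_tx <- cumw[kx]
      ws_tx <- min(max(c_tx - 3L, lo_tx), hi_tx - 6L)
      c_tx <- ws_tx + 3L
      g_site <- gpos_cache[[tid]][ws_tx:(ws_tx + 6L)]
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        id = sid, chrom = m$chrom, start = min(g_site), end = max(g_site),
        strand = m$strand, score = round(stats::runif(1, 2, 6), 3),
        pvalue = round(stats::runif(1, 0, 0.009), 6),
        category = "motif_site", transcript_id = tid,
        te_k = NA_integer_, te_side = NA_character_,
        pair_partner = NA_character_, stringsAsFactors = FALSE)
      motif_truth[[length(motif_truth) + 1L]] <- data.frame(
        motif_id = mo$motif_id, spec = mo$spec, transcript_id = tid,
        tx_start = a, tx_end = b, split = req$split,
        n_blocks = length(blocks),
        blocks = paste(blocks, collapse = ","),
        instance = instance, site_id = sid, stringsAsFactors = FALSE)
    }
  }
  motif_truth <- if (length(motif_truth)) do.call(rbind, motif_truth) else
    data.frame()

  ## --- scrub accidental motif matches from genomic context windows ----
  ## The genomic-context window of a junction-split instance must contain
  ## no full motif match (the planted bases are interrupted by the intron);
  ## chance matches in the random background are mutated away, never
  ## touching planted (protected) bases.
  if (nrow(motif_truth) > 0L) {
    all_motifs <- lapply(parsed_requests, `[[`, "motif")
    is_protected <- function(chrom, pos) {
      prot <- protected[[chrom]]
      ifelse(pos <= length(prot), prot[pos], FALSE)
    }
    scrub_window <- function(r) {
      m <- prominent[[motif_truth$transcript_id[r]]]
      srow <- site_truth_row(site_rows, motif_truth$site_id[r])
      ctr <- srow$start + (srow$end - srow$start) %/% 2L
      ws <- max(1L, ctr - 80L)
      we <- min(length(genome_chars[[m$chrom]]), ctr + 80L)
      flipped <- FALSE
      for (pass in 1:10) {
        win <- genome_chars[[m$chrom]][ws:we]
        winseq <- if (m$strand == "-") {
          paste(complement_chars(rev(win)), collapse = "")
        } else paste(win, collapse = "")
        dirty <- FALSE
        for (mo in all_motifs) {
          h <- scan_motif(winseq, mo)
          for (hi in seq_len(nrow(h))) {
            gps <- if (m$strand == "-") {
              seq.int(we - h$end[hi] + 1L, we - h$start[hi] + 1L)
            } else {
              seq.int(ws + h$start[hi] - 1L, ws + h$end[hi] - 1L)
            }
            free <- gps[!is_protected(m$chrom, gps)]
            if (length(free) == 0L) next
            # rotate every unprotected base of the hit: a spacer-only flip
            # would leave compound-motif matches intact
            cur <- genome_chars[[m$chrom]][free]
            genome_chars[[m$chrom]][free] <<- chartr("ACGT", "CGTA", cur)
            dirty <- TRUE; flipped <- TRUE
          }
        }
        if (!dirty) break
      }
      flipped
    }
    for (round in 1:3) {
      any_flip <- FALSE
      for (r in seq_len(nrow(motif_truth))) {
        if (scrub_window(r)) any_flip <- TRUE
      }
      if (!any_flip) break
    }
  }

  ## --- site planting --------------------------------------------------
  cnt <- function(k) as.integer(n_sites[[k]] %||% 0L)
  used_borders <- character()   # "tid:intron:side"
  multi <- names(prominent)[vapply(prominent, function(m)
    length(m$exons) >= 2L, logical(1))]
  pick_tid <- function(pool) if (length(pool) == 1L) pool else
    sample(pool, 1L)
  new_site <- function(id, tid, g_start, g_end, category,
                       te_k = NA_integer_, te_side = NA_character_,
                       partner = NA_character_) {
    m <- prominent[[tid]]
    data.frame(id = id, chrom = m$chrom, start = g_start, end = g_end,
               strand = m$strand, score = round(stats::runif(1, 1, 6), 3),
               pvalue = round(stats::runif(1, 0, 0.009), 6),
               category = category, transcript_id = tid, te_k = te_k,
               te_side = te_side, pair_partner = partner,
               stringsAsFactors = FALSE)
  }
  # deep exonic: both ends > border_margin from the exon borders
  for (i in seq_len(cnt("exonic"))) {
    st <- NULL
    for (.try in 1:500) {
      tid <- pick_tid(names(prominent))
      m <- prominent[[tid]]
      len <- rand_int(site_len[1], site_len[2])
      okx <- which(IRanges::width(m$exons) >= 2L * (border_margin + 1L) + len)
      if (length(okx) == 0L) next
      k <- if (length(okx) == 1L) okx else sample(okx, 1L)
      es <- IRanges::start(m$exons)[k]; ee <- IRanges::end(m$exons)[k]
      s <- rand_int(es + border_margin + 1L, ee - border_margin - len)
      # deep also means far from the transcript ends: the centered +/-80 nt
      # transcript window must fit without truncation
      gp <- gpos_cache[[tid]]
      p <- range(match(c(s, s + len - 1L), gp))
      cen <- p[1L] + (p[2L] - p[1L]) %/% 2L
      if (cen - 80L < 1L || cen + 80L > length(gp)) next
      st <- new_site(sprintf("ex%03d", i), tid, s, s + len - 1L, "exonic")
      break
    }
    if (is.null(st)) stop("could not place deep exonic site ", i)
    site_rows[[length(site_rows) + 1L]] <- st
  }
  # near-border: 10..border_margin nt from an intron-facing border
  for (i in seq_len(cnt("near_border"))) {
    st <- NULL
    for (.try in 1:500) {
      tid <- pick_tid(multi)
      m <- prominent[[tid]]
      exons_tx <- tx_order_exons(m)
      nex <- length(exons_tx)
      len <- rand_int(site_len[1], site_len[2])
      j <- rand_int(1L, nex - 1L)          # junction (tx order)
      side <- sample(c("donor", "acceptor"), 1L)
      key <- paste(tid, j, side, sep = ":")
      if (key %in% used_borders) next
      d <- rand_int(10L, border_margin)
      if (side == "donor") {               # 3' end of exon j near border
        ex <- exons_tx[j]
        if (m$strand == "+") {
          e <- IRanges::end(ex) - d; s <- e - len + 1L
          if (s <= IRanges::start(ex) + 10L) next
        } else {
          s <- IRanges::start(ex) + d; e <- s + len - 1L
          if (e >= IRanges::end(ex) - 10L) next
        }
      } else {                             # 5' end of exon j+1 near border
        ex <- exons_tx[j + 1L]
        if (m$strand == "+") {
          s <- IRanges::start(ex) + d; e <- s + len - 1L
          if (e >= IRanges::end(ex) - 10L) next
        } else {
          e <- IRanges::end(ex) - d; s <- e - len + 1L
          if (s <= IRanges::start(ex) + 10L) next
        }
      }
      used_borders <- c(used_borders, key)
      st <- new_site(sprintf("nb%03d", i), tid, s, e, "near_border")
      break
    }
    if (is.null(st)) stop("could not place near-border site ", i,
                          "; too few free exon borders")
    site_rows[[length(site_rows) + 1L]] <- st
  }
  # pair sites: both inner ends < 10 nt from adjacent borders of an intron
  for (i in seq_len(cnt("pair") %/% 2L)) {
    placed <- FALSE
    for (.try in 1:500) {
      tid <- pick_tid(multi)
      m <- prominent[[tid]]
      exons_tx <- tx_order_exons(m)
      j <- rand_int(1L, length(exons_tx) - 1L)
      k1 <- paste(tid, j, "donor", sep = ":")
      k2 <- paste(tid, j, "acceptor", sep = ":")
      if (k1 %in% used_borders || k2 %in% used_borders) next
      d1 <- rand_int(0L, 9L); d2 <- rand_int(0L, 9L)
      l1 <- rand_int(site_len[1], site_len[2])
      l2 <- rand_int(site_len[1], site_len[2])
      ex1 <- exons_tx[j]; ex2 <- exons_tx[j + 1L]
      if (IRanges::width(ex1) < l1 + d1 + 11L ||
          IRanges::width(ex2) < l2 + d2 + 11L) next
      if (m$strand == "+") {
        e1 <- IRanges::end(ex1) - d1; s1 <- e1 - l1 + 1L
        s2 <- IRanges::start(ex2) + d2; e2 <- s2 + l2 - 1L
      } else {
        s1 <- IRanges::start(ex1) + d1; e1 <- s1 + l1 - 1L
        e2 <- IRanges::end(ex2) - d2; s2 <- e2 - l2 + 1L
      }
      used_borders <- c(used_borders, k1, k2)
      id1 <- sprintf("pr%03da", i); id2 <- sprintf("pr%03db", i)
      site_rows[[length(site_rows) + 1L]] <-
        new_site(id1, tid, s1, e1, "pair", partner = id2)
      site_rows[[length(site_rows) + 1L]] <-
        new_site(id2, tid, s2, e2, "pair", partner = id1)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place site pair ", i,
                      "; too few free splice junctions")
  }
  # intronic
  for (i in seq_len(cnt("intronic"))) {
    placed <- FALSE
    for (.try in 1:500) {
      tid <- pick_tid(multi)
      m <- prominent[[tid]]
      n_ex <- length(m$exons)
      j <- rand_int(1L, n_ex - 1L)
      is_ <- IRanges::end(m$exons)[j] + 1L
      ie_ <- IRanges::start(m$exons)[j + 1L] - 1L
      len <- rand_int(site_len[1], site_len[2])
      if (ie_ - is_ + 1L < len + 4L) next
      s <- rand_int(is_ + 2L, ie_ - len - 1L)
      site_rows[[length(site_rows) + 1L]] <-
        new_site(sprintf("in%03d", i), tid, s, s + len - 1L, "intronic")
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place intronic site ", i)
  }
  # transcript-end: center k nt (3 <= k < 80) from the transcript 5'/3' end
  for (i in seq_len(cnt("transcript_end"))) {
    placed <- FALSE
    for (.try in 1:500) {
      tid <- pick_tid(names(prominent))
      m <- prominent[[tid]]
      sl <- spliced_length(m)
      side <- sample(c("5p", "3p"), 1L)
      k <- rand_int(3L, 79L)
      c_tx <- if (side == "5p") k + 1L else sl - k
      a <- c_tx - 3L; b <- c_tx + 3L
      if (a < 1L || b > sl) next
      gp <- gpos_cache[[tid]][a:b]
      if (any(abs(diff(gp)) != 1L)) next   # keep the site within one exon
      site_rows[[length(site_rows) + 1L]] <-
        new_site(sprintf("te%03d", i), tid, min(gp), max(gp),
                 "transcript_end", te_k = k, te_side = side)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place transcript-end site ", i)
  }
  site_truth <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), score = numeric(),
               pvalue = numeric(), category = character(),
               transcript_id = character(), te_k = integer(),
               te_side = character(), pair_partner = character(),
               stringsAsFactors = FALSE)

  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste, "",
                                            collapse = ""))
  names(genome) <- chroms
  sites_gr <- GenomicRanges::GRanges(
    site_truth$chrom,
    IRanges::IRanges(site_truth$start, site_truth$end),
    strand = site_truth$strand, id = site_truth$id,
    score = site_truth$score, pvalue = site_truth$pvalue,
    category = site_truth$category)
  names(sites_gr) <- site_truth$id

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = file.path(out_dir, "genome.fa"),
                  gtf = file.path(out_dir, "annotation.gtf"),
                  bed = file.path(out_dir, "sites.bed"),
                  site_truth = file.path(out_dir, "truth_sites.tsv"),
                  motif_truth = file.path(out_dir, "truth_motifs.tsv"),
                  prominent = file.path(out_dir, "truth_prominent.tsv"))
    Biostrings::writeXStringSet(genome, paths$fasta, width = 80L)
    write_fixture_gtf(models, paths$gtf)
    write_bed(sites_gr, paths$bed)
    utils::write.table(site_truth, paths$site_truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(motif_truth, paths$motif_truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = names(expected), transcript_id = unname(expected)),
      paths$prominent, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(genome = genome, models = models,
       expected_prominent = expected, prominent = prominent,
       sites = sites_gr, site_truth = site_truth,
       motif_truth = motif_truth, paths = paths, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_fixture_gtf <- function(models, path) {
  lines <- character()
  for (m in models) {
    tags <- character()
    if (isTRUE(m$basic)) tags <- c(tags, 'tag "basic";')
    if (m$appris != "none") {
      lab <- sub("^(principal|alternative)([0-9])$", "appris_\\1_\\2",
                 m$appris)
      tags <- c(tags, sprintf('tag "%s";', lab))
    }
    tsl_attr <- sprintf('transcript_support_level "%s";',
                        ifelse(is.na(m$tsl), "NA", m$tsl))
    for (k in seq_along(m$exons)) {
      attrs <- paste(
        sprintf('gene_id "%s";', m$gene_id),
        sprintf('transcript_id "%s";', m$transcript_id),
        sprintf('gene_name "%s";', m$gene_name),
        sprintf('gene_biotype "%s";', m$biotype),
        tsl_attr, paste(tags, collapse = " "))
      lines <- c(lines, paste(m$chrom, "txclip_fixture", "exon",
                              IRanges::start(m$exons)[k],
                              IRanges::end(m$exons)[k],
                              ".", m$strand, ".", trimws(attrs),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
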