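#' Map a genomic interval to spliced-transcript coordinates
#'
#' Transcript coordinates are 1-based closed and run 5'->3' along the mature
#' mRNA, so on a minus-strand model the genomic *end* of an exonic interval
#' maps to the smallest transcript coordinate. Fully exonic intervals map to
#' a single contiguous transcript interval; intervals that partially overlap
#' introns are reported with their exonic fraction and the transcript span of
#' their exonic bases, so that callers can apply their own overlap-fraction
#' policy.
#'
#' @param sites A [GenomicRanges::GRanges] of genomic intervals (one or more)
#'   on the model's chromosome.
#' @param model A [transcript_model()].
#' @return A data.frame with one row per input site: `site_id`,
#'   `transcript_id`, `tx_start`, `tx_end` (1-based closed; `NA` when no
#'   exonic overlap), `exonic_bases`, `site_width`, `exonic_fraction`, and
#'   `status` (`"mapped"`, `"partial"`, or `"none"`).
#' @export
genome_to_transcript <- function(sites, model) {
  stopifnot(methods::is(sites, "GRanges"))
  n <- length(sites)
  ids <- if (!is.null(names(sites)) && all(nzchar(names(sites)))) {
    names(sites)
  } else if (!is.null(sites$id)) as.character(sites$id) else
    paste0("site", seq_len(n))
  exons <- tx_order_exons(model)
  cum <- c(0L, cumsum(IRanges::width(exons)))
  out <- data.frame(site_id = ids, transcript_id = model$transcript_id,
                    tx_start = NA_integer_, tx_end = NA_integer_,
                    exonic_bases = 0L,
                    site_width = GenomicRanges::width(sites),
                    exonic_fraction = 0, status = "none",
                    stringsAsFactors = FALSE)
  on_chrom <- as.character(GenomicRanges::seqnames(sites)) == model$chrom
  s <- GenomicRanges::start(sites)
  e <- GenomicRanges::end(sites)
  for (i in seq_len(n)) {
    if (!on_chrom[i]) next
    lo <- Inf; hi <- -Inf; exonic <- 0L
    for (k in seq_along(exons)) {
      es <- IRanges::start(exons)[k]; ee <- IRanges::end(exons)[k]
      a <- max(s[i], es); b <- min(e[i], ee)
      if (a > b) next
      exonic <- exonic + (b - a + 1L)
      if (model$strand == "+") {
        t1 <- cum[k] + (a - es) + 1L
        t2 <- cum[k] + (b - es) + 1L
      } else {
        t1 <- cum[k] + (ee - b) + 1L
        t2 <- cum[k] + (ee - a) + 1L
      }
      lo <- min(lo, t1); hi <- max(hi, t2)
    }
    if (exonic > 0L) {
      out$tx_start[i] <- as.integer(lo)
      out$tx_end[i] <- as.integer(hi)
      out$exonic_bases[i] <- exonic
      out$exonic_fraction[i] <- exonic / out$site_width[i]
      out$status[i] <- if (exonic == out$site_width[i]) "mapped" else "partial"
    }
  }
  out
}

#' Map a transcript interval back to genomic coordinates
#'
#' The exact inverse of [genome_to_transcript()] on exonic bases. An interval
#' crossing k splice junctions yields k+1 genomic blocks, returned in genomic
#' order; consecutive blocks are separated exactly by whole introns of the
#' model.
#'
#' @param tx_start,tx_end 1-based closed spliced coordinates
#'   (`1 <= tx_start <= tx_end <= spliced_length(model)`).
#' @param model A [transcript_model()].
#' @return A [GenomicRanges::GRanges] of blocks on the model's
#'   chromosome/strand, sorted by genomic start.
#' @export
transcript_to_genome <- function(tx_start, tx_end, model) {
  sl <- spliced_length(model)
  if (tx_start < 1L || tx_end < tx_start || tx_end > sl) {
    stop("transcript interval [", tx_start, ",", tx_end,
         "] outside spliced length ", sl, " of ", model$transcript_id)
  }
  exons <- tx_order_exons(model)
  cum <- c(0L, cumsum(IRanges::width(exons)))
  starts <- integer(); ends <- integer()
  for (k in seq_along(exons)) {
    a <- max(tx_start, cum[k] + 1L)
    b <- min(tx_end, cum[k + 1L])
    if (a > b) next
    es <- IRanges::start(exons)[k]; ee <- IRanges::end(exons)[k]
    if (model$strand == "+") {
      gs <- es + (a - cum[k] - 1L)
      ge <- es + (b - cum[k] - 1L)
    } else {
      ge <- ee - (a - cum[k] - 1L)
      gs <- ee - (b - cum[k] - 1L)
    }
    starts <- c(starts, gs); ends <- c(ends, ge)
  }
  o <- order(starts)
  GenomicRanges::GRanges(model$chrom,
                         IRanges::IRanges(starts[o], ends[o]),
                         strand = model$strand)
}

#' Spliced (mature mRNA) sequence of a transcript model
#'
#' Concatenates the exon substrings in genomic order and reverse-complements
#' the result for minus-strand models, yielding the 5'->3' mRNA sequence
#' (DNA alphabet, uppercased).
#'
#' @param model A [transcript_model()].
#' @param genome A named [Biostrings::DNAStringSet] (names = chromosomes) or
#'   a path to a FASTA file.
#' @return A character scalar of length `spliced_length(model)`.
#' @export
spliced_sequence <- function(model, genome) {
  genome <- as_genome(genome)
  if (!model$chrom %in% names(genome)) {
    stop("chromosome ", model$chrom, " not present in genome")
  }
  chrom <- genome[[model$chrom]]
  if (max(IRanges::end(model$exons)) > length(chrom)) {
    stop("exon of ", model$transcript_id, " exceeds length of ",
         model$chrom, " (", length(chrom), " nt)")
  }
  seq <- unlist(Biostrings::extractAt(chrom, model$exons))
  if (model$strand == "-") seq <- Biostrings::reverseComplement(seq)
  toupper(as.character(seq))
}

as_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    # FASTA headers may carry descriptions after the id
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Assign genomic sites to transcript models by maximal exon overlap
#'
#' Each site is assigned to the model (among e.g. the most prominent
#' isoforms) whose exons it overlaps most, requiring matching strand
#' (strand `"*"` sites match both); ties are broken lexicographically by
#' transcript id. Sites with no exonic overlap get `NA`.
#'
#' @param sites A [GenomicRanges::GRanges] with a `$id` column (or names).
#' @param models List of [transcript_model()] objects.
#' @return Character vector of transcript ids, parallel to `sites`.
#' @export
assign_sites <- function(sites, models) {
  n <- length(sites)
  if (n == 0L || length(models) == 0L) return(rep(NA_character_, n))
  ex <- suppressWarnings(do.call(c, unname(lapply(models, function(m) {
    g <- GenomicRanges::GRanges(m$chrom, m$exons, strand = m$strand)
    g$tid <- m$transcript_id
    g
  }))))
  hits <- GenomicRanges::findOverlaps(sites, ex)
  if (length(hits) == 0L) return(rep(NA_character_, n))
  ov <- IRanges::pintersect(
    GenomicRanges::ranges(sites)[S4Vectors::queryHits(hits)],
    GenomicRanges::ranges(ex)[S4Vectors::subjectHits(hits)])
  df <- data.frame(site = S4Vectors::queryHits(hits),
                   tid = ex$tid[S4Vectors::subjectHits(hits)],
                   w = IRanges::width(ov), stringsAsFactors = FALSE)
  agg <- stats::aggregate(w ~ site + tid, data = df, FUN = sum)
  agg <- agg[order(agg$site, -agg$w, agg$tid), ]
  best <- agg[!duplicated(agg$site), ]
  out <- rep(NA_character_, n)
  out[best$site] <- best$tid
  out
}
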