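#' Sample negative (unbound) sites for classifier training
#'
#' Negative sites are drawn uniformly at random from the gene spans (first to
#' last exon of each model) of genes covered by at least one positive peak
#' region, under two constraints taken base-by-base: a negative never
#' overlaps any positive site (on either strand), and sampled negatives are
#' mutually non-overlapping. Each negative inherits the strand of its gene.
#' Sampling is deterministic for a fixed seed.
#'
#' @param models Named list of [transcript_model()] objects (e.g. the most
#'   prominent isoforms).
#' @param positives A [GenomicRanges::GRanges] of positive sites.
#' @param n Number of negatives requested.
#' @param site_len Length of each negative in nt; defaults to 161
#'   (= 2*80 + 1), matching the full context window so negatives need no
#'   further extension.
#' @param seed Integer seed.
#' @return A [GenomicRanges::GRanges] with `id` and `score` (0) columns and
#'   an attribute `exhausted = TRUE` (plus a warning) when fewer than `n`
#'   eligible positions exist.
#' @export
sample_negatives <- function(models, positives, n, site_len = 161L,
                             seed = 1L) {
  stopifnot(n >= 1L, site_len >= 1L)
  spans <- suppressWarnings(do.call(c, unname(lapply(models, function(m) {
    GenomicRanges::GRanges(m$chrom,
                           IRanges::IRanges(min(IRanges::start(m$exons)),
                                            max(IRanges::end(m$exons))),
                           strand = m$strand)
  }))))
  covered <- spans[suppressWarnings(
    IRanges::overlapsAny(spans, positives, ignore.strand = TRUE))]
  if (length(covered) == 0L) {
    stop("no genes covered by positive sites; cannot sample negatives")
  }
  # free intervals = covered spans minus positive bases (strand-blind)
  free <- suppressWarnings(GenomicRanges::setdiff(
    GenomicRanges::GRanges(GenomicRanges::seqnames(covered),
                           GenomicRanges::ranges(covered), strand = "*"),
    GenomicRanges::GRanges(GenomicRanges::seqnames(positives),
                           GenomicRanges::ranges(positives), strand = "*")))
  # candidate start positions admitting a full-length site
  cand <- list()
  for (i in seq_along(free)) {
    w <- GenomicRanges::width(free)[i]
    if (w < site_len) next
    chrom <- as.character(GenomicRanges::seqnames(free)[i])
    starts <- GenomicRanges::start(free)[i]:(GenomicRanges::end(free)[i] -
                                               site_len + 1L)
    cand[[length(cand) + 1L]] <- data.frame(chrom = chrom, start = starts,
                                            stringsAsFactors = FALSE)
  }
  out_chrom <- character(); out_start <- integer()
  if (length(cand) > 0L) {
    cand <- unique(do.call(rbind, cand))
    cand <- cand[order(cand$chrom, cand$start), , drop = FALSE]
    set.seed(seed)
    alive <- rep(TRUE, nrow(cand))
    while (length(out_start) < n && any(alive)) {
      idx <- which(alive)
      pick <- idx[sample.int(length(idx), 1L)]
      out_chrom <- c(out_chrom, cand$chrom[pick])
      out_start <- c(out_start, cand$start[pick])
      clash <- cand$chrom == cand$chrom[pick] &
        abs(cand$start - cand$start[pick]) < site_len
      alive[clash] <- FALSE
    }
  }
  exhausted <- length(out_start) < n
  if (exhausted) {
    warning("only ", length(out_start), " of ", n,
            " requested negatives could be sampled")
  }
  strand_of <- function(chrom, start) {
    hit <- which(as.character(GenomicRanges::seqnames(covered)) == chrom &
                   GenomicRanges::start(covered) <= start &
                   GenomicRanges::end(covered) >= start)
    if (length(hit)) as.character(GenomicRanges::strand(covered))[hit[1L]]
    else "*"
  }
  gr <- GenomicRanges::GRanges(
    out_chrom, IRanges::IRanges(out_start, width = site_len),
    strand = vapply(seq_along(out_start),
                    function(i) strand_of(out_chrom[i], out_start[i]), ""),
    id = if (length(out_start)) paste0("neg", seq_along(out_start))
         else character(),
    score = rep(0, length(out_start)))
  gr <- sort(gr)
  gr$id <- if (length(gr)) paste0("neg", seq_along(gr)) else character()
  names(gr) <- gr$id
  attr(gr, "exhausted") <- exhausted
  gr
}
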