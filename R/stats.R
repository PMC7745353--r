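#' Dataset-level exon-binding statistics
#'
#' Composes the site-classification steps into the summary reported per
#' CLIP-seq dataset: the fraction of sites with >= `exon_overlap_frac` exon
#' overlap (exonic sites), the fraction *of exonic sites* lying within
#' `border_dist` nt of an exon border, the fraction *of exonic sites* that
#' form adjacent-exon-border pairs at `pair_dist`, and the mean log2 fold
#' change of exonic sites and of pair sites.
#'
#' Sites are assumed already replicate-merged and LFC-filtered. Border
#' distances are measured after clipping intron-overhanging ends to the exon
#' union of the assigned model (sites classified exonic at fractional
#' overlap may overhang by up to 10% of their length).
#'
#' @param sites A [GenomicRanges::GRanges] site set.
#' @param models Named list of [transcript_model()] (the most prominent
#'   isoforms).
#' @param thr A [thresholds()] object (uses `exon_overlap_frac`,
#'   `border_dist`, `pair_dist`).
#' @return A list of class `dataset_stats`: `n_sites`, `n_exonic`,
#'   `exonic_ratio`, `n_near_border`, `near_border_ratio`, `n_pair_sites`
#'   (number of sites in pairs, even), `pair_ratio`, `mean_score_exonic`,
#'   `mean_score_pairs`, and the per-site table `site_table`. Ratios over an
#'   empty denominator are `NA`.
#' @export
dataset_stats <- function(sites, models, thr = thresholds()) {
  exons <- exon_union(models)
  cls <- classify_exonic(sites, exons, frac = thr$exon_overlap_frac)
  exonic <- sites[cls$exonic]
  assigned <- assign_sites(exonic, models)
  by_tid <- stats::setNames(models,
                            vapply(models, `[[`, "", "transcript_id"))
  min_bd <- rep(NA_integer_, length(exonic))
  for (i in seq_along(exonic)) {
    tid <- assigned[i]
    if (is.na(tid) || is.null(by_tid[[tid]])) next
    bd <- tryCatch(border_distance(exonic[i], by_tid[[tid]], clip = TRUE),
                   error = function(e) NULL)
    if (!is.null(bd)) min_bd[i] <- min(bd$dist5, bd$dist3)
  }
  near <- !is.na(min_bd) & min_bd <= thr$border_dist
  pairs <- detect_pairs(exonic, assigned, models, pair_dist = thr$pair_dist)
  in_pair <- exonic$id %in% c(pairs$id1, pairs$id2)
  n_ex <- length(exonic)
  st <- data.frame(id = if (n_ex) exonic$id else character(),
                   transcript_id = assigned,
                   min_border_dist = min_bd,
                   near_border = near, in_pair = in_pair,
                   score = if (n_ex) exonic$score else numeric(),
                   stringsAsFactors = FALSE)
  structure(list(
    n_sites = length(sites),
    n_exonic = n_ex,
    exonic_ratio = if (length(sites)) n_ex / length(sites) else NA_real_,
    n_near_border = sum(near),
    near_border_ratio = if (n_ex) sum(near) / n_ex else NA_real_,
    n_pair_sites = sum(in_pair),
    pair_ratio = if (n_ex) sum(in_pair) / n_ex else NA_real_,
    mean_score_exonic = if (n_ex) mean(exonic$score) else NA_real_,
    mean_score_pairs = if (any(in_pair)) mean(exonic$score[in_pair])
                       else NA_real_,
    pairs = pairs, site_table = st), class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  pct <- function(r) ifelse(is.na(r), "NA", sprintf("%.1f%%", 100 * r))
  cat(sprintf("%d sites; %d exonic (%s)\n", x$n_sites, x$n_exonic,
              pct(x$exonic_ratio)))
  cat(sprintf("  near-border: %d (%s of exonic)\n", x$n_near_border,
              pct(x$near_border_ratio)))
  cat(sprintf("  pair sites:  %d (%s of exonic)\n", x$n_pair_sites,
              pct(x$pair_ratio)))
  cat(sprintf("  mean LFC exonic %.3f, pairs %.3f\n",
              x$mean_score_exonic, x$mean_score_pairs))
  invisible(x)
}

#' Bin exonic-site ratios of many datasets into percentage ranges
#'
#' Bins are `[0,25)`, `[25,50)`, `[50,75)`, `[75,100]` percent (the top bin
#' is right-closed).
#'
#' @param ratios Numeric vector of exonic-site ratios in `[0, 1]`.
#' @return A data.frame with `bin`, `count` and `percent` (of all datasets).
#' @export
ratio_binning <- function(ratios) {
  pct <- 100 * ratios
  labels <- c("[0,25)", "[25,50)", "[50,75)", "[75,100]")
  bin <- findInterval(pct, c(0, 25, 50, 75), rightmost.closed = FALSE)
  bin[pct >= 100] <- 4L
  counts <- tabulate(bin, nbins = 4L)
  data.frame(bin = labels, count = counts,
             percent = if (length(ratios)) 100 * counts / length(ratios)
                       else rep(0, 4L),
             stringsAsFactors = FALSE)
}

#' Squared Pearson correlation of exonic-site ratios across cell lines
#'
#' @param ratio_a,ratio_b Numeric vectors (one entry per RBP measured in
#'   both cell lines).
#' @return A list: `r_squared` (`NA` with `undefined = TRUE` when either
#'   vector has zero variance), `n`.
#' @export
exon_ratio_correlation <- function(ratio_a, ratio_b) {
  stopifnot(length(ratio_a) == length(ratio_b), length(ratio_a) >= 2L)
  if (stats::sd(ratio_a) == 0 || stats::sd(ratio_b) == 0) {
    return(list(r_squared = NA_real_, undefined = TRUE,
                n = length(ratio_a)))
  }
  list(r_squared = stats::cor(ratio_a, ratio_b)^2, undefined = FALSE,
       n = length(ratio_a))
}
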