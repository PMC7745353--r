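#' Center a site on a single base
#'
#' Odd-length sites keep their middle base; for even-length sites the more
#' 5' (on the site's strand) of the two central bases is chosen, so that
#' reverse-complementing an input reverses the choice consistently. Strand
#' `"*"` is treated as `"+"`.
#'
#' @param sites A [GenomicRanges::GRanges]; works for genomic sites and for
#'   transcript-space sites (seqnames = transcript id, strand `"+"`).
#' @return A GRanges of width-1 centers, metadata preserved.
#' @export
center_site <- function(sites) {
  w <- GenomicRanges::width(sites)
  stopifnot(all(w >= 1L))
  s <- GenomicRanges::start(sites)
  minus <- as.character(GenomicRanges::strand(sites)) == "-"
  c_odd <- s + (w - 1L) %/% 2L
  c_even <- ifelse(minus, s + w %/% 2L, s + w %/% 2L - 1L)
  centers <- ifelse(w %% 2L == 1L, c_odd, c_even)
  out <- sites
  GenomicRanges::ranges(out) <- IRanges::IRanges(centers, width = 1L)
  out
}

new_context <- function(site_id, space, target, strand, win_start, win_end,
                        up_trunc, dn_trunc, viewpoint, sequence) {
  data.frame(site_id = site_id, space = space, target = target,
             strand = strand, win_start = win_start, win_end = win_end,
             up_truncated = up_trunc, dn_truncated = dn_trunc,
             viewpoint = viewpoint, sequence = sequence,
             stringsAsFactors = FALSE)
}

#' Extract genomic sequence context around site centers
#'
#' Each site is centered ([center_site()]) and extended `ext` nt up- and
#' downstream on the genome (window length 2*ext+1, 161 nt at the default
#' ext = 80), reading straight through any introns. The sequence is
#' reverse-complemented for minus-strand sites so it reads 5'->3'; windows
#' are truncated only at chromosome ends, with the number of bases lost
#' recorded in `up_truncated`/`dn_truncated` (5'/3' of the site).
#'
#' @param sites Genomic [GenomicRanges::GRanges] sites (any width; centered
#'   internally).
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param ext Extension in nt on each side of the center (default 80).
#' @return A context data.frame: `site_id`, `space` (`"genomic"`), `target`
#'   (chromosome), `strand`, `win_start`/`win_end` (1-based genomic),
#'   `up_truncated`, `dn_truncated`, `viewpoint` (1-based position of the
#'   center within `sequence`), `sequence`.
#' @export
extract_genomic_context <- function(sites, genome, ext = 80L) {
  genome <- as_genome(genome)
  centers <- center_site(sites)
  n <- length(centers)
  rows <- vector("list", n)
  ids <- if (!is.null(centers$id)) centers$id else paste0("site", seq_len(n))
  for (i in seq_len(n)) {
    chrom <- as.character(GenomicRanges::seqnames(centers)[i])
    if (!chrom %in% names(genome)) {
      stop("chromosome ", chrom, " not present in genome")
    }
    clen <- length(genome[[chrom]])
    cpos <- GenomicRanges::start(centers)[i]
    ws <- max(1L, cpos - ext)
    we <- min(clen, cpos + ext)
    left_lost <- ws - (cpos - ext)
    right_lost <- (cpos + ext) - we
    seq <- toupper(as.character(Biostrings::subseq(genome[[chrom]], ws, we)))
    minus <- as.character(GenomicRanges::strand(centers)[i]) == "-"
    if (minus) {
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
      up <- right_lost; dn <- left_lost
      vp <- we - cpos + 1L
    } else {
      up <- left_lost; dn <- right_lost
      vp <- cpos - ws + 1L
    }
    rows[[i]] <- new_context(ids[i], "genomic", chrom,
                             if (minus) "-" else "+",
                             ws, we, up, dn, vp, seq)
  }
  do.call(rbind, rows)
}

#' Extract transcript (spliced) sequence context around site centers
#'
#' Sites are first mapped to spliced-transcript coordinates; the window
#' extension then happens in transcript space, reading through splice
#' junctions, and is truncated at the transcript 5'/3' ends with the lost
#' lengths recorded. Sequences come from [spliced_sequence()] and are
#' already 5'->3'.
#'
#' @param sites Genomic [GenomicRanges::GRanges] sites whose centers are
#'   exonic in their assigned model.
#' @param assigned Character vector of transcript ids parallel to `sites`
#'   ([assign_sites()]).
#' @param models Named list of [transcript_model()] objects (searched by
#'   transcript id).
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param ext Extension in nt on each side of the center (default 80).
#' @return A context data.frame as in [extract_genomic_context()], with
#'   `space = "transcript"`, `target` = transcript id, `win_start`/`win_end`
#'   in 1-based spliced coordinates and strand `"+"`.
#' @export
extract_transcript_context <- function(sites, assigned, models, genome,
                                       ext = 80L) {
  genome <- as_genome(genome)
  by_tid <- stats::setNames(models,
                            vapply(models, `[[`, "", "transcript_id"))
  centers <- center_site(sites)
  n <- length(centers)
  ids <- if (!is.null(centers$id)) centers$id else paste0("site", seq_len(n))
  seq_cache <- new.env(parent = emptyenv())
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tid <- assigned[i]
    if (is.na(tid) || is.null(by_tid[[tid]])) {
      stop("site ", ids[i], " has no assigned transcript model")
    }
    m <- by_tid[[tid]]
    map <- genome_to_transcript(centers[i], m)
    if (map$status != "mapped") {
      stop("center of site ", ids[i], " is not exonic in ", tid)
    }
    if (is.null(seq_cache[[tid]])) {
      seq_cache[[tid]] <- spliced_sequence(m, genome)
    }
    txseq <- seq_cache[[tid]]
    sl <- nchar(txseq)
    cpos <- map$tx_start
    ws <- max(1L, cpos - ext)
    we <- min(sl, cpos + ext)
    up <- ws - (cpos - ext)
    dn <- (cpos + ext) - we
    rows[[i]] <- new_context(ids[i], "transcript", tid, "+", ws, we,
                             up, dn, cpos - ws + 1L,
                             substr(txseq, ws, we))
  }
  do.call(rbind, rows)
}

#' Write a context set to FASTA
#'
#' Headers encode the site id, space, target coordinates (1-based closed),
#' strand, viewpoint position and truncation bookkeeping, e.g.
#' `>s1 space=transcript;target=t3;win=401-561;strand=+;vp=81;up_trunc=0;dn_trunc=0`.
#'
#' @param contexts A context data.frame from [extract_genomic_context()] or
#'   [extract_transcript_context()].
#' @param path Output FASTA path.
#' @export
write_context_fasta <- function(contexts, path) {
  headers <- sprintf(
    "%s space=%s;target=%s;win=%d-%d;strand=%s;vp=%d;up_trunc=%d;dn_trunc=%d",
    contexts$site_id, contexts$space, contexts$target,
    contexts$win_start, contexts$win_end, contexts$strand,
    contexts$viewpoint, contexts$up_truncated, contexts$dn_truncated)
  out <- character(2L * nrow(contexts))
  out[c(TRUE, FALSE)] <- paste0(">", headers)
  out[c(FALSE, TRUE)] <- contexts$sequence
  writeLines(out, path)
  invisible(path)
}
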