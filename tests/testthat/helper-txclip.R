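suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# Build a GRanges site from BED-style 0-based half-open coordinates, the
# convention most interval examples are naturally written in.
gi <- function(chrom, start0, end0, strand = "+", id = "s1", score = 1,
               pvalue = NULL) {
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand,
                id = id, score = score)
  if (!is.null(pvalue)) gr$pvalue <- pvalue
  names(gr) <- id
  gr
}

# Transcript model from 0-based half-open exon pairs.
tm <- function(exons0, strand = "+", chrom = "chr1", tid = "t1",
               gid = "g1", ...) {
  ex <- IRanges(vapply(exons0, `[`, 0, 1) + 1L, vapply(exons0, `[`, 0, 2))
  transcript_model(tid, gid, chrom, strand, ex, ...)
}

# ---- independent per-base oracles ------------------------------------

# Genomic positions of a model's transcript, 5'->3', by direct enumeration.
oracle_tx_positions <- function(model) {
  ex <- model$exons
  pos <- unlist(lapply(seq_along(ex), function(k) start(ex)[k]:end(ex)[k]))
  if (model$strand == "-") rev(pos) else pos
}

# Brute-force genome->transcript map of the exonic bases of [s, e] (1-based).
oracle_g2t <- function(s, e, model) {
  gp <- oracle_tx_positions(model)
  tx <- which(gp %in% s:e)
  if (length(tx) == 0L) return(NULL)
  list(tx_start = min(tx), tx_end = max(tx), n_exonic = length(tx))
}

# Brute-force exonic fraction of a site against an exon table.
oracle_exonic_fraction <- function(chrom, s, e, strand, exons_gr) {
  n_in <- 0L
  for (p in s:e) {
    hit <- any(as.character(seqnames(exons_gr)) == chrom &
                 start(exons_gr) <= p & end(exons_gr) >= p &
                 (as.character(strand(exons_gr)) == strand |
                    strand == "*" | as.character(strand(exons_gr)) == "*"))
    if (hit) n_in <- n_in + 1L
  }
  n_in / (e - s + 1L)
}

# Brute-force spliced sequence by walking transcript positions one by one.
oracle_spliced_seq <- function(model, genome) {
  chars <- strsplit(as.character(genome[[model$chrom]]), "")[[1]]
  gp <- oracle_tx_positions(model)
  out <- chars[gp]
  if (model$strand == "-") out <- chartr("ACGTN", "TGCAN", out)
  paste(out, collapse = "")
}

# ---- exhaustive motif-scan oracle ------------------------------------

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N"))

oracle_block_at <- function(chars, block, pos) {
  bl <- strsplit(block, "")[[1]]
  if (pos + length(bl) - 1L > length(chars)) return(FALSE)
  for (j in seq_along(bl)) {
    if (!chars[pos + j - 1L] %in% ORACLE_IUPAC[[bl[j]]]) return(FALSE)
  }
  TRUE
}

# All start positions with at least one gap assignment, by full enumeration
# of every gap combination (a start is a hit iff every block matches at the
# offsets that combination implies).
oracle_scan_starts <- function(sequence, motif) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  K <- length(motif$blocks)
  blens <- nchar(motif$blocks)
  bm <- lapply(motif$blocks, function(b) {
    bl <- strsplit(b, "")[[1]]
    if (n < length(bl)) return(logical(0))
    vapply(seq_len(n - length(bl) + 1L), function(p)
      all(mapply(function(ch, q) chars[q] %in% ORACLE_IUPAC[[ch]],
                 bl, p + seq_along(bl) - 1L)), logical(1))
  })
  gap_grid <- if (K == 1L) matrix(0L, 1, 1) else
    as.matrix(expand.grid(lapply(2:K, function(k)
      motif$gap_min[k]:motif$gap_max[k])))
  hit <- rep(FALSE, n)
  for (r in seq_len(nrow(gap_grid))) {
    gaps <- if (K == 1L) integer(0) else as.integer(gap_grid[r, ])
    total <- sum(blens) + sum(gaps)
    if (total > n) next
    np <- n - total + 1L
    ok <- bm[[1L]][seq_len(np)]
    off <- 0L
    if (K > 1L) for (k in 2:K) {
      off <- off + blens[k - 1L] + gaps[k - 1L]
      ok <- ok & bm[[k]][off + seq_len(np)]
    }
    hit[seq_len(np)] <- hit[seq_len(np)] | ok
  }
  which(hit)
}

# Random sequence / model generators (draw from the current RNG stream).
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_model <- function(n_exons = NULL, strand = NULL, tid = "tR") {
  if (is.null(n_exons)) n_exons <- sample(2:5, 1)
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  ws <- sample(30:120, n_exons, replace = TRUE)
  gaps <- sample(20:80, max(1, n_exons - 1), replace = TRUE)[seq_len(n_exons - 1)]
  starts <- 101L + c(0L, cumsum(ws[-n_exons] + gaps))
  transcript_model(tid, "gR", "chrR", strand,
                   IRanges(starts, starts + ws - 1L),
                   appris = "principal1", tsl = 1L, basic = TRUE)
}

# Shared medium fixture for cross-module tests (built once per test run).
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_fixture(
        n_genes = 10,
        n_sites = list(exonic = 8, near_border = 5, pair = 4,
                       intronic = 8, transcript_end = 4),
        motifs = list(list(motif = known_motifs()$PUM2_PRE, n = 4,
                           split = TRUE),
                      list(motif = known_motifs()$IGF2BP3, n = 2,
                           split = TRUE)),
        seed = 20260925L)
    }
    cache
  }
})
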