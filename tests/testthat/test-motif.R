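test_that("motif grammar parses IUPAC strings, gaps and repeats", {
  # PUM2 PRE: RNA alphabet normalised to DNA, single block
  pre <- parse_motif("UGUANAUA")
  expect_length(pre$blocks, 1L)
  expect_equal(pre$blocks, "TGTANATA")
  expect_equal(pre$gap_min, 0L)
  # IGF2BP3 compound motif: 5 blocks with bounded spacers
  igf <- parse_motif("GGC-N{15-25}-CA-N{7-20}-CA-N{15-25}-GGC-N{2-8}-[CA]4")
  expect_equal(igf$blocks, c("GGC", "CA", "CA", "GGC", "CACACACA"))
  expect_equal(igf$gap_min, c(0L, 15L, 7L, 15L, 2L))
  expect_equal(igf$gap_max, c(0L, 25L, 20L, 25L, 8L))
  # plain exact block
  expect_equal(parse_motif("ACGT")$blocks, "ACGT")
  # errors carry the offending position
  expect_error(parse_motif("ACX"), "position")
  expect_error(parse_motif("AC-N{5-2}-GG"), "5 > 2")
  expect_error(parse_motif("N{2-3}AC"), "start with a gap")
  expect_error(parse_motif("AC-N{2-3}"), "ends with a gap")
})

test_that("scanning matches IUPAC codes and respects masked bases", {
  pre <- parse_motif("UGUANAUA", motif_id = "PRE")
  h <- scan_motif("TGTACATA", pre)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(1L, 8L))
  expect_equal(h$matched, "TGTACATA")
  # no match
  expect_equal(nrow(scan_motif("AAAA", parse_motif("ACGT"))), 0L)
  # sequence N matches only motif N
  expect_equal(nrow(scan_motif("TGTANATA", pre)), 1L)  # N at motif-N slot
  expect_equal(nrow(scan_motif("TGTACATN", pre)), 0L)  # N at fixed slot
  # overlapping hits at different starts are all reported
  h2 <- scan_motif("ACACAC", parse_motif("ACA"))
  expect_equal(h2$start, c(1L, 3L))
})

test_that("gapped scanning reports one minimal-gap hit per start", {
  mo <- parse_motif("GG-N{1-3}-CC", motif_id = "gap")
  # both gap 1 and gap 3 assignments exist; minimal total gap is reported
  h <- scan_motif("GGACCACC", mo)
  expect_equal(nrow(h), 1L)
  expect_equal(h$matched, "GGACC")
  # an assignment that only works with the larger gap is still found
  h2 <- scan_motif("GGAAACC", mo)
  expect_equal(h2$matched, "GGAAACC")
})

test_that("scan equals the exhaustive gap-enumeration oracle", {
  set.seed(404)
  alphabet <- c("A", "C", "G", "T")
  iupac <- c(alphabet, "R", "Y", "S", "W", "N")
  for (case in 1:60) {
    n <- sample(100:500, 1)
    seqc <- random_seq(n)
    k <- sample(1:3, 1)
    blocks <- vapply(seq_len(k), function(i)
      paste(sample(iupac, sample(2:4, 1), replace = TRUE), collapse = ""),
      "")
    gmin <- c(0L, sample(0:3, max(0, k - 1), replace = TRUE))[seq_len(k)]
    gmax <- gmin + c(0L, sample(0:3, max(0, k - 1), replace = TRUE))[seq_len(k)]
    spec <- blocks[1]
    if (k > 1) for (i in 2:k) {
      spec <- paste0(spec, "-N{", gmin[i], "-", gmax[i], "}-", blocks[i])
    }
    mo <- parse_motif(spec)
    got <- scan_motif(seqc, mo)$start
    want <- oracle_scan_starts(seqc, mo)
    expect_equal(got, want, info = spec)
  }
})

test_that("hit deduplication is keyed on absolute position and motif", {
  h <- data.frame(
    motif_id = c("m1", "m1", "m2"), site_id = c("s1", "s2", "s1"),
    space = "genomic", target = "chr1", strand = "+",
    start = c(100L, 100L, 100L), end = c(107L, 107L, 107L),
    ctx_start = 1L, ctx_end = 8L, matched = "AAAAAAAA",
    stringsAsFactors = FALSE)
  d <- dedupe_hits(h)
  # same position from two overlapping windows counts once; a different
  # motif at the same position stays
  expect_equal(nrow(d), 2L)
  expect_setequal(d$motif_id, c("m1", "m2"))
  expect_equal(nrow(dedupe_hits(h[0, ])), 0L)
})

test_that("dedup makes counts invariant to context-window tiling", {
  set.seed(505)
  genome <- DNAStringSet(c(chr1 = random_seq(1500)))
  pre <- parse_motif("UGUANAUA", motif_id = "PRE")
  sites <- c(gi("chr1", 700, 701, id = "w0"),
             gi("chr1", 690, 691, id = "wminus"),
             gi("chr1", 710, 711, id = "wplus"))
  ctx_all <- extract_genomic_context(sites, genome, 80)
  # windows shifted by +/-10 nt cover the same central region; any hit
  # there is counted once
  base <- dedupe_hits(scan_contexts(ctx_all[1, , drop = FALSE], pre))
  tiled <- dedupe_hits(scan_contexts(ctx_all, pre))
  central <- tiled[tiled$start >= 700 - 70 & tiled$end <= 701 + 70, ]
  expect_true(all(base$start %in% tiled$start))
  expect_equal(anyDuplicated(paste(tiled$start, tiled$end)), 0L)
  expect_equal(nrow(central),
               length(unique(paste(central$start, central$end))))
})

test_that("transcript hits map to genomic split blocks conserving length", {
  m <- tm(list(c(100, 200), c(300, 400)))
  hit <- data.frame(motif_id = "PRE", site_id = "s1", space = "transcript",
                    target = "t1", strand = "+", start = 96L, end = 103L,
                    ctx_start = 1L, ctx_end = 8L, matched = "TGTACATA",
                    stringsAsFactors = FALSE)
  mg <- map_hit_to_genome(hit, m)
  expect_true(mg$split)
  expect_length(mg$blocks, 2L)
  expect_equal(width(mg$blocks), c(5L, 3L))
  expect_equal(sum(width(mg$blocks)), 8L)
  # fully intra-exon hit is not split
  hit2 <- transform(hit, start = 10L, end = 17L)
  mg2 <- map_hit_to_genome(hit2, m)
  expect_false(mg2$split)
  expect_length(mg2$blocks, 1L)
})

test_that("frequency comparison normalises by context-set length", {
  r <- compare_frequencies(10, 1000, 5, 1000)
  expect_equal(r$percent_change, 100)
  # different set lengths: 0.01 vs 0.005 density
  r2 <- compare_frequencies(5, 500, 10, 2000)
  expect_equal(r2$percent_change, 100)
  expect_equal(compare_frequencies(7, 700, 10, 1000)$percent_change, 0)
  # undefined with zero genomic hits
  r3 <- compare_frequencies(3, 100, 0, 100)
  expect_true(r3$undefined)
  expect_error(compare_frequencies(1, 0, 1, 10), "lengths")
})

test_that("planted junction-split motifs are recovered only in transcript context", {
  fx <- shared_fixture()
  prom <- fx$prominent
  msites <- fx$sites[fx$sites$category == "motif_site"]
  assigned <- assign_sites(msites, prom)
  ctx_t <- extract_transcript_context(msites, assigned, prom, fx$genome, 80)
  ctx_g <- extract_genomic_context(msites, fx$genome, 80)
  motifs <- known_motifs()
  hits_t <- dedupe_hits(scan_contexts(ctx_t, motifs))
  hits_g <- dedupe_hits(scan_contexts(ctx_g, motifs))
  truth <- fx$motif_truth
  # zero false negatives in transcript context
  for (r in seq_len(nrow(truth))) {
    expect_true(any(hits_t$target == truth$transcript_id[r] &
                      hits_t$start == truth$tx_start[r] &
                      hits_t$end == truth$tx_end[r] &
                      hits_t$motif_id == truth$motif_id[r]),
                info = paste("instance", r))
  }
  # genomic context of the same windows contains no full match
  expect_equal(nrow(hits_g), 0L)
  # every planted hit maps back to >= 2 blocks covering the planted bases
  by_tid <- prom
  for (r in seq_len(nrow(truth))) {
    i <- which(hits_t$target == truth$transcript_id[r] &
                 hits_t$start == truth$tx_start[r] &
                 hits_t$end == truth$tx_end[r] &
                 hits_t$motif_id == truth$motif_id[r])[1]
    mg <- map_hit_to_genome(hits_t[i, ], by_tid[[truth$transcript_id[r]]])
    expect_true(mg$split)
    got_bases <- sort(unlist(lapply(seq_along(mg$blocks), function(b)
      start(mg$blocks)[b]:end(mg$blocks)[b])))
    want_bases <- sort(oracle_tx_positions(
      by_tid[[truth$transcript_id[r]]])[truth$tx_start[r]:truth$tx_end[r]])
    expect_equal(got_bases, want_bases)
  }
})
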