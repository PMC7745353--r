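test_that("BED reader/writer round-trips and validates", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\ts1\t2.5\t+", bed)
  s <- read_bed(bed)
  expect_equal(as.character(seqnames(s)), "chr1")
  expect_equal(c(start(s) - 1L, end(s)), c(10L, 20L))
  expect_equal(s$score, 2.5)
  expect_equal(s$id, "s1")
  # empty file -> empty set
  writeLines(character(), bed)
  expect_length(read_bed(bed), 0L)
  # write . read is byte-stable on canonical BED6(+p-value)
  writeLines(c("chr1\t10\t20\ts1\t2.5\t+\t0.001",
               "chr2\t5\t9\ts2\t-1\t-\t0.5"), bed)
  out <- tempfile(fileext = ".bed")
  write_bed(read_bed(bed), out)
  expect_identical(readLines(out), readLines(bed))
  # invalid coordinates error with the line number
  writeLines(c("chr1\t10\t20\ts1\t1\t+", "chr1\t30\t30\ts2\t1\t+"), bed)
  expect_error(read_bed(bed), "line 2")
  writeLines("chr1\tx\t20\ts1\t1\t+", bed)
  expect_error(read_bed(bed), "line 1")
})

test_that("site filtering applies inclusive length/LFC/p-value bounds", {
  sites <- c(gi("chr1", 0, 81, id = "too_long", score = 5, pvalue = 0.001),
             gi("chr1", 100, 180, id = "at_bounds", score = 3, pvalue = 0.01),
             gi("chr1", 300, 320, id = "weak", score = 0.5, pvalue = 0.5))
  thr <- thresholds(min_lfc = 3, max_len = 80, max_pvalue = 0.01)
  expect_equal(filter_sites(sites, thr)$id, "at_bounds")
  # LFC-only filter at the merged-replicate default threshold
  thr1 <- thresholds(min_lfc = 1)
  expect_setequal(filter_sites(sites, thr1)$id, c("too_long", "at_bounds"))
  # all criteria disabled keeps everything
  expect_length(filter_sites(sites, thresholds(min_lfc = -Inf)), 3L)
})

test_that("replicate merging keeps the highest-LFC site per overlap", {
  a <- gi("chr1", 10, 20, id = "a1", score = 2)
  b <- gi("chr1", 15, 25, id = "b1", score = 3)
  m <- merge_replicates(a, b)
  expect_equal(m$id, "b1")
  expect_equal(c(start(m) - 1L, end(m)), c(15L, 25L))  # winner's own span
  # disjoint sites pass through
  m2 <- merge_replicates(gi("chr1", 10, 20, id = "a1", score = 1),
                         gi("chr1", 30, 40, id = "b1", score = 1))
  expect_setequal(m2$id, c("a1", "b1"))
  # transitive chain collapses to the single best site
  chain <- c(gi("chr1", 10, 20, id = "x", score = 1),
             gi("chr1", 18, 28, id = "y", score = 5),
             gi("chr1", 26, 36, id = "z", score = 2))
  m3 <- merge_replicates(chain[1:2], chain[3])
  expect_equal(m3$id, "y")
  # book-ended (gap 0) sites do NOT merge: overlap >= 1 nt required
  m4 <- merge_replicates(gi("chr1", 10, 20, id = "l", score = 1),
                         gi("chr1", 20, 30, id = "r", score = 9))
  expect_length(m4, 2L)
  # opposite strands never merge
  m5 <- merge_replicates(gi("chr1", 10, 20, id = "p", score = 1),
                         gi("chr1", 10, 20, id = "m", score = 9,
                            strand = "-"))
  expect_length(m5, 2L)
})

test_that("nearby-site merging uses a strict gap threshold", {
  # gap 5 < 10 -> merge, winner by LFC
  s <- c(gi("chr1", 10, 20, id = "a", score = 2),
         gi("chr1", 25, 35, id = "b", score = 4))
  expect_equal(merge_nearby(s, 10)$id, "b")
  # gap exactly 10 -> both kept
  s2 <- c(gi("chr1", 10, 20, id = "a", score = 2),
          gi("chr1", 30, 40, id = "b", score = 4))
  expect_length(merge_nearby(s2, 10), 2L)
  # single site unchanged
  expect_equal(merge_nearby(gi("chr1", 5, 9, id = "o"), 10)$id, "o")
})

test_that("merging is idempotent, order-invariant and never alters spans", {
  set.seed(77)
  for (rep in 1:20) {
    n <- 30
    starts <- sample(1:500, n)
    s <- GRanges("chr1", IRanges(starts, width = sample(5:40, n, TRUE)),
                 strand = sample(c("+", "-"), n, TRUE),
                 id = paste0("s", 1:n), score = round(runif(n, 0, 5), 3))
    m1 <- merge_nearby(s, 10)
    # idempotent
    expect_equal(as.data.frame(merge_nearby(m1, 10)), as.data.frame(m1))
    # order invariant
    m2 <- merge_nearby(s[sample(n)], 10)
    expect_equal(as.data.frame(m1), as.data.frame(m2))
    # output is a subset of input with untouched coordinates
    expect_true(all(m1$id %in% s$id))
    expect_equal(start(m1), start(s)[match(m1$id, s$id)])
    expect_lte(length(m1), n)
    # same properties for replicate merging
    r1 <- merge_replicates(s[1:15], s[16:30])
    expect_equal(as.data.frame(merge_replicates(r1, GRanges(id = character(), score = numeric()))),
                 as.data.frame(r1))
  }
})

test_that("exon-overlap classification matches stated fractions", {
  exons <- GRanges("chr1", IRanges(c(101, 301), c(200, 400)), strand = "+")
  # fully inside an exon
  r <- classify_exonic(gi("chr1", 110, 150), exons)
  expect_equal(r$overlap_fraction, 1)
  expect_true(r$exonic)
  # 89 of 100 bases exonic at frac 0.90 -> not exonic
  r2 <- classify_exonic(gi("chr1", 111, 211), exons, frac = 0.90)
  expect_equal(r2$overlap_fraction, 0.89)
  expect_false(r2$exonic)
  # 95/100 spanning two exons of the union (5 nt intron) -> exonic
  exons2 <- GRanges("chr1", IRanges(c(101, 206), c(200, 400)), strand = "+")
  r3 <- classify_exonic(gi("chr1", 150, 250), exons2, frac = 0.90)
  expect_equal(r3$overlap_fraction, 0.95)
  expect_true(r3$exonic)
})

test_that("classification agrees with the per-base membership oracle", {
  fx <- shared_fixture()
  exons <- exon_union(fx$prominent)
  set.seed(303)
  n <- 250
  chroms <- names(fx$genome)
  ch <- sample(chroms, n, replace = TRUE)
  st <- vapply(ch, function(c) sample(length(fx$genome[[c]]) - 60L, 1L), 0L)
  sites <- GRanges(ch, IRanges(st, width = sample(10:50, n, TRUE)),
                   strand = sample(c("+", "-"), n, TRUE),
                   id = paste0("r", 1:n), score = 1)
  got <- classify_exonic(sites, exons, frac = 0.9)
  for (i in seq_len(n)) {
    frac <- oracle_exonic_fraction(ch[i], start(sites)[i], end(sites)[i],
                                   as.character(strand(sites))[i], exons)
    expect_equal(got$overlap_fraction[i], frac, info = paste("site", i))
    expect_equal(got$exonic[i], frac >= 0.9)
  }
})

test_that("border distances are measured to the containing exon's edges", {
  m <- tm(list(c(100, 200), c(300, 400)))
  # site (100,120): flush 5' border, 80 nt to the 3' border
  bd <- border_distance(gi("chr1", 100, 120), m)
  expect_equal(c(bd$dist5, bd$dist3), c(0L, 80L))
  expect_true(min(bd$dist5, bd$dist3) <= 50)
  # interior site: min distance 40 -> near at 50, not at 10
  bd2 <- border_distance(gi("chr1", 140, 160), m)
  expect_equal(min(bd2$dist5, bd2$dist3), 40L)
  expect_false(min(bd2$dist5, bd2$dist3) <= 10)
  # site flush with both borders of a 30 nt exon
  m30 <- tm(list(c(100, 130), c(200, 250)))
  bd3 <- border_distance(gi("chr1", 100, 130), m30)
  expect_equal(c(bd3$dist5, bd3$dist3), c(0L, 0L))
  # minus strand: 5'/3' swap and exon indices reverse
  mneg <- tm(list(c(100, 200), c(300, 400)), strand = "-")
  bd4 <- border_distance(gi("chr1", 100, 120, strand = "-"), mneg)
  expect_equal(c(bd4$dist5, bd4$dist3), c(80L, 0L))
  expect_equal(bd4$exon3, 2L)
  # intronic end errors unless clipped
  expect_error(border_distance(gi("chr1", 190, 210), m), "intron")
  bd5 <- border_distance(gi("chr1", 190, 210), m, clip = TRUE)
  expect_equal(bd5$dist3, 0L)
})

test_that("pair sites require both inner ends < pair_dist at one junction", {
  m <- tm(list(c(100, 200), c(300, 400)))
  models <- list(t1 = m)
  # ends 3 nt from both adjacent borders -> pair
  s <- c(gi("chr1", 180, 197, id = "up", score = 2),
         gi("chr1", 303, 330, id = "dn", score = 3))
  p <- detect_pairs(s, c("t1", "t1"), models, pair_dist = 10)
  expect_equal(nrow(p), 1L)
  expect_setequal(c(p$id1, p$id2), c("up", "dn"))
  expect_equal(c(p$dist1, p$dist2), c(3L, 3L))
  # downstream site 15 nt from the border -> no pair
  s2 <- c(gi("chr1", 180, 197, id = "up", score = 2),
          gi("chr1", 315, 330, id = "dn", score = 3))
  expect_equal(nrow(detect_pairs(s2, c("t1", "t1"), models, 10)), 0L)
  # non-adjacent exon borders never pair
  m3 <- tm(list(c(100, 200), c(300, 400), c(500, 600)))
  s3 <- c(gi("chr1", 195, 199, id = "e1end", score = 1),
          gi("chr1", 500, 520, id = "e3start", score = 1))
  expect_equal(nrow(detect_pairs(s3, c("t1", "t1"), list(t1 = m3), 10)), 0L)
  # each site joins at most one pair: best summed LFC wins
  s4 <- c(gi("chr1", 180, 197, id = "upA", score = 1),
          gi("chr1", 185, 198, id = "upB", score = 5),
          gi("chr1", 303, 330, id = "dn", score = 3))
  p4 <- detect_pairs(s4, c("t1", "t1", "t1"), models, 10)
  expect_equal(nrow(p4), 1L)
  expect_setequal(c(p4$id1, p4$id2), c("upB", "dn"))
})

test_that("detected pairs are a subset of near-border sites", {
  fx <- shared_fixture()
  keep <- !fx$sites$category %in% c("transcript_end", "motif_site")
  sites <- fx$sites[keep]
  exons <- exon_union(fx$prominent)
  cls <- classify_exonic(sites, exons, 0.9)
  exonic <- sites[cls$exonic]
  assigned <- assign_sites(exonic, fx$prominent)
  pairs <- detect_pairs(exonic, assigned, fx$prominent, pair_dist = 10)
  paired_ids <- c(pairs$id1, pairs$id2)
  by_tid <- setNames(fx$prominent,
                     vapply(fx$prominent, `[[`, "", "transcript_id"))
  for (id in paired_ids) {
    i <- which(exonic$id == id)
    bd <- border_distance(exonic[i], by_tid[[assigned[i]]], clip = TRUE)
    expect_lte(min(bd$dist5, bd$dist3), 10)
    # strand-consistent with the model
    expect_equal(as.character(strand(exonic[i])),
                 by_tid[[assigned[i]]]$strand)
  }
})
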