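# Hand-derived fixtures on a 100 Mb chr1 (centromere 45-50 Mb) and an
# 80 Mb chr2; coordinates in Mb via toy_profile().

test_that("LOH counting applies the strict 15 Mb rule", {
  b <- toy_build()
  # interstitial 20 Mb minor_cn = 0 run
  p20 <- toy_profile(list(list("chr1", 0, 10, 2, 1),
                          list("chr1", 10, 30, 2, 0),
                          list("chr1", 30, 100, 2, 1)))
  expect_equal(count_loh(p20, b), 1L)
  # 10 Mb: below threshold
  p10 <- toy_profile(list(list("chr1", 0, 10, 2, 1),
                          list("chr1", 10, 20, 2, 0),
                          list("chr1", 20, 100, 2, 1)))
  expect_equal(count_loh(p10, b), 0L)
  # exactly 15 Mb: "exceeding" is strict; 15 Mb + 1 bp counts
  p15 <- toy_profile(list(list("chr1", 0, 10, 2, 1),
                          list("chr1", 10, 25, 2, 0),
                          list("chr1", 25, 100, 2, 1)))
  expect_equal(count_loh(p15, b), 0L)
  p15plus <- segment_profile("T1", data.frame(
    chrom = "chr1", start = c(0, 10e6, 25e6 + 1), end = c(10e6, 25e6 + 1, 100e6),
    total_cn = c(2, 2, 2), minor_cn = c(1, 0, 1)), build = b)
  expect_equal(count_loh(p15plus, b), 1L)
})

test_that("whole-chromosome LOH is excluded by default, counted on request", {
  b <- toy_build()
  whole <- toy_profile(list(list("chr1", 0, 100, 2, 0)))
  expect_equal(count_loh(whole, b), 0L)
  expect_equal(count_loh(whole, b, count_whole_chrom = TRUE), 1L)
  # abutting minor-0 segments merge before the whole-chromosome test
  split_whole <- toy_profile(list(list("chr1", 0, 60, 2, 0),
                                  list("chr1", 60, 100, 3, 0)))
  expect_equal(count_loh(split_whole, b), 0L)
  expect_equal(count_loh(split_whole, b, count_whole_chrom = TRUE), 1L)
})

test_that("LST counts state changes between long segments, with smoothing", {
  b <- toy_build()
  # adjacent 12 Mb (2,1) and 15 Mb (3,1), zero gap
  pair <- toy_profile(list(list("chr1", 0, 12, 2, 1),
                           list("chr1", 12, 27, 3, 1),
                           list("chr1", 31, 100, 2, 1)))
  expect_equal(count_lst(pair, b), 1L)
  # one segment: no breakpoint
  expect_equal(count_lst(toy_profile(list(list("chr1", 0, 100, 2, 1))), b), 0L)
  # a 2 Mb equal-state artifact interrupting the left flank is smoothed away
  smoothed <- toy_profile(list(list("chr1", 0, 6, 2, 1),
                               list("chr1", 6, 8, 3, 2),
                               list("chr1", 8, 12, 2, 1),
                               list("chr1", 12, 27, 3, 1),
                               list("chr1", 31, 100, 2, 1)))
  expect_equal(count_lst(smoothed, b), 1L)
  # without smoothing the interrupted flank is too short on both sides
  expect_equal(count_lst(smoothed, b, smooth_below = 0), 0L)
  # a 3 Mb gap between the long segments voids the breakpoint (strict < 3 Mb)
  gapped <- toy_profile(list(list("chr1", 0, 12, 2, 1),
                             list("chr1", 15, 30, 3, 1)))
  expect_equal(count_lst(gapped, b), 0L)
  # flank below 10 Mb does not count
  shortflank <- toy_profile(list(list("chr1", 0, 9, 2, 1),
                                 list("chr1", 9, 27, 3, 1)))
  expect_equal(count_lst(shortflank, b), 0L)
})

test_that("TAI requires telomere contact without spanning the chromosome", {
  b <- toy_build()
  # imbalanced (2,0) terminal 30 Mb on chr2 (80 Mb, no centromere)
  tel <- toy_profile(list(list("chr2", 0, 30, 2, 0),
                          list("chr2", 30, 80, 2, 1)))
  expect_equal(count_tai(tel, b), 1L)
  # the same imbalance placed interstitially
  interstitial <- toy_profile(list(list("chr2", 0, 10, 2, 1),
                                   list("chr2", 10, 40, 2, 0),
                                   list("chr2", 40, 80, 2, 1)))
  expect_equal(count_tai(interstitial, b), 0L)
  # fully balanced: nothing
  expect_equal(count_tai(toy_profile(list(list("chr2", 0, 80, 2, 1))), b), 0L)
  # whole-chromosome imbalance is not telomeric AI
  expect_equal(count_tai(toy_profile(list(list("chr2", 0, 80, 3, 1))), b), 0L)
  # crossing the centromere (chr1 45-50 Mb) disqualifies
  crossing <- toy_profile(list(list("chr1", 0, 60, 3, 1),
                               list("chr1", 60, 100, 2, 1)))
  expect_equal(count_tai(crossing, b), 0L)
  # confined to the p-arm it counts
  parm <- toy_profile(list(list("chr1", 0, 40, 3, 1),
                           list("chr1", 40, 100, 2, 1)))
  expect_equal(count_tai(parm, b), 1L)
})

test_that("scar score sums the three counters and is per-chromosome additive", {
  b <- toy_build()
  balanced <- toy_profile(list(list("chr1", 0, 100, 2, 1),
                               list("chr2", 0, 80, 2, 1)))
  r <- scar_score(balanced, b)
  expect_equal(c(r$loh, r$lst, r$tai, r$scar_total), c(0L, 0L, 0L, 0L))

  on1 <- toy_profile(list(list("chr1", 0, 10, 2, 1),
                          list("chr1", 10, 30, 2, 0),
                          list("chr1", 30, 100, 2, 1)))
  on2 <- toy_profile(list(list("chr2", 0, 30, 2, 0),
                          list("chr2", 30, 80, 2, 1)))
  both <- segment_profile("T1", rbind(on1$segments, on2$segments), build = b)
  r1 <- scar_score(on1, b); r2 <- scar_score(on2, b); rb <- scar_score(both, b)
  expect_equal(rb$scar_total, r1$scar_total + r2$scar_total)
  expect_equal(rb$scar_total, rb$loh + rb$lst + rb$tai)

  # permuting segment row order never changes counts
  perm <- segment_profile("T1", both$segments[sample(nrow(both$segments)), ],
                          build = b)
  expect_equal(scar_score(perm, b)$scar_total, rb$scar_total)
})

test_that("sex chromosomes are excluded by default", {
  b <- genome_build(c(chr1 = 100e6, chrX = 150e6))
  p <- toy_profile(list(list("chrX", 0, 30, 2, 0),
                        list("chrX", 30, 150, 2, 1)), build = b)
  expect_equal(count_loh(p, b), 0L)
  expect_equal(count_loh(p, b, include_sex = TRUE), 1L)
  bad <- toy_profile(list(list("chr2", 0, 10, 2, 1)), build = toy_build())
  expect_error(count_loh(bad, b), "absent from build")
})

test_that("adding a planted event increments exactly its own counter", {
  build <- grch38_autosomes()
  base <- scar_score(simulate_segments("A", build, 1, 1, 1, seed = 5), build)
  plus_loh <- scar_score(simulate_segments("A", build, 2, 1, 1, seed = 5), build)
  plus_lst <- scar_score(simulate_segments("A", build, 1, 2, 1, seed = 5), build)
  plus_tai <- scar_score(simulate_segments("A", build, 1, 1, 2, seed = 5), build)
  expect_equal(c(plus_loh$loh, plus_loh$lst, plus_loh$tai),
               c(base$loh + 1L, base$lst, base$tai))
  expect_equal(c(plus_lst$loh, plus_lst$lst, plus_lst$tai),
               c(base$loh, base$lst + 1L, base$tai))
  expect_equal(c(plus_tai$loh, plus_tai$lst, plus_tai$tai),
               c(base$loh, base$lst, base$tai + 1L))
})
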