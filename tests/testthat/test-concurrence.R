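test_that("read dissection follows the M/U/C fragment rules", {
  fr <- dissect_read(c(100L, 110L, 120L, 130L), c(1L, 0L, 1L, 1L))
  expect_equal(fr$label, c("M", "C", "M"))
  expect_equal(fr$n_cpgs, c(1L, 1L, 2L))

  fr <- dissect_read(c(1L, 2L, 3L, 4L), c(0L, 0L, 0L, 0L))
  expect_equal(fr$label, "U")
  expect_equal(fr$n_cpgs, 4L)

  fr <- dissect_read(c(1L, 2L, 3L, 4L), c(1L, 1L, 1L, 1L))
  expect_equal(fr$label, "M")

  # missing calls are skipped without breaking runs of equal state
  fr <- dissect_read(c(100L, 110L, 120L, 130L), c(1L, NA, 1L, 0L))
  expect_equal(fr$label, c("M", "C"))
  expect_equal(fr$n_cpgs, c(2L, 1L))
  expect_equal(fr$positions[[1]], c(100L, 120L))

  expect_error(dissect_read(c(1L, 2L), c(NA_integer_, NA_integer_)),
               "all calls missing")
})

test_that("dissection with missing calls equals dissection of the compacted read", {
  set.seed(41)
  for (i in 1:50) {
    k <- sample(3:8, 1)
    calls <- sample(c(0L, 1L, NA), k, replace = TRUE,
                    prob = c(0.4, 0.4, 0.2))
    if (all(is.na(calls))) calls[1] <- 1L
    pos <- cumsum(sample(1:20, k)) + 100L
    keep <- !is.na(calls)
    expect_equal(dissect_read(pos, calls)[c("label", "n_cpgs")],
                 dissect_read(pos[keep], calls[keep])[c("label", "n_cpgs")])
  }
})

test_that("region concurrence matches hand-enumerated fixtures", {
  r <- shared_reads(c("1111", "0000", "1011"))
  # one C-labeled CpG among 12 observations
  expect_equal(concurrence_ratio(r, coverage_min = 1L), 1 / 12)
  expect_equal(mean_methylation(r, coverage_min = 1L), 7 / 12)
  expect_equal(chalm(r, coverage_min = 1L), 2 / 3)
  # concordant-only libraries have zero concurrence at any mean level
  expect_equal(concurrence_ratio(shared_reads(c("0000", "0000")),
                                 coverage_min = 1L), 0)
  expect_equal(concurrence_ratio(shared_reads(c("1111", "1111")),
                                 coverage_min = 1L), 0)
  expect_equal(concurrence_ratio(shared_reads(rep(c("1111", "0000"), 3)),
                                 coverage_min = 1L), 0)
})

test_that("fragment labels come from the full read, weights from in-region CpGs", {
  # read 1100 spans the region boundary: only its two unmethylated CpGs
  # (a C fragment, because the full read is mixed) fall inside
  r <- shared_reads(c("1100", "1111", "1111", "0011"),
                    positions = c(100L, 110L, 120L, 130L))
  region <- single_region("chr1", 115, 135)
  # in-region observations: r1 contributes C,C; r2/r3 M,M; r4 M,M
  expect_equal(concurrence_ratio(r, region, coverage_min = 1L), 2 / 8)
  # unweighted: clipped fragments count once each (C, M, M, M)
  expect_equal(concurrence_ratio(r, region, weighted = FALSE,
                                 coverage_min = 1L), 1 / 4)
})

test_that("per-CpG coverage filter drops CpGs below four reads", {
  # 4 reads at positions 100-130, a 5th read extends to 140 (coverage 1)
  r <- epireads("chr1", sprintf("r%d", 1:5),
                c(rep(list(c(100L, 110L, 120L, 130L)), 4),
                  list(c(130L, 140L))),
                list(c(1L, 0L, 1L, 1L), c(1L, 1L, 1L, 1L),
                     c(0L, 0L, 0L, 0L), c(1L, 0L, 1L, 0L),
                     c(1L, 0L)))
  track <- concurrence_track(r, coverage_min = 4L)
  expect_false(140L %in% track$pos)   # coverage 1 < 4
  expect_true(all(c(100L, 110L, 120L, 130L) %in% track$pos))
  # labels at 110: C (r1), M (r2), U (r3), C (r4) -> 2 of 4
  expect_equal(track$value[track$pos == 110L], 2 / 4)
  # all-U column: zero concurrence, not missing
  ru <- shared_reads(rep("0000", 4))
  expect_equal(unique(concurrence_track(ru)$value), 0)
  # no qualifying CpG -> missing, not zero
  expect_true(is.na(concurrence_ratio(shared_reads("1010"),
                                      coverage_min = 4L)))
})

test_that("region_metrics strict mode drops regions with undercovered CpGs", {
  r <- epireads("chr1", sprintf("r%d", 1:5),
                c(rep(list(c(100L, 110L, 120L, 130L)), 4),
                  list(c(130L, 140L))),
                list(c(1L, 0L, 1L, 1L), c(1L, 1L, 1L, 1L),
                     c(0L, 0L, 0L, 0L), c(1L, 0L, 1L, 0L),
                     c(1L, 0L)))
  regions <- genomic_intervals("chr1", c(95L, 95L), c(150L, 135L),
                               name = c("with_low", "all_covered"))
  strict <- region_metrics(r, regions, mode = "strict")
  expect_true(is.na(strict$concurrence[1]))   # CpG 140 has coverage 1
  expect_false(is.na(strict$concurrence[2]))
  lenient <- region_metrics(r, regions, mode = "lenient")
  # lenient drops only the failing CpG, so both regions are computed and
  # agree (CpG 140 is the only difference)
  expect_equal(lenient$concurrence[1], lenient$concurrence[2])
  expect_equal(attr(strict, "coverage_mode"), "strict")
  # weighted concurrence equals the C-label proportion
  expect_equal(strict$concurrence[2],
               oracle_concurrence(r, regions[2, ], coverage_min = 4L))
})

test_that("Eq.-1 fragment sums, per-CpG counting and the loop oracle agree exactly", {
  set.seed(7)
  for (i in 1:60) {
    r <- random_readset(sample(2:8, 1))
    expect_identical(concurrence_ratio(r, coverage_min = 1L),
                     fragment_sum_concurrence(r, coverage_min = 1L))
    expect_identical(concurrence_ratio(r, coverage_min = 1L),
                     oracle_concurrence(r, coverage_min = 1L))
    expect_identical(concurrence_ratio(r, coverage_min = 2L),
                     oracle_concurrence(r, coverage_min = 2L))
  }
})

test_that("concurrence is bounded in [0, 1) with max (k-1)/k for single reads", {
  for (k in 2:6) {
    vals <- vapply(0:(2^k - 1), function(code) {
      calls <- as.integer(intToBits(code))[1:k]
      r <- epireads("chr1", "r", list(seq(100L, by = 10L,
                                          length.out = k)), list(calls))
      concurrence_ratio(r, coverage_min = 1L)
    }, numeric(1))
    expect_true(all(vals >= 0 & vals < 1))
    expect_equal(max(vals), (k - 1) / k)
  }
})

test_that("chalm equals mean methylation when every read covers one CpG", {
  set.seed(9)
  pos <- seq(100L, by = 10L, length.out = 12L)
  r <- epireads("chr1", sprintf("r%d", 1:60),
                lapply(sample(pos, 60, replace = TRUE), identity),
                lapply(sample(0:1, 60, replace = TRUE), as.integer))
  expect_equal(chalm(r, coverage_min = 1L),
               mean_methylation(r, coverage_min = 1L))
})
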