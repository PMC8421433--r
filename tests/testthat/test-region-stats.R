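test_that("binned matrix covers TSS-2kb..TSS+10kb in 120 strand-oriented bins", {
  # one CpG at TSS+150 (bin 22 on the plus strand) with 3/4 methylation
  track <- data.frame(chrom = "chr1", pos = 5150L, n_reads = 4L,
                      n_meth = 3L)
  genes <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(5000L, 5000L),
                      tts = c(9000L, 1000L), stringsAsFactors = FALSE)
  m <- binned_matrix(track, genes)
  expect_equal(dim(m), c(2L, 120L))
  expect_equal(unname(m["plus", 22]), 0.75)
  expect_true(all(is.na(m["plus", -22])))
  # minus strand: TSS+150 lies 150 bp UPstream of transcription -> bin 19
  expect_equal(unname(m["minus", 19]), 0.75)
  expect_true(all(is.na(m["minus", -19])))
  # bins pool coverage-weighted methylation over their CpGs
  tr2 <- data.frame(chrom = "chr1", pos = c(5110L, 5190L),
                    n_reads = c(4L, 12L), n_meth = c(0L, 12L))
  m2 <- binned_matrix(tr2, genes[1, ])
  expect_equal(unname(m2[1, 22]), 12 / 16)
})

test_that("per-bin rank correlation handles perfect, reversed and constant bins", {
  n <- 30
  m <- matrix(NA_real_, n, 120, dimnames = list(paste0("g", 1:n), NULL))
  expr <- stats::setNames(seq_len(n) + 0.5, paste0("g", 1:n))
  m[, 1] <- seq_len(n)            # identical ranks
  m[, 2] <- rev(seq_len(n))       # reversed ranks
  m[, 3] <- 1                     # constant -> undefined
  m[1:5, 4] <- 1:5                # below the gene floor
  rho <- per_bin_correlation(m, expr, min_genes = 10L)
  expect_equal(rho[1], 1)
  expect_equal(rho[2], -1)
  expect_true(is.na(rho[3]))
  expect_true(is.na(rho[4]))
  expect_equal(length(rho), 120L)
})

test_that("CPK counts midpoint hits per kilobase and is split-invariant", {
  regions <- genomic_intervals("chr1", c(1000L, 3000L), c(2000L, 4000L))
  hits <- genomic_intervals("chr1",
                            c(1100L, 1500L, 1900L, 3100L, 3500L, 5000L),
                            c(1110L, 1510L, 1910L, 3110L, 3510L, 5010L))
  expect_equal(cpk(hits, regions), 5 / 2)
  expect_equal(cpk(hits[0, ], regions), 0)
  expect_error(cpk(hits, regions[0, ]), "zero-length")
  # splitting a region into abutting halves leaves CPK unchanged
  halves <- genomic_intervals("chr1", c(1000L, 1500L, 3000L, 3500L),
                              c(1500L, 2000L, 3500L, 4000L))
  expect_equal(cpk(hits, halves), cpk(hits, regions))
  # a hit straddling an internal border is counted once, by its midpoint
  border <- genomic_intervals("chr1", 1480L, 1520L)
  expect_equal(cpk(border, halves), cpk(border, regions))
  expect_equal(cpk(border, halves) * 2, 1)
})

test_that("motif fold enrichment recovers a planted density contrast", {
  set.seed(77)
  acny <- genomic_intervals("chr1", 0L, 50000L)
  pcny <- genomic_intervals("chr1", 100000L, 150000L)
  mk <- function(n_a, n_p) {
    s <- c(sample(0:49990, n_a), sample(100000:149990, n_p))
    genomic_intervals("chr1", s, s + 10L)
  }
  # methyl-minus motifs planted 2x denser in aCanyons, methyl-plus the
  # reverse
  hits <- list(minus1 = mk(80, 40), minus2 = mk(60, 30),
               plus1 = mk(40, 80), plus2 = mk(30, 60))
  prefs <- c(minus1 = -1.2, minus2 = -0.4, plus1 = 0.8, plus2 = 1.5)
  res <- motif_fold_enrichment(hits, acny, pcny, prefs)
  expect_equal(res$table$class,
               c("methyl-minus", "methyl-minus", "methyl-plus",
                 "methyl-plus"))
  expect_true(all(res$table$log2_fold[1:2] > 0))
  expect_true(all(res$table$log2_fold[3:4] < 0))
  expect_lt(res$correlation$rho, 0)
  expect_equal(res$table$log2_fold[1], log2((80 / 50) / (40 / 50)))
  # zero CPK triggers the flagged pseudocount
  z <- motif_fold_enrichment(list(m = mk(10, 0)), acny, pcny,
                             c(m = 0.5))
  expect_true(z$table$pseudocount)
  expect_true(is.finite(z$table$log2_fold))
})

test_that("TF occupancy ratio is the ratio of occupied-canyon fractions", {
  ac <- genomic_intervals("chr1", c(0L, 1000L, 2000L, 3000L),
                          c(500L, 1500L, 2500L, 3500L))
  pc <- genomic_intervals("chr1", c(10000L, 11000L, 12000L, 13000L),
                          c(10500L, 11500L, 12500L, 13500L))
  peaks <- genomic_intervals("chr1", c(100L, 1100L, 10100L),
                             c(110L, 1110L, 10110L))
  expect_equal(tf_odds_ratio(peaks, ac, pc), (2 / 4) / (1 / 4))
  expect_equal(tf_odds_ratio(peaks, ac, ac), 1)
  nopeak <- genomic_intervals("chr1", 100L, 110L)
  expect_equal(tf_odds_ratio(nopeak, ac, pc), Inf)
})

test_that("interaction labels partition anchor pairs", {
  regions <- genomic_intervals("chr1", c(1000L, 5000L), c(2000L, 6000L),
                               name = c("X", "Y"))
  pairs <- list(
    anchor1 = genomic_intervals("chr1", c(1100L, 1100L, 1100L, 8000L),
                                c(1200L, 1200L, 1200L, 8100L)),
    anchor2 = genomic_intervals("chr1", c(1800L, 5500L, 8000L, 9000L),
                                c(1900L, 5600L, 8100L, 9100L)))
  lab <- classify_interactions(pairs, regions)
  expect_equal(lab, c("self-interacting",    # both in X
                      "distant-interacting", # X and Y: different regions
                      "distant-interacting", # only one anchor in a region
                      "none"))
  # idempotent relabeling
  expect_equal(classify_interactions(pairs, regions), lab)
})

test_that("shuffled controls preserve lengths, stay disjoint and are seeded", {
  regions <- genomic_intervals("chr1", c(0L, 10000L, 30000L),
                               c(4000L, 15000L, 36000L))
  sizes <- c(chr1 = 1e6, chr2 = 1e6)
  s1 <- shuffle_regions(regions, sizes, seed = 4L)
  s2 <- shuffle_regions(regions, sizes, seed = 4L)
  expect_identical(s1, s2)
  expect_equal(sort(s1$end - s1$start),
               sort(regions$end - regions$start))
  expect_equal(nrow(overlap_pairs(s1, s1)), 3L)
})

test_that("occupancy on shuffled controls hovers near parity for random peaks", {
  set.seed(55)
  sizes <- c(chr1 = 2e6)
  regions <- genomic_intervals("chr1", seq(0L, by = 20000L,
                                           length.out = 50L),
                               seq(5000L, by = 20000L,
                                   length.out = 50L))
  ors <- replicate(20, {
    starts <- sample.int(2e6 - 100L, 400L)
    peaks <- genomic_intervals("chr1", starts, starts + 100L)
    a <- shuffle_regions(regions, sizes)
    b <- shuffle_regions(regions, sizes)
    tf_odds_ratio(peaks, a, b)
  })
  expect_lt(abs(mean(ors) - 1), 0.25)
})
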