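# Minimum-count qualification, hypergeometric subsampling, min_found.

test_that("samples qualify at a locus iff depth reaches min_count", {
  samples <- c("S1", "S2", "S3")
  loci <- make_loci(list(matrix(c(8L, 5L, 6L, 4L, 4L, 4L), 3)),
                    list(c("A", "G")), samples)
  q <- qualify_samples(loci, min_count = 10)
  expect_equal(q$depth, c(12L, 9L, 10L))
  expect_equal(q$qualifies, c(TRUE, FALSE, TRUE))

  zero <- make_loci(list(matrix(0L, 3, 2)), list(c("A", "G")), samples)
  expect_false(any(qualify_samples(zero, min_count = 10)$qualifies))
  expect_false(any(qualify_samples(zero, min_count = 1)$qualifies))
  one <- make_loci(list(matrix(c(1L, 0L, 0L, 0L, 0L, 0L), 3)),
                   list(c("A", "G")), samples)
  expect_equal(qualify_samples(one, min_count = 1)$qualifies,
               c(TRUE, FALSE, FALSE))
})

test_that("subsample_counts is an exact multivariate hypergeometric draw", {
  expect_equal(subsample_counts(c(20L, 0L), 10), c(10L, 0L))
  expect_equal(subsample_counts(c(10L, 0L, 0L), 10), c(10L, 0L, 0L))
  expect_equal(subsample_counts(c(4L, 6L), 10), c(4L, 6L))  # at target
  expect_error(subsample_counts(c(4L, 3L), 10), "Cannot subsample")

  set.seed(11)
  draws <- t(replicate(20000, subsample_counts(c(10L, 10L), 10)))
  expect_true(all(rowSums(draws) == 10))
  expect_true(all(draws >= 0 & draws <= 10))
  # hypergeometric expectation: mean of first entry = 10 * 10/20 = 5
  se <- sqrt(10 * 0.5 * 0.5 * (10 / 19) / 20000)
  expect_lt(abs(mean(draws[, 1]) - 5), max(4 * se, 0.05))
})

test_that("subsampling preserves expected allele frequencies", {
  set.seed(3)
  counts <- c(23L, 11L, 6L)
  draws <- t(replicate(5000, subsample_counts(counts, 10)))
  f_obs <- colMeans(draws) / 10
  f_true <- counts / sum(counts)
  se <- sqrt(f_true * (1 - f_true) / 10 / 5000)  # conservative (binomial) SE
  expect_true(all(abs(f_obs - f_true) < 3 * pmax(se, 1e-3)))
})

test_that("min_found removes loci seen in too few qualifying samples", {
  samples <- c("S1", "S2", "S3")
  loci <- make_loci(
    list(matrix(c(12L, 11L, 0L, 2L, 3L, 0L), 3),   # qualifies in 2 samples
         matrix(c(3L, 2L, 1L, 0L, 0L, 0L), 3),     # qualifies in none
         matrix(c(14L, 0L, 0L, 1L, 0L, 0L), 3)),   # qualifies in 1 sample
    list(c("A", "G"), c("A", "T"), c("A", "C")), samples)
  f1 <- filter_loci(loci, min_count = 10, subsample = 0, min_found = 1)
  expect_setequal(unique(f1$locus_id), c(1L, 3L))
  expect_equal(attr(f1, "provenance")$loci_dropped_min_found, 1L)

  f_all <- filter_loci(loci, min_count = 10, subsample = 0,
                       min_found = length(samples))
  expect_equal(nrow(f_all), 0)

  empty <- loci[0, ]
  attr(empty, "samples") <- samples
  expect_equal(nrow(filter_loci(empty, min_found = 1)), 0)
})

test_that("filtered counts sum exactly to the subsample target", {
  set.seed(21)
  samples <- sprintf("S%d", 1:4)
  counts_list <- replicate(30, matrix(sample(0:30, 8, TRUE), 4),
                           simplify = FALSE)
  alleles_list <- replicate(30, c("A", "G"), simplify = FALSE)
  loci <- make_loci(counts_list, alleles_list, samples)
  f <- filter_loci(loci, min_count = 10, subsample = 10, min_found = 1,
                   seed = 99)
  sums <- f %>%
    dplyr::group_by(locus_id, sample) %>%
    dplyr::summarise(n = sum(count), .groups = "drop")
  expect_true(all(sums$n == 10))
  # per-entry bound: subsampled counts never exceed originals
  joined <- dplyr::inner_join(
    f, loci, by = c("locus_id", "contig", "pos", "allele", "sample"),
    suffix = c("_sub", "_orig"))
  expect_true(all(joined$count_sub <= joined$count_orig))
})

test_that("filtering is idempotent and monotone in its thresholds", {
  set.seed(5)
  samples <- sprintf("S%d", 1:3)
  counts_list <- replicate(40, matrix(sample(0:25, 6, TRUE), 3),
                           simplify = FALSE)
  alleles_list <- replicate(40, c("A", "G"), simplify = FALSE)
  loci <- make_loci(counts_list, alleles_list, samples)

  f1 <- filter_loci(loci, min_count = 10, subsample = 10, min_found = 1,
                    seed = 1)
  f2 <- filter_loci(f1, min_count = 10, subsample = 10, min_found = 1,
                    seed = 1)
  expect_equal(as.data.frame(f2), as.data.frame(f1), ignore_attr = TRUE)

  n_loci <- function(x) dplyr::n_distinct(x$locus_id)
  for (mc in c(1, 5, 10, 20)) {
    expect_gte(n_loci(filter_loci(loci, min_count = mc, subsample = 0)),
               n_loci(filter_loci(loci, min_count = mc + 5, subsample = 0)))
  }
  for (mf in 1:3) {
    expect_gte(
      n_loci(filter_loci(loci, min_count = 10, subsample = 0,
                         min_found = mf)),
      n_loci(filter_loci(loci, min_count = 10, subsample = 0,
                         min_found = mf + 1)))
  }

  expect_error(filter_loci(loci, min_count = 10, subsample = 20),
               "must not exceed")
})
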