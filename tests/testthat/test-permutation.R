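# Locus-shuffling permutation test for gene-wise differentiation.

test_that("the p-value formula counts ties and caps at 1", {
  expect_equal(permutation_p(0.74, rep(0.1, 10000)), 1e-4)
  expect_equal(permutation_p(0.2, rep(0.9, 10000)), 1.0)     # capped
  expect_equal(permutation_p(0.5, 0.5, n_perm = 1), 1.0)     # tie counts
  expect_equal(permutation_p(0.5, c(0.5, 0.4, 0.6), n_perm = 3), 1.0)
  # undefined permuted values: >= only when actual is <= 0
  expect_equal(permutation_p(0.3, c(NA, 0.1, 0.1), n_perm = 3), 1 / 3)
  expect_equal(permutation_p(0, c(NA, -0.1), n_perm = 2), 1.0)
  expect_true(is.na(permutation_p(NA, c(0.1, 0.2))))
})

test_that("shuffling preserves per-gene locus counts", {
  set.seed(17)
  samples <- c("S1", "S2")
  n_loci <- 30
  loci <- make_loci(replicate(n_loci, matrix(10L, 2, 2) - c(0L, 0L, 10L, 10L),
                              simplify = FALSE),
                    replicate(n_loci, c("A", "G"), simplify = FALSE),
                    samples, pos = seq(5L, by = 10L, length.out = n_loci))
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"), contig = "c1",
    start = c(1L, 101L, 200L), end = c(50L, 160L, 220L),
    strand = "+", phase = 0L)
  orig <- poolpg:::loci_in_genes(dplyr::distinct(loci, locus_id, contig, pos),
                                 genes) %>%
    dplyr::count(gene_id)
  for (i in 1:5) {
    sh <- shuffle_loci(loci, genes)
    got <- dplyr::count(sh, gene_id)
    expect_equal(got$n[match(orig$gene_id, got$gene_id)], orig$n)
    expect_true(all(sh$locus_id %in% loci$locus_id))
    # gC covers no locus positions (loci at 5,15,...,295; 200-220 -> 205,215)
  }
  zero_gene <- tibble::tibble(gene_id = "gZ", contig = "c1", start = 2L,
                              end = 3L, strand = "+", phase = 0L)
  expect_equal(nrow(shuffle_loci(loci, zero_gene)), 0)
})

test_that("a gene holding every locus always matches its own permutations", {
  samples <- c("S1", "S2")
  counts <- replicate(8, rbind(c(8L, 2L), c(2L, 8L)), simplify = FALSE)
  f <- make_filtered(counts, replicate(8, c("A", "G"), simplify = FALSE),
                     samples)
  genes <- tibble::tibble(gene_id = "g1", contig = "c1", start = 1L,
                          end = 100L, strand = "+", phase = 0L)
  res <- fst_permutation(f, genes, samples, n_perm = 50, seed = 2)
  expect_equal(res$actual_fst, 0.36)
  expect_equal(res$n_ge, 50L)      # every permutation ties the actual value
  expect_equal(res$p_value, 1.0)
})

test_that("identical allele contrasts at every locus give p = 1 for all genes", {
  samples <- c("S1", "S2")
  counts <- replicate(20, rbind(c(9L, 1L), c(3L, 7L)), simplify = FALSE)
  f <- make_filtered(counts, replicate(20, c("A", "G"), simplify = FALSE),
                     samples)
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), contig = "c1", start = c(1L, 101L),
    end = c(100L, 201L), strand = "+", phase = 0L)
  res <- fst_permutation(f, genes, samples, n_perm = 200, seed = 4)
  expect_equal(res$p_value, c(1, 1))
})

test_that("the same seed reproduces every exceedance count exactly", {
  set.seed(19)
  samples <- c("S1", "S2")
  counts <- replicate(40, rbind(as.integer(rmultinom(1, 10, c(.6, .4))),
                                as.integer(rmultinom(1, 10, c(.4, .6)))),
                      simplify = FALSE)
  f <- make_filtered(counts, replicate(40, c("A", "G"), simplify = FALSE),
                     samples)
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:4), contig = "c1",
    start = c(1L, 101L, 201L, 301L), end = c(100L, 200L, 300L, 400L),
    strand = "+", phase = 0L)
  r1 <- fst_permutation(f, genes, samples, n_perm = 300, seed = 77)
  r2 <- fst_permutation(f, genes, samples, n_perm = 300, seed = 77)
  expect_identical(r1$n_ge, r2$n_ge)
  expect_identical(r1$p_value, r2$p_value)
  # q-values are the BH adjustment of the p-values
  expect_equal(r1$q_value, stats::p.adjust(r1$p_value, "BH"))
})

test_that("genes carrying injected high-contrast loci rank first", {
  sim <- simulate_genome(genome_length = 30000, n_genes = 20,
                         gene_length = 900, seed = 55)
  dat <- simulate_allele_counts(
    sim, n_samples = 2, n_populations = 2, target_fst = 0.05,
    snv_density = 0.01, depth = 10,
    signal_genes = c("gene_004", "gene_011"), signal_loci = 6, seed = 56)
  f <- filter_loci(dat$loci, min_count = 10, subsample = 10, seed = 57)
  res <- fst_permutation(f, sim$genes, dat$samples, n_perm = 400, seed = 58)
  ranked <- dplyr::arrange(dplyr::filter(res, !is.na(p_value)), p_value)
  expect_setequal(ranked$gene_id[1:2], c("gene_004", "gene_011"))
  expect_equal(dplyr::filter(res, gene_id == "gene_004")$actual_fst, 1.0)
})
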