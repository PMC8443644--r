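# Codon mapping, amino-acid frequencies, Nei-Gojobori sites, pN/pS.

# 300 bp fixture contig: a + strand gene at 1-12 (M E K F), filler, and a
# - strand gene at 289-300 whose coding sequence is also M E K F.
fixture_genome <- function() {
  g <- paste0("ATGGAAAAATTT", strrep("C", 276), "AAATTTTTCCAT")
  stats::setNames(g, "c1")
}

fixture_genes <- function() {
  tibble::tibble(
    gene_id = c("g_plus", "g_minus"), contig = "c1",
    start = c(1L, 289L), end = c(12L, 300L),
    strand = c("+", "-"), phase = 0L)
}

test_that("loci map to codons with correct index, position and translation", {
  samples <- c("S1", "S2")
  loci <- make_loci(
    list(matrix(c(7L, 5L, 3L, 5L), 2),    # pos 6: GAA 3rd base, A->G (syn)
         matrix(c(7L, 5L, 3L, 5L), 2),    # pos 7: AAA 1st base, A->G (K->E)
         matrix(c(7L, 5L, 3L, 5L), 2)),   # pos 300 (- strand): T->C = A->G
    list(c("A", "G"), c("A", "G"), c("T", "C")), samples,
    pos = c(6L, 7L, 300L))
  cv <- map_loci_to_codons(filter_loci(loci, min_count = 1, subsample = 0),
                           fixture_genes(), fixture_genome())

  at <- function(p) dplyr::filter(cv, pos == p, sample == "S1")
  expect_equal(unique(at(6)$codon_index), 2L)
  expect_equal(unique(at(6)$codon_pos), 3L)
  expect_equal(unique(at(6)$ref_codon), "GAA")
  expect_equal(sort(at(6)$aa), c("E", "E"))       # synonymous pair

  expect_equal(unique(at(7)$codon_index), 3L)
  expect_equal(unique(at(7)$codon_pos), 1L)
  expect_equal(at(7)$aa[match(c("A", "G"), at(7)$allele)], c("K", "E"))

  # minus strand: genomic pos 300 is codon 1 position 1, complemented
  expect_equal(unique(at(300)$codon_index), 1L)
  expect_equal(unique(at(300)$codon_pos), 1L)
  expect_equal(unique(at(300)$gene_id), "g_minus")
  expect_equal(sort(unique(at(300)$allele)), c("A", "G"))
  expect_equal(at(300)$aa[match("A", at(300)$allele)], "M")

  # both fixture genes translate to MEKF via an independent route
  for (i in 1:2) {
    gg <- fixture_genes()[i, ]
    cds <- Biostrings::DNAString(substring(fixture_genome()[["c1"]],
                                           gg$start, gg$end))
    if (gg$strand == "-") cds <- Biostrings::reverseComplement(cds)
    expect_equal(as.character(Biostrings::translate(cds)), "MEKF")
  }
})

test_that("loci in partial codons or the phase leader are excluded", {
  samples <- "S1"
  genes <- tibble::tibble(gene_id = "g", contig = "c1", start = 1L,
                          end = 11L, strand = "+", phase = 1L)
  # positions 1 (phase leader), 11 (trailing partial codon), 5 (codon 2)
  loci <- make_loci(
    list(matrix(c(6L, 4L), 1), matrix(c(6L, 4L), 1), matrix(c(6L, 4L), 1)),
    list(c("A", "G"), c("T", "C"), c("A", "G")), samples,
    pos = c(1L, 11L, 5L))
  cv <- map_loci_to_codons(filter_loci(loci, min_count = 1, subsample = 0),
                           genes, fixture_genome())
  expect_equal(unique(cv$pos), 5L)
  expect_equal(attr(cv, "n_excluded_partial"), 2L)
})

test_that("amino-acid frequencies collapse synonymous alleles and sum to 1", {
  samples <- c("S1", "S2")
  loci <- make_loci(
    list(matrix(c(7L, 5L, 3L, 5L), 2),    # AAA pos 1 -> K 0.7 / E 0.3 in S1
         matrix(c(7L, 10L, 3L, 0L), 2)),  # GAA pos 3, syn -> E 1.0
    list(c("A", "G"), c("A", "G")), samples, pos = c(7L, 6L))
  cv <- map_loci_to_codons(filter_loci(loci, min_count = 1, subsample = 0),
                           fixture_genes(), fixture_genome())
  af <- aa_frequencies(cv)

  k1 <- dplyr::filter(af, codon_index == 3, sample == "S1")
  expect_equal(k1$freq[match(c("K", "E"), k1$aa)], c(0.7, 0.3))
  syn <- dplyr::filter(af, codon_index == 2, sample == "S1")
  expect_equal(syn$aa, "E")
  expect_equal(syn$freq, 1.0)

  sums <- af %>%
    dplyr::group_by(gene_id, codon_index, codon_pos, sample) %>%
    dplyr::summarise(s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("amino-acid level pi and FST collapse synonymous variation", {
  samples <- c("S1", "S2")
  genes <- fixture_genes()
  # synonymous locus (pos 6) polymorphic 5/5; nonsynonymous locus (pos 7)
  # fixed difference between samples
  loci <- make_loci(
    list(matrix(c(5L, 5L, 5L, 5L), 2), matrix(c(10L, 0L, 0L, 10L), 2)),
    list(c("A", "G"), c("A", "G")), samples, pos = c(6L, 7L))
  f <- filter_loci(loci, min_count = 1, subsample = 0)
  cv <- map_loci_to_codons(f, genes, fixture_genome())

  aap <- aa_pi_genes(cv, genes)
  # pos 6 collapses (contributes 0); pos 7 is monomorphic per sample
  expect_equal(dplyr::filter(aap, gene_id == "g_plus")$pi_aa, c(0, 0))

  aaf <- aa_fst_genes(cv, genes)
  expect_equal(dplyr::filter(aaf, gene_id == "g_plus")$fst_aa, 1.0)

  # nonsynonymous 5/5 polymorphism: aa pi equals nucleotide pi
  loci2 <- make_loci(list(matrix(c(5L, 5L, 5L, 5L), 2)),
                     list(c("A", "G")), samples, pos = 7L)
  cv2 <- map_loci_to_codons(filter_loci(loci2, min_count = 1, subsample = 0),
                            genes, fixture_genome())
  aap2 <- aa_pi_genes(cv2, genes)
  expect_equal(dplyr::filter(aap2, gene_id == "g_plus")$pi_aa,
               rep((1 - 40 / 90) / 12, 2))
})

test_that("Nei-Gojobori site counts match exhaustive mutant enumeration", {
  code <- genetic_code("11")
  sense <- names(code)[code != "*"]
  genome <- stats::setNames(paste(sense, collapse = ""), "c1")
  genes <- tibble::tibble(
    gene_id = sense, contig = "c1",
    start = 3L * seq_along(sense) - 2L, end = 3L * seq_along(sense),
    strand = "+", phase = 0L)
  got <- nei_gojobori_sites(genes, genome)

  # independent oracle: enumerate the 9 mutants of each codon
  oracle_s <- vapply(sense, function(cd) {
    s <- 0
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substr(cd, p, p))) {
      mut <- cd
      substr(mut, p, p) <- b
      if (code[[mut]] == code[[cd]]) s <- s + 1 / 3
    }
    s
  }, numeric(1))
  expect_equal(got$s_sites, unname(oracle_s[got$gene_id]))
  expect_equal(got$n_sites + got$s_sites, rep(3, length(sense)))

  expect_equal(got$s_sites[got$gene_id == "TTT"], 1 / 3)
  expect_equal(got$s_sites[got$gene_id == "ATG"], 0)
  expect_equal(got$n_sites[got$gene_id == "ATG"], 3)
})

test_that("site counting skips reference stop codons with a warning", {
  genome <- stats::setNames("ATGTAAAAATTT", "c1")   # M * K F
  genes <- tibble::tibble(gene_id = "g", contig = "c1", start = 1L,
                          end = 12L, strand = "+", phase = 0L)
  expect_warning(s <- nei_gojobori_sites(genes, genome), "internal stop")
  expect_equal(s$n_codons, 3L)
  expect_equal(s$n_stop_codons, 1L)
  expect_equal(s$n_sites + s$s_sites, 9)
})

test_that("gene-wise pN/pS splits diversity by consequence and site counts", {
  samples <- "S1"
  genes <- fixture_genes()[1, ]
  genome <- fixture_genome()
  sites <- nei_gojobori_sites(genes, genome)
  pi55 <- 1 - 40 / 90

  syn_only <- map_loci_to_codons(
    filter_loci(make_loci(list(matrix(c(5L, 5L), 1)), list(c("A", "G")),
                          samples, pos = 6L),
                min_count = 1, subsample = 0), genes, genome)
  r1 <- gene_pnps(syn_only, sites, genes)
  expect_equal(r1$pn, 0)
  expect_equal(r1$ps, pi55 / sites$s_sites)
  expect_equal(r1$pnps, 0)

  nonsyn_only <- map_loci_to_codons(
    filter_loci(make_loci(list(matrix(c(5L, 5L), 1)), list(c("A", "G")),
                          samples, pos = 7L),
                min_count = 1, subsample = 0), genes, genome)
  r2 <- gene_pnps(nonsyn_only, sites, genes)
  expect_equal(r2$ps, 0)
  expect_true(is.na(r2$pnps))

  both <- map_loci_to_codons(
    filter_loci(make_loci(list(matrix(c(5L, 5L), 1), matrix(c(5L, 5L), 1)),
                          list(c("A", "G"), c("A", "G")), samples,
                          pos = c(6L, 7L)),
                min_count = 1, subsample = 0), genes, genome)
  r3 <- gene_pnps(both, sites, genes)
  # equal diversity at one syn and one nonsyn locus -> ratio = S/N
  expect_equal(r3$pnps, sites$s_sites / sites$n_sites)
})

test_that("charge frequencies average acidic/alkaline content over SAVs", {
  samples <- c("S1", "S2")
  loci <- make_loci(list(matrix(c(7L, 10L, 3L, 0L), 2)),
                    list(c("A", "G")), samples, pos = 7L)
  cv <- map_loci_to_codons(filter_loci(loci, min_count = 1, subsample = 0),
                           fixture_genes(), fixture_genome())
  ch <- charge_frequencies(aa_frequencies(cv))
  # S1: K 0.7 (alkaline), E 0.3 (acidic); S2 monomorphic K
  expect_equal(ch$acidic[ch$sample == "S1"], 0.3)
  expect_equal(ch$alkaline[ch$sample == "S1"], 0.7)
  expect_equal(ch$acidic[ch$sample == "S2"], 0)
  expect_equal(ch$alkaline[ch$sample == "S2"], 1)
})

test_that("third-position variation in 4-fold codons yields pN of zero", {
  sim <- simulate_genome(genome_length = 12000, n_genes = 8,
                         gene_length = 600, seed = 41)
  dat <- simulate_allele_counts(sim, n_samples = 2, target_fst = 0,
                                snv_density = 0.02, depth = 15,
                                fraction_nonsynonymous = 0, seed = 42)
  f <- filter_loci(dat$loci, min_count = 10, subsample = 10, seed = 43)
  cv <- map_loci_to_codons(f, sim$genes, sim$genome)
  pp <- gene_pnps(cv, nei_gojobori_sites(sim$genes, sim$genome), sim$genes)
  expect_true(all(pp$pn == 0))
})
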