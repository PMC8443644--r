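# End-to-end run: ingest -> filter -> diversity -> differentiation ->
# codon-aware statistics -> permutation test, with bit-stable TSV output.

write_fixed_tsv <- function(df, path, digits = 6L) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- format_num(out[[nm]], digits)
  }
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Serialize result tables as TSV files
#'
#' Writes every table present in `results` with fixed column order,
#' 6-decimal fixed-point floats and the literal `NA` for missing values.
#' File names follow `<prefix>.<table>.tsv`; the pairwise F_ST matrix is
#' written square with sample ids as both header and first column.
#'
#' @param results Named list as assembled by [run_pipeline()]; recognized
#'   elements: `intradiversity`, `fst`, `gene_pi`, `gene_fst`, `pnps`,
#'   `aa_freqs`, `gene_aa_pi`, `gene_aa_fst`, `charge_freqs`,
#'   `gene_fst_perm`.
#' @param prefix Output path prefix.
#' @return Character vector of written file paths, invisibly.
#' @export
write_result_tables <- function(results, prefix) {
  written <- character(0)
  put <- function(df, name) {
    p <- sprintf("%s.%s.tsv", prefix, name)
    write_fixed_tsv(df, p)
    written <<- c(written, p)
  }
  if (!is.null(results$intradiversity)) {
    put(results$intradiversity, "intradiversity")
  }
  if (!is.null(results$fst)) {
    m <- fst_matrix(results$fst)
    df <- as_tibble(m, rownames = "sample")
    put(df, "fst")
  }
  if (!is.null(results$gene_pi)) {
    put(tidyr::pivot_wider(results$gene_pi, names_from = "sample",
                           values_from = "pi"), "gene_pi")
  }
  if (!is.null(results$gene_fst)) {
    df <- results$gene_fst %>%
      mutate(sample_pair = paste(.data$sample_a, .data$sample_b,
                                 sep = ":")) %>%
      select("gene_id", "sample_pair", "fst", "loci_used")
    put(df, "gene_fst")
  }
  if (!is.null(results$pnps)) {
    put(tidyr::pivot_wider(
      results$pnps %>% select("gene_id", "sample", "pnps"),
      names_from = "sample", values_from = "pnps"), "pnps")
  }
  if (!is.null(results$aa_freqs)) put(results$aa_freqs, "aa_freqs")
  if (!is.null(results$gene_aa_pi)) put(results$gene_aa_pi, "gene_aa_pi")
  if (!is.null(results$gene_aa_fst)) {
    df <- results$gene_aa_fst %>%
      mutate(sample_pair = paste(.data$sample_a, .data$sample_b,
                                 sep = ":")) %>%
      select("gene_id", "sample_pair", "fst_aa", "loci_used")
    put(df, "gene_aa_fst")
  }
  if (!is.null(results$charge_freqs)) put(results$charge_freqs,
                                          "charge_freqs")
  if (!is.null(results$gene_fst_perm)) {
    put(results$gene_fst_perm, "gene_fst_perm")
  }
  invisible(written)
}

#' Run the full analysis pipeline on input files
#'
#' Executes ingest, filtering, within-sample diversity and pairwise F_ST;
#' with a GFF also gene-wise tables; with GFF plus FASTA also amino-acid
#' frequencies, amino-acid-level gene diversity/F_ST and pN/pS; with
#' `n_perm > 0` also the gene-wise F_ST permutation test for a focal
#' sample pair. Capability tiers degrade gracefully (no GFF: genome-level
#' tables only), but invalid combinations — the permutation test without a
#' focal pair or without gene models — are rejected before any computation.
#' All tables are
#' written via [write_result_tables()] together with a JSON run report
#' recording package version, seed, parameters and provenance counters.
#'
#' @param vcf Path to the multi-sample VCF.
#' @param out_prefix Output path prefix for the TSV tables and run report.
#' @param gff,fasta Optional paths to CDS annotation and genome sequence.
#' @param genome_size Genome size in bp; required when no FASTA is given.
#' @param samples Optional character vector restricting and ordering the
#'   samples (the sample-file idea).
#' @param min_count,subsample,min_found,seed Filtering parameters, see
#'   [filter_loci()].
#' @param estimator F_ST estimator, `"nei"` (default) or `"hudson"`.
#' @param n_perm Number of permutations for the gene-wise test; 0 (default)
#'   disables it.
#' @param pair Character vector of two sample ids for the permutation test.
#' @param pair_by Alternative to `pair`: name of a numeric column in
#'   `metadata` whose two extreme samples form the focal pair.
#' @param metadata Optional data frame (or TSV path) with a `sample` column,
#'   used by `pair_by`.
#' @param code_id Translation table id (default `"11"`).
#' @return Invisibly, a named list with every computed table
#'   (`loci`, `filtered`, `intradiversity`, `fst`, and when applicable
#'   `gene_pi`, `gene_fst`, `codon_variants`, `aa_freqs`, `gene_aa_pi`,
#'   `gene_aa_fst`, `pnps`, `charge_freqs`, `gene_fst_perm`) plus
#'   `report`, the run-report list.
#' @export
run_pipeline <- function(vcf, out_prefix, gff = NULL, fasta = NULL,
                         genome_size = NULL, samples = NULL,
                         min_count = 10, subsample = 10, min_found = 1,
                         estimator = c("nei", "hudson"), n_perm = 0,
                         pair = NULL, pair_by = NULL, metadata = NULL,
                         seed = NULL, code_id = "11") {
  estimator <- match.arg(estimator)
  if (is.character(metadata) && length(metadata) == 1) {
    metadata <- readr::read_tsv(metadata, show_col_types = FALSE)
  }
  if (n_perm > 0 && is.null(pair) && (is.null(pair_by) || is.null(metadata))) {
    abort("Permutation test needs `pair`, or `pair_by` plus `metadata`")
  }
  if (n_perm > 0 && is.null(gff)) {
    abort("Permutation test needs gene models (`gff`)")
  }
  if (is.null(fasta) && is.null(genome_size)) {
    abort("Either `fasta` or `genome_size` must be given")
  }

  genome <- if (!is.null(fasta)) read_genome(fasta) else NULL
  gsize <- if (!is.null(genome)) genome_size(genome) else
    as.integer(genome_size)
  genes <- if (!is.null(gff)) read_gene_models(gff, genome) else NULL

  loci <- read_loci(vcf, samples = samples)
  filtered <- filter_loci(loci, min_count = min_count, subsample = subsample,
                          min_found = min_found, seed = seed)

  results <- list(loci = loci, filtered = filtered)
  results$intradiversity <- pi_genome(filtered, gsize)
  if (length(sample_ids(filtered)) >= 2) {
    results$fst <- fst_pairwise(filtered, estimator = estimator)
  }

  if (!is.null(genes)) {
    results$gene_pi <- pi_genes(filtered, genes)
    if (!is.null(results$fst)) {
      results$gene_fst <- fst_genes(filtered, genes, estimator = estimator)
    }
    if (!is.null(genome)) {
      cv <- map_loci_to_codons(filtered, genes, genome, code_id = code_id)
      results$codon_variants <- cv
      results$aa_freqs <- aa_frequencies(cv)
      results$gene_aa_pi <- aa_pi_genes(cv, genes)
      if (length(sample_ids(filtered)) >= 2) {
        results$gene_aa_fst <- aa_fst_genes(cv, genes, estimator = estimator)
      }
      sites <- nei_gojobori_sites(genes, genome, code_id = code_id)
      results$pnps <- gene_pnps(cv, sites, genes)
      results$charge_freqs <- charge_frequencies(results$aa_freqs)
    }
    if (n_perm > 0) {
      if (is.null(pair)) pair <- select_extreme_pair(metadata, pair_by)
      results$gene_fst_perm <- fst_permutation(
        filtered, genes, pair, n_perm = n_perm, estimator = estimator,
        seed = seed)
    }
  }

  prov <- attr(filtered, "provenance")
  report <- list(
    package = "poolpg",
    version = as.character(utils::packageVersion("poolpg")),
    inputs = list(vcf = vcf, gff = gff, fasta = fasta,
                  genome_size = gsize),
    params = list(min_count = min_count, subsample = subsample,
                  min_found = min_found, estimator = estimator,
                  n_perm = n_perm, pair = pair, seed = seed,
                  code_id = code_id),
    samples = sample_ids(filtered),
    provenance = list(
      loci_in = prov$loci_in,
      loci_out = prov$loci_out,
      loci_dropped_min_found = prov$loci_dropped_min_found,
      included_per_sample = prov$included_per_sample,
      skip_log = as.list(attr(loci, "skip_log"))
    )
  )
  results$report <- report

  write_result_tables(results, out_prefix)
  jsonlite::write_json(report, sprintf("%s.run_report.json", out_prefix),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  message(sprintf(
    "poolpg: %d loci in, %d after filtering (%d dropped by min_found)",
    prov$loci_in, prov$loci_out, prov$loci_dropped_min_found))
  invisible(results)
}
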