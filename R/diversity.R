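# Within-sample nucleotide diversity at locus, gene and genome level.

#' Nucleotide diversity at a single locus
#'
#' Probability that two reads drawn without replacement from the pool
#' covering the position differ: `1 - sum(c_i (c_i - 1)) / (n (n - 1))`
#' with `n = sum(c)`. This is the unbiased (without-replacement) form, not
#' `1 - sum(f^2)`.
#'
#' @param counts Non-negative integer vector of per-allele read counts with
#'   total at least 2.
#' @return Numeric in \[0, 1\].
#' @export
locus_pi <- function(counts) {
  n <- sum(counts)
  if (n < 2) abort("locus_pi requires a total read count of at least 2")
  1 - sum(counts * (counts - 1)) / (n * (n - 1))
}

# Per-(locus, sample) pi over a long locus table; returns locus_id, contig,
# pos, sample, depth, pi.
locus_sample_pi <- function(loci) {
  assert_loci_tbl(loci)
  loci %>%
    group_by(.data$locus_id, .data$contig, .data$pos, .data$sample) %>%
    summarise(depth = sum(.data$count),
              pi = 1 - sum(.data$count * (.data$count - 1)) /
                (depth * (depth - 1)),
              .groups = "drop")
}

#' Overall SNV frequency
#'
#' Number of variant loci divided by genome size (per-bp).
#'
#' @param n_variant_loci Number of variant loci.
#' @param genome_size Genome size in bp.
#' @return Numeric frequency.
#' @export
snv_frequency <- function(n_variant_loci, genome_size) {
  if (genome_size <= 0) abort("`genome_size` must be positive")
  n_variant_loci / genome_size
}

#' Genome-wide nucleotide diversity per sample
#'
#' For each sample, sums locus diversity over the loci included for that
#' sample and divides by the genome size (monomorphic and excluded positions
#' contribute zero). Because under `min_found = 1` different samples can
#' include different locus subsets, a normalized value is also reported:
#' mean per-included-locus diversity rescaled by the overall SNV density,
#' `(sum(pi) / n_included) * (n_variant_loci / genome_size)`.
#'
#' @param filtered A `poolpg_filtered` tibble from [filter_loci()].
#' @param genome_size Genome size in bp.
#' @return A `poolpg_pi` tibble: `sample`, `included_loci`, `pi`,
#'   `pi_normalized` (NA for samples with no included loci). Attributes:
#'   `genome_size`, `n_variant_loci`, `snv_frequency`.
#' @export
pi_genome <- function(filtered, genome_size) {
  assert_loci_tbl(filtered)
  samples <- sample_ids(filtered)
  n_var <- n_distinct(filtered$locus_id)
  dens <- snv_frequency(n_var, genome_size)
  out <- locus_sample_pi(filtered) %>%
    group_by(.data$sample) %>%
    summarise(included_loci = dplyr::n(),
              pi_sum = sum(.data$pi),
              .groups = "drop") %>%
    mutate(pi = .data$pi_sum / genome_size,
           pi_normalized = .data$pi_sum / .data$included_loci * dens) %>%
    select("sample", "included_loci", "pi", "pi_normalized") %>%
    tidyr::complete(sample = samples,
                    fill = list(included_loci = 0L, pi = NA_real_,
                                pi_normalized = NA_real_)) %>%
    arrange(match(.data$sample, samples))
  attr(out, "genome_size") <- genome_size
  attr(out, "n_variant_loci") <- n_var
  attr(out, "snv_frequency") <- dens
  class(out) <- unique(c("poolpg_pi", class(out)))
  out
}

# Assign loci to the gene models whose span contains them (a locus inside
# two overlapping genes is assigned to both). Returns the input plus
# gene_id; loci outside every gene are dropped.
loci_in_genes <- function(tbl, genes) {
  tbl %>%
    inner_join(genes %>% select("gene_id", "contig", "start", "end"),
               by = "contig", relationship = "many-to-many") %>%
    filter(.data$pos >= .data$start, .data$pos <= .data$end) %>%
    select(-"start", -"end")
}

#' Gene-wise nucleotide diversity per sample
#'
#' Sums locus diversity over included loci falling inside each gene model
#' and divides by the gene length in bp (trailing partial codon bases
#' included in the length). Genes without variant loci get 0 for every
#' sample.
#'
#' @param filtered A `poolpg_filtered` tibble from [filter_loci()].
#' @param genes Gene model tibble from [read_gene_models()].
#' @return Tibble: `gene_id`, `sample`, `pi`.
#' @export
pi_genes <- function(filtered, genes) {
  assert_loci_tbl(filtered)
  samples <- sample_ids(filtered)
  glen <- genes %>%
    mutate(gene_length = .data$end - .data$start + 1L) %>%
    select("gene_id", "gene_length")
  lp <- locus_sample_pi(filtered)
  loci_in_genes(lp, genes) %>%
    group_by(.data$gene_id, .data$sample) %>%
    summarise(pi_sum = sum(.data$pi), .groups = "drop") %>%
    tidyr::complete(gene_id = genes$gene_id, sample = samples,
                    fill = list(pi_sum = 0)) %>%
    inner_join(glen, by = "gene_id") %>%
    mutate(pi = .data$pi_sum / .data$gene_length) %>%
    select("gene_id", "sample", "pi") %>%
    arrange(match(.data$gene_id, genes$gene_id), match(.data$sample, samples))
}
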