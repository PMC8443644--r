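# Codon-aware statistics: mapping variant loci into codons, amino-acid
# frequencies, amino-acid-level diversity/differentiation, Nei-Gojobori
# site counting and gene-wise pN/pS.

#' Map variant loci into codons of their gene models
#'
#' Computes, for every included locus inside a CDS, its codon index and
#' within-codon position honoring strand and phase, the reference codon,
#' the strand-oriented allele states and their translations. Each variant
#' allele is substituted into the reference codon with the other two
#' positions held at the reference state (co-occurring variants within one
#' codon are evaluated independently; read-level phasing is not available
#' from a VCF). Loci in the phase-trimmed leader or in a trailing partial
#' codon are excluded and tallied in attribute `n_excluded_partial`; loci
#' whose reference allele disagrees with the genome sequence are dropped
#' with a warning.
#'
#' @param filtered A `poolpg_filtered` (or any long locus) tibble.
#' @param genes Gene model tibble from [read_gene_models()].
#' @param genome Named character vector of contig sequences.
#' @param code_id Translation table for [genetic_code()]; default `"11"`.
#' @return A `poolpg_codon` tibble with one row per
#'   (gene, locus, allele, sample): `gene_id`, `locus_id`, `contig`, `pos`,
#'   `codon_index` (1-based), `codon_pos` (1-3), `ref_codon`, `nt_allele`
#'   (as in the VCF), `allele` (strand-oriented), `is_ref`, `aa`, `sample`,
#'   `count`.
#' @export
map_loci_to_codons <- function(filtered, genes, genome, code_id = "11") {
  assert_loci_tbl(filtered)
  samples <- sample_ids(filtered)
  code <- genetic_code(code_id)

  df <- filtered %>%
    inner_join(genes, by = "contig", relationship = "many-to-many") %>%
    filter(.data$pos >= .data$start, .data$pos <= .data$end)
  if (nrow(df) == 0) {
    out <- tibble(gene_id = character(), locus_id = integer(),
                  contig = character(), pos = integer(),
                  codon_index = integer(), codon_pos = integer(),
                  ref_codon = character(), nt_allele = character(),
                  allele = character(), is_ref = logical(), aa = character(),
                  sample = character(), count = integer())
    out <- set_loci_attrs(out, samples, "poolpg_codon")
    attr(out, "n_excluded_partial") <- 0L
    return(out)
  }

  plus <- df$strand == "+"
  ncod <- (df$end - df$start + 1L - df$phase) %/% 3L
  pos_in_cds <- ifelse(plus,
                       df$pos - (df$start + df$phase) + 1L,
                       (df$end - df$phase) - df$pos + 1L)
  complete <- pos_in_cds >= 1L & pos_in_cds <= 3L * ncod
  n_excluded <- df %>%
    filter(!complete) %>%
    distinct(.data$gene_id, .data$locus_id) %>%
    nrow()
  df <- df[complete, , drop = FALSE]
  plus <- plus[complete]
  pos_in_cds <- pos_in_cds[complete]

  codon_index <- (pos_in_cds - 1L) %/% 3L + 1L
  codon_pos <- (pos_in_cds - 1L) %% 3L + 1L

  seqs <- genome[df$contig]
  cstart <- ifelse(plus,
                   df$start + df$phase + 3L * (codon_index - 1L),
                   (df$end - df$phase) - 3L * codon_index + 1L)
  codon_fwd <- toupper(substring(seqs, cstart, cstart + 2L))
  ref_codon <- ifelse(plus, codon_fwd, revcomp(codon_fwd))

  allele_or <- ifelse(plus, df$allele, complement_base(df$allele))
  mutated <- paste0(substring(ref_codon, 1L, codon_pos - 1L), allele_or,
                    substring(ref_codon, codon_pos + 1L, 3L))
  aa <- unname(code[mutated])

  # reference allele must reproduce the genome base at its codon position
  ref_rows <- df$is_ref
  agree <- substring(ref_codon, codon_pos, codon_pos) == allele_or
  bad_keys <- unique(paste(df$gene_id, df$locus_id)[ref_rows & !agree])
  if (length(bad_keys) > 0) {
    warn(sprintf(
      "Dropping %d locus/gene pair(s) where the VCF reference allele %s",
      length(bad_keys), "disagrees with the genome sequence"))
  }
  keep <- !(paste(df$gene_id, df$locus_id) %in% bad_keys)

  out <- tibble(
    gene_id = df$gene_id, locus_id = df$locus_id, contig = df$contig,
    pos = df$pos, codon_index = codon_index, codon_pos = codon_pos,
    ref_codon = ref_codon, nt_allele = df$allele, allele = allele_or,
    is_ref = df$is_ref, aa = aa, sample = df$sample, count = df$count
  )[keep, , drop = FALSE]
  out <- set_loci_attrs(out, samples, "poolpg_codon")
  attr(out, "n_excluded_partial") <- n_excluded
  out
}

#' Amino-acid frequencies per variant codon position
#'
#' For each gene, codon position and sample, the frequency of each amino
#' acid is the summed frequency of the nucleotide alleles translating to
#' it; synonymous alleles collapse onto one amino acid.
#'
#' @param codon_variants A `poolpg_codon` tibble from
#'   [map_loci_to_codons()].
#' @return Tibble: `gene_id`, `codon_index`, `codon_pos`, `sample`, `aa`,
#'   `freq` (frequencies sum to 1 within each position/sample).
#' @export
aa_frequencies <- function(codon_variants) {
  codon_variants %>%
    group_by(.data$gene_id, .data$codon_index, .data$codon_pos,
             .data$sample) %>%
    mutate(depth = sum(.data$count)) %>%
    group_by(.data$gene_id, .data$codon_index, .data$codon_pos,
             .data$sample, .data$aa) %>%
    summarise(freq = sum(.data$count / .data$depth), .groups = "drop") %>%
    arrange(.data$gene_id, .data$codon_index, .data$codon_pos, .data$sample,
            .data$aa)
}

# Amino-acid-level long locus table: nucleotide counts collapsed onto
# translated states, one pseudo-locus per (gene, original locus).
aa_locus_table <- function(codon_variants) {
  samples <- sample_ids(codon_variants)
  tbl <- codon_variants %>%
    group_by(.data$gene_id, .data$locus_id, .data$contig, .data$pos,
             .data$sample, .data$aa) %>%
    summarise(count = sum(.data$count), is_ref = any(.data$is_ref),
              .groups = "drop")
  key <- paste(tbl$gene_id, tbl$locus_id)
  tbl <- tbl %>%
    mutate(gene_locus = match(key, unique(key))) %>%
    rename(nt_locus_id = "locus_id", locus_id = "gene_locus",
           allele = "aa")
  set_loci_attrs(tbl, samples)
}

#' Gene-wise amino-acid-level nucleotide diversity
#'
#' Same estimator as [pi_genes()] applied to amino-acid state counts per
#' variant codon position: positions whose alleles are all synonymous
#' contribute zero.
#'
#' @inheritParams aa_frequencies
#' @param genes Gene model tibble.
#' @return Tibble: `gene_id`, `sample`, `pi_aa` (per bp of gene length).
#' @export
aa_pi_genes <- function(codon_variants, genes) {
  samples <- sample_ids(codon_variants)
  glen <- genes %>%
    mutate(gene_length = .data$end - .data$start + 1L) %>%
    select("gene_id", "gene_length")
  aa_locus_table(codon_variants) %>%
    group_by(.data$gene_id, .data$locus_id, .data$sample) %>%
    summarise(depth = sum(.data$count),
              pi = 1 - sum(.data$count * (.data$count - 1)) /
                (depth * (depth - 1)),
              .groups = "drop") %>%
    group_by(.data$gene_id, .data$sample) %>%
    summarise(pi_sum = sum(.data$pi), .groups = "drop") %>%
    tidyr::complete(gene_id = genes$gene_id, sample = samples,
                    fill = list(pi_sum = 0)) %>%
    inner_join(glen, by = "gene_id") %>%
    mutate(pi_aa = .data$pi_sum / .data$gene_length) %>%
    select("gene_id", "sample", "pi_aa") %>%
    arrange(match(.data$gene_id, genes$gene_id), match(.data$sample, samples))
}

#' Gene-wise amino-acid-level F_ST for all sample pairs
#'
#' Same estimators as [fst_genes()] applied to amino-acid state counts;
#' positions where the pooled pair carries a single amino acid contribute
#' zero heterozygosity.
#'
#' @inheritParams aa_pi_genes
#' @param estimator `"nei"` (default) or `"hudson"`.
#' @return Tibble: `gene_id`, `sample_a`, `sample_b`, `fst_aa`,
#'   `loci_used`.
#' @export
aa_fst_genes <- function(codon_variants, genes,
                         estimator = c("nei", "hudson")) {
  estimator <- match.arg(estimator)
  samples <- sample_ids(codon_variants)
  if (length(samples) < 2) abort("At least two samples are required")
  aa_tbl <- aa_locus_table(codon_variants)
  gene_of <- aa_tbl %>% distinct(.data$locus_id, .data$gene_id)
  pairs <- utils::combn(samples, 2)
  purrr::map(seq_len(ncol(pairs)), function(i) {
    pr <- pairs[, i]
    terms <- pair_locus_terms(aa_tbl, pr) %>%
      inner_join(gene_of, by = "locus_id")
    terms %>%
      group_by(.data$gene_id) %>%
      summarise(fst_aa = fst_from_terms(dplyr::pick(dplyr::everything()),
                                        estimator),
                loci_used = dplyr::n(), .groups = "drop") %>%
      tidyr::complete(gene_id = genes$gene_id,
                      fill = list(fst_aa = NA_real_, loci_used = 0L)) %>%
      mutate(sample_a = pr[1], sample_b = pr[2])
  }) %>%
    bind_rows() %>%
    select("gene_id", "sample_a", "sample_b", "fst_aa", "loci_used") %>%
    arrange(match(.data$gene_id, genes$gene_id))
}

# Per-codon synonymous site counts under equal mutation rates: for each of
# the three positions, the fraction of the three single-base mutants that
# preserve the amino acid. Stop-gain mutants count as non-synonymous.
syn_sites_by_codon <- function(code) {
  codons <- names(code)
  vapply(codons, function(cd) {
    aa0 <- code[[cd]]
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(BASES, substr(cd, p, p))) {
        mut <- cd
        substr(mut, p, p) <- b
        if (code[[mut]] == aa0) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
}

#' Nei-Gojobori synonymous and non-synonymous site counts per gene
#'
#' For every complete reference codon, each of the nine single-nucleotide
#' mutants is classified; the per-position synonymous fraction accumulates
#' into S, the remainder into N (so N + S = 3 per counted codon).
#' Stop-gain mutants are non-synonymous; reference stop codons (including
#' a trailing stop) are excluded from the counts, with a warning when they
#' occur internally.
#'
#' @param genes Gene model tibble.
#' @param genome Named character vector of contig sequences.
#' @param code_id Translation table id; default `"11"`.
#' @return Tibble: `gene_id`, `n_sites`, `s_sites`, `n_codons`
#'   (codons counted), `n_stop_codons` (reference stops excluded).
#' @export
nei_gojobori_sites <- function(genes, genome, code_id = "11") {
  code <- genetic_code(code_id)
  syn_tab <- syn_sites_by_codon(code)

  purrr::pmap(genes, function(gene_id, contig, start, end, strand, phase,
                              ...) {
    seqc <- toupper(substring(genome[[contig]], start, end))
    if (strand == "-") seqc <- revcomp(seqc)
    cds <- substring(seqc, phase + 1L)
    nc <- nchar(cds) %/% 3L
    cods <- substring(cds, 3L * (seq_len(nc) - 1L) + 1L, 3L * seq_len(nc))
    is_stop <- code[cods] == "*"
    if (any(is_stop[-length(is_stop)])) {
      warn(sprintf("Gene %s has %d internal stop codon(s); skipped in %s",
                   gene_id, sum(is_stop[-length(is_stop)]), "site counts"))
    }
    cods <- cods[!is_stop]
    s <- sum(syn_tab[cods])
    tibble(gene_id = gene_id, n_sites = 3 * length(cods) - s, s_sites = s,
           n_codons = length(cods), n_stop_codons = sum(is_stop))
  }) %>%
    bind_rows()
}

#' Gene-wise pN/pS per sample
#'
#' Polymorphism rates from read-pair weights consistent with the diversity
#' estimator: at each variant position the probability that two reads drawn
#' without replacement differ splits into a non-synonymous part (the reads
#' translate to different amino acids, equal to the amino-acid-level locus
#' diversity) and a synonymous part (different bases, same amino acid; the
#' nucleotide-level minus the amino-acid-level diversity). The parts are
#' summed over a gene's variant positions and divided by the gene's
#' Nei-Gojobori non-synonymous and synonymous site counts; `pnps` is their
#' ratio, `NA` when `ps` is zero.
#'
#' @inheritParams aa_pi_genes
#' @param sites Site-count tibble from [nei_gojobori_sites()].
#' @return Tibble: `gene_id`, `sample`, `pn`, `ps`, `pnps`, `n_sites`,
#'   `s_sites`.
#' @export
gene_pnps <- function(codon_variants, sites, genes = NULL) {
  samples <- sample_ids(codon_variants)
  per_locus <- codon_variants %>%
    group_by(.data$gene_id, .data$locus_id, .data$sample) %>%
    summarise(depth = sum(.data$count),
              nt_pi = 1 - sum(.data$count * (.data$count - 1)) /
                (depth * (depth - 1)),
              aa_pi = {
                cc <- tapply(.data$count, .data$aa, sum)
                1 - sum(cc * (cc - 1)) / (depth * (depth - 1))
              },
              .groups = "drop")
  gene_ids <- if (!is.null(genes)) genes$gene_id else sites$gene_id
  per_locus %>%
    group_by(.data$gene_id, .data$sample) %>%
    summarise(nonsyn = sum(.data$aa_pi),
              syn = sum(.data$nt_pi - .data$aa_pi), .groups = "drop") %>%
    tidyr::complete(gene_id = gene_ids, sample = samples,
                    fill = list(nonsyn = 0, syn = 0)) %>%
    inner_join(sites %>% select("gene_id", "n_sites", "s_sites"),
               by = "gene_id") %>%
    mutate(pn = .data$nonsyn / .data$n_sites,
           ps = .data$syn / .data$s_sites,
           pnps = ifelse(.data$ps > 0, .data$pn / .data$ps, NA_real_)) %>%
    select("gene_id", "sample", "pn", "ps", "pnps", "n_sites", "s_sites") %>%
    arrange(match(.data$gene_id, gene_ids), match(.data$sample, samples))
}

#' Acidic and alkaline amino-acid frequencies in the population proteome
#'
#' Mean frequency of acidic (Asp, Glu) and alkaline (Lys, Arg, His)
#' residues across all variant codon positions of a sample, computed from
#' the single-amino-acid-variant frequency table.
#'
#' @param aa_freqs Frequency tibble from [aa_frequencies()].
#' @return Tibble: `sample`, `n_positions`, `acidic`, `alkaline` (both NA
#'   when a sample has no variant codon positions).
#' @export
charge_frequencies <- function(aa_freqs) {
  aa_freqs %>%
    group_by(.data$gene_id, .data$codon_index, .data$codon_pos,
             .data$sample) %>%
    summarise(acidic = sum(.data$freq[.data$aa %in% ACIDIC_AA]),
              alkaline = sum(.data$freq[.data$aa %in% ALKALINE_AA]),
              .groups = "drop") %>%
    group_by(.data$sample) %>%
    summarise(n_positions = dplyr::n(),
              acidic = mean(.data$acidic),
              alkaline = mean(.data$alkaline), .groups = "drop")
}
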