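# Pairwise fixation index between samples, genome-wide and per gene.

#' Within- and total heterozygosity for one locus in a sample pair
#'
#' Computes allele frequencies from the two count vectors (aligned to the
#' same allele order), then `H_a = 1 - sum(f_a^2)`, `H_b` likewise,
#' `H_S = (H_a + H_b)/2` and, with the equal-weight pooled frequency
#' `fbar = (f_a + f_b)/2`, `H_T = 1 - sum(fbar^2)`.
#'
#' @param counts_a,counts_b Allele-count vectors of equal length with
#'   positive totals.
#' @return Named numeric vector `c(H_S = ..., H_T = ...)`.
#' @export
locus_heterozygosities <- function(counts_a, counts_b) {
  na <- sum(counts_a); nb <- sum(counts_b)
  if (na <= 0 || nb <= 0) abort("Both samples need positive depth at the locus")
  fa <- counts_a / na
  fb <- counts_b / nb
  hs <- ((1 - sum(fa^2)) + (1 - sum(fb^2))) / 2
  fbar <- (fa + fb) / 2
  c(H_S = hs, H_T = 1 - sum(fbar^2))
}

# Per-locus FST ingredients for one sample pair, over loci where both
# samples are included. Returns locus_id, contig, pos, hs, ht (Nei-style
# plain-frequency heterozygosities), pw, pb (Hudson-style within/between
# pi, the within form without replacement).
pair_locus_terms <- function(filtered, pair) {
  assert_loci_tbl(filtered)
  stopifnot(length(pair) == 2)
  sub <- filtered %>% filter(.data$sample %in% pair)
  pres <- sub %>%
    distinct(.data$locus_id, .data$sample) %>%
    count(.data$locus_id) %>%
    filter(.data$n == 2L)
  if (nrow(pres) == 0) {
    return(tibble(locus_id = integer(), contig = character(),
                  pos = integer(), hs = numeric(), ht = numeric(),
                  pw = numeric(), pb = numeric()))
  }
  wide <- sub %>%
    semi_join(pres, by = "locus_id") %>%
    select("locus_id", "contig", "pos", "allele", "sample", "count") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0L) %>%
    rename(ca = !!rlang::sym(pair[1]), cb = !!rlang::sym(pair[2]))
  wide %>%
    group_by(.data$locus_id, .data$contig, .data$pos) %>%
    summarise(
      na = sum(.data$ca), nb = sum(.data$cb),
      ha = 1 - sum((.data$ca / na)^2),
      hb = 1 - sum((.data$cb / nb)^2),
      hs = (ha + hb) / 2,
      ht = 1 - sum(((.data$ca / na + .data$cb / nb) / 2)^2),
      pw = ((1 - sum(.data$ca * (.data$ca - 1)) / (na * (na - 1))) +
            (1 - sum(.data$cb * (.data$cb - 1)) / (nb * (nb - 1)))) / 2,
      pb = 1 - sum(.data$ca * .data$cb) / (na * nb),
      .groups = "drop") %>%
    select("locus_id", "contig", "pos", "hs", "ht", "pw", "pb")
}

# Multi-locus FST as a ratio of sums over the supplied per-locus terms.
fst_from_terms <- function(terms, estimator) {
  if (nrow(terms) == 0) return(NA_real_)
  if (estimator == "nei") {
    sht <- sum(terms$ht)
    if (sht <= 0) return(NA_real_)
    (sht - sum(terms$hs)) / sht
  } else {
    spb <- sum(terms$pb)
    if (spb <= 0) return(NA_real_)
    1 - sum(terms$pw) / spb
  }
}

#' Fixation index between one pair of samples
#'
#' Multi-locus F_ST over loci where both samples are included, aggregated
#' as a ratio of sums across loci. The default `"nei"` estimator is
#' `(sum(H_T) - sum(H_S)) / sum(H_T)` on plain allele frequencies with
#' equal-weight pooling (bounded to \[0, 1\]); `"hudson"` is
#' `1 - sum(pi_within)/sum(pi_between)` with within-sample diversity in the
#' without-replacement form (unbiased at finite depth, may be negative).
#'
#' @param filtered A `poolpg_filtered` tibble from [filter_loci()].
#' @param pair Character vector of two sample ids.
#' @param estimator `"nei"` (default) or `"hudson"`.
#' @param genes Optional gene model tibble; when supplied, F_ST is computed
#'   per gene instead of genome-wide.
#' @return A single numeric (genome-wide; NA when the pooled pair is
#'   monomorphic at every shared locus) or, with `genes`, a tibble
#'   `gene_id`, `fst`, `loci_used`.
#' @export
pairwise_fst <- function(filtered, pair, estimator = c("nei", "hudson"),
                         genes = NULL) {
  estimator <- match.arg(estimator)
  terms <- pair_locus_terms(filtered, pair)
  if (is.null(genes)) {
    return(fst_from_terms(terms, estimator))
  }
  loci_in_genes(terms, genes) %>%
    group_by(.data$gene_id) %>%
    summarise(fst = fst_from_terms(dplyr::pick(dplyr::everything()),
                                   estimator),
              loci_used = dplyr::n(), .groups = "drop") %>%
    tidyr::complete(gene_id = genes$gene_id,
                    fill = list(fst = NA_real_, loci_used = 0L)) %>%
    arrange(match(.data$gene_id, genes$gene_id))
}

#' Pairwise F_ST for all sample pairs
#'
#' @param filtered A `poolpg_filtered` tibble from [filter_loci()].
#' @param estimator `"nei"` (default) or `"hudson"`.
#' @return A `poolpg_fst` tibble with one row per unordered pair:
#'   `sample_a`, `sample_b`, `fst`, `loci_used`. Attributes `samples` and
#'   `estimator`. Use [fst_matrix()] for the square symmetric form.
#' @export
fst_pairwise <- function(filtered, estimator = c("nei", "hudson")) {
  estimator <- match.arg(estimator)
  samples <- sample_ids(filtered)
  if (length(samples) < 2) abort("At least two samples are required")
  pairs <- utils::combn(samples, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(i) {
    pr <- pairs[, i]
    terms <- pair_locus_terms(filtered, pr)
    tibble(sample_a = pr[1], sample_b = pr[2],
           fst = fst_from_terms(terms, estimator),
           loci_used = nrow(terms))
  })
  out <- bind_rows(rows)
  if (any(out$loci_used == 0)) {
    warn(sprintf("%d sample pair(s) share no qualifying loci",
                 sum(out$loci_used == 0)))
  }
  attr(out, "samples") <- samples
  attr(out, "estimator") <- estimator
  class(out) <- unique(c("poolpg_fst", class(out)))
  out
}

#' Gene-wise F_ST for all sample pairs
#'
#' @inheritParams fst_pairwise
#' @param genes Gene model tibble from [read_gene_models()].
#' @return Tibble: `gene_id`, `sample_a`, `sample_b`, `fst`, `loci_used`
#'   (NA fst for gene/pair combinations without usable polymorphism).
#' @export
fst_genes <- function(filtered, genes, estimator = c("nei", "hudson")) {
  estimator <- match.arg(estimator)
  samples <- sample_ids(filtered)
  if (length(samples) < 2) abort("At least two samples are required")
  pairs <- utils::combn(samples, 2)
  purrr::map(seq_len(ncol(pairs)), function(i) {
    pr <- pairs[, i]
    pairwise_fst(filtered, pr, estimator = estimator, genes = genes) %>%
      mutate(sample_a = pr[1], sample_b = pr[2])
  }) %>%
    bind_rows() %>%
    select("gene_id", "sample_a", "sample_b", "fst", "loci_used")
}

#' Square symmetric matrix view of pairwise F_ST
#'
#' @param x A `poolpg_fst` tibble from [fst_pairwise()].
#' @return Numeric matrix, samples x samples, zero diagonal.
#' @export
fst_matrix <- function(x) {
  samples <- attr(x, "samples") %||% unique(c(x$sample_a, x$sample_b))
  m <- matrix(NA_real_, length(samples), length(samples),
              dimnames = list(samples, samples))
  diag(m) <- 0
  for (i in seq_len(nrow(x))) {
    m[x$sample_a[i], x$sample_b[i]] <- x$fst[i]
    m[x$sample_b[i], x$sample_a[i]] <- x$fst[i]
  }
  m
}
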