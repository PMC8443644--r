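# Gene-wise FST permutation test: shuffle variant loci over the genome,
# keeping per-gene locus counts, and compare actual to permuted values.

#' Permutation p-value
#'
#' `p = (1 + number of permuted values >= actual) / n_perm`, capped at 1
#' (the formula can exceed 1 when every permuted value ties or beats the
#' actual). Ties count as greater-or-equal; comparisons use a 1e-12
#' tolerance so that re-summing identical terms in a different order still
#' counts as a tie. Permuted values that are undefined (NA: the permuted
#' locus set carries no polymorphism) count as >= only when the actual
#' value is <= 0.
#'
#' @param actual Actual statistic value.
#' @param permuted Numeric vector of permuted values (may contain NA).
#' @param n_perm Number of permutations (default `length(permuted)`).
#' @return Numeric p-value in (0, 1].
#' @export
permutation_p <- function(actual, permuted, n_perm = length(permuted)) {
  if (n_perm < 1) abort("`n_perm` must be at least 1")
  if (is.na(actual)) return(NA_real_)
  ok <- !is.na(permuted)
  n_ge <- sum(permuted[ok] >= actual - 1e-12)
  if (actual <= 0) n_ge <- n_ge + sum(!ok)
  min(1, (1 + n_ge) / n_perm)
}

#' One random reassignment of loci to genes
#'
#' Permutes the genome-wide pool of variant loci and hands each gene as
#' many loci as it originally contained (allele counts travel with their
#' locus); leftover loci form the intergenic remainder. Draws from the
#' current RNG state.
#'
#' @param loci Any table with `locus_id`, `contig`, `pos` columns (one row
#'   per locus, e.g. distinct loci of a filtered table).
#' @param genes Gene model tibble.
#' @return Tibble `gene_id`, `locus_id` giving the permuted assignment.
#' @export
shuffle_loci <- function(loci, genes) {
  pool <- loci %>% distinct(.data$locus_id, .data$contig, .data$pos)
  m <- loci_in_genes(pool, genes) %>%
    count(.data$gene_id, name = "n_loci") %>%
    tidyr::complete(gene_id = genes$gene_id, fill = list(n_loci = 0L)) %>%
    arrange(match(.data$gene_id, genes$gene_id))
  idx <- sample.int(nrow(pool))
  ends <- cumsum(m$n_loci)
  starts <- ends - m$n_loci + 1L
  purrr::map(which(m$n_loci > 0), function(g) {
    tibble(gene_id = m$gene_id[g],
           locus_id = pool$locus_id[idx[starts[g]:ends[g]]])
  }) %>%
    bind_rows()
}

#' Permutation test for gene-wise F_ST between a focal sample pair
#'
#' Computes the actual gene-wise F_ST for the pair, then repeatedly
#' shuffles the genome-wide pool of pair-qualifying variant loci so that
#' each gene receives a random locus set of its original size, re-scoring
#' every gene from the same global shuffle (one permutation per
#' replicate). The p-value follows [permutation_p()]; q-values are
#' Benjamini-Hochberg adjusted across the genome's genes.
#'
#' Genes whose spans overlap so heavily that they jointly contain more
#' loci than the pool holds fall back to independent per-gene draws within
#' each replicate.
#'
#' @param filtered A `poolpg_filtered` tibble from [filter_loci()].
#' @param genes Gene model tibble.
#' @param pair Character vector of two sample ids (e.g. the two samples at
#'   the extremes of an environmental gradient; see
#'   [select_extreme_pair()]).
#' @param n_perm Number of permutations (default 10000).
#' @param estimator `"nei"` (default) or `"hudson"`.
#' @param seed Optional integer seed; fixed seed reproduces every `n_ge`
#'   exactly.
#' @return A `poolpg_fst_perm` tibble: `gene_id`, `n_loci`, `actual_fst`,
#'   `n_perm`, `n_ge`, `p_value`, `q_value` (NA rows for genes without
#'   usable loci). Attributes: `pair`, `estimator`.
#' @export
fst_permutation <- function(filtered, genes, pair, n_perm = 10000,
                            estimator = c("nei", "hudson"), seed = NULL) {
  estimator <- match.arg(estimator)
  if (n_perm < 1) abort("`n_perm` must be at least 1")
  local_seed(seed)

  terms <- pair_locus_terms(filtered, pair)
  L <- nrow(terms)
  if (L == 0) abort("The focal pair shares no qualifying loci")

  if (estimator == "nei") {
    num <- terms$ht - terms$hs   # per-locus numerator contribution
    den <- terms$ht
  } else {
    num <- terms$pb - terms$pw
    den <- terms$pb
  }

  assign0 <- loci_in_genes(terms %>% select("locus_id", "contig", "pos"),
                           genes)
  m <- assign0 %>%
    count(.data$gene_id, name = "n_loci") %>%
    tidyr::complete(gene_id = genes$gene_id, fill = list(n_loci = 0L)) %>%
    arrange(match(.data$gene_id, genes$gene_id))

  actual <- assign0 %>%
    left_join(tibble(locus_id = terms$locus_id, num = num, den = den),
              by = "locus_id") %>%
    group_by(.data$gene_id) %>%
    summarise(s_num = sum(.data$num), s_den = sum(.data$den),
              .groups = "drop") %>%
    mutate(actual_fst = ifelse(.data$s_den > 0,
                               .data$s_num / .data$s_den, NA_real_))
  m <- m %>% left_join(actual %>% select("gene_id", "actual_fst"),
                       by = "gene_id")

  active <- which(m$n_loci > 0)
  sizes <- m$n_loci[active]
  contiguous <- sum(sizes) <= L
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L

  n_ge <- integer(nrow(m))
  act <- m$actual_fst
  tol <- 1e-12
  for (r in seq_len(n_perm)) {
    if (contiguous) {
      idx <- sample.int(L, sum(sizes))
      cn <- cumsum(num[idx]); cd <- cumsum(den[idx])
      s_num <- cn[ends] - c(0, cn[head(ends, -1)])
      s_den <- cd[ends] - c(0, cd[head(ends, -1)])
    } else {
      s_num <- numeric(length(active)); s_den <- numeric(length(active))
      for (g in seq_along(active)) {
        idx <- sample.int(L, sizes[g])
        s_num[g] <- sum(num[idx]); s_den[g] <- sum(den[idx])
      }
    }
    perm_fst <- ifelse(s_den > 0, s_num / s_den, NA_real_)
    a <- act[active]
    ge <- !is.na(a) &
      ((!is.na(perm_fst) & perm_fst >= a - tol) | (is.na(perm_fst) & a <= 0))
    n_ge[active] <- n_ge[active] + ge
  }

  out <- m %>%
    mutate(n_perm = n_perm,
           n_ge = ifelse(is.na(.data$actual_fst), NA_integer_, n_ge),
           p_value = purrr::map2_dbl(.data$actual_fst, n_ge, function(a, k) {
             if (is.na(a)) NA_real_ else min(1, (1 + k) / n_perm)
           })) %>%
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) %>%
    select("gene_id", "n_loci", "actual_fst", "n_perm", "n_ge", "p_value",
           "q_value")
  attr(out, "pair") <- pair
  attr(out, "estimator") <- estimator
  class(out) <- unique(c("poolpg_fst_perm", class(out)))
  out
}

#' Pick the two samples at the extremes of a metadata gradient
#'
#' @param metadata Data frame with one row per sample.
#' @param column Name of the numeric gradient column (e.g. salinity).
#' @param sample_col Name of the sample-id column (default `"sample"`).
#' @return Character vector of two sample ids (minimum, maximum).
#' @export
select_extreme_pair <- function(metadata, column, sample_col = "sample") {
  v <- metadata[[column]]
  if (is.null(v)) abort(sprintf("Column `%s` not found in metadata", column))
  s <- metadata[[sample_col]]
  c(s[which.min(v)], s[which.max(v)])
}
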