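# Tidier and summary methods for the package's result objects.

#' @rdname poolpg-tidiers
#' @param x A `poolpg_pi`, `poolpg_fst`, `poolpg_fst_perm` or
#'   `poolpg_filtered` object.
#' @param ... Unused, for generic consistency.
#' @return `tidy()` returns a plain tibble (one row per sample, sample
#'   pair, or gene); `glance()` a one-row summary tibble.
#' @export
tidy.poolpg_pi <- function(x, ...) {
  as_tibble(unclass(x)[c("sample", "included_loci", "pi", "pi_normalized")])
}

#' @rdname poolpg-tidiers
#' @export
glance.poolpg_pi <- function(x, ...) {
  tibble(
    n_samples = nrow(x),
    n_variant_loci = attr(x, "n_variant_loci"),
    genome_size = attr(x, "genome_size"),
    snv_frequency = attr(x, "snv_frequency"),
    mean_pi = mean(x$pi, na.rm = TRUE),
    mean_pi_normalized = mean(x$pi_normalized, na.rm = TRUE)
  )
}

#' Tidiers for poolpg result objects
#'
#' Broom-style `tidy()` and `glance()` methods: `tidy()` strips the class
#' and attributes down to a plain observation-per-row tibble, `glance()`
#' gives a one-row model-level summary.
#'
#' @name poolpg-tidiers
NULL

#' @rdname poolpg-tidiers
#' @export
tidy.poolpg_fst <- function(x, ...) {
  as_tibble(unclass(x)[c("sample_a", "sample_b", "fst", "loci_used")])
}

#' @rdname poolpg-tidiers
#' @export
glance.poolpg_fst <- function(x, ...) {
  tibble(
    n_samples = length(attr(x, "samples")),
    n_pairs = nrow(x),
    estimator = attr(x, "estimator"),
    mean_fst = mean(x$fst, na.rm = TRUE),
    max_fst = max(x$fst, na.rm = TRUE),
    min_loci_used = min(x$loci_used)
  )
}

#' @rdname poolpg-tidiers
#' @param alpha Significance threshold on the FDR-adjusted p-value used by
#'   `glance.poolpg_fst_perm()` (default 0.05).
#' @export
glance.poolpg_fst_perm <- function(x, alpha = 0.05, ...) {
  tibble(
    n_genes = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_perm = x$n_perm[1],
    pair = paste(attr(x, "pair"), collapse = ":"),
    estimator = attr(x, "estimator"),
    n_significant = sum(x$q_value < alpha, na.rm = TRUE),
    min_p = min(x$p_value, na.rm = TRUE)
  )
}

#' @rdname poolpg-tidiers
#' @export
tidy.poolpg_fst_perm <- function(x, ...) {
  as_tibble(unclass(x)[c("gene_id", "n_loci", "actual_fst", "n_perm",
                         "n_ge", "p_value", "q_value")])
}

#' @rdname poolpg-tidiers
#' @export
glance.poolpg_filtered <- function(x, ...) {
  prov <- attr(x, "provenance")
  params <- attr(x, "params")
  tibble(
    loci_in = prov$loci_in,
    loci_out = prov$loci_out,
    loci_dropped_min_found = prov$loci_dropped_min_found,
    n_samples = length(attr(x, "samples")),
    min_count = params$min_count,
    subsample = params$subsample,
    min_found = params$min_found
  )
}
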