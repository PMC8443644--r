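# autoplot() methods for the main result types.

#' Plot per-sample nucleotide diversity
#'
#' @param object A `poolpg_pi` tibble from [pi_genome()].
#' @param normalized Plot the normalized value instead of the raw one
#'   (default FALSE).
#' @param ... Unused.
#' @return A ggplot object (one point per sample).
#' @export
autoplot.poolpg_pi <- function(object, normalized = FALSE, ...) {
  y <- if (normalized) "pi_normalized" else "pi"
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$sample, levels = .data$sample),
    y = .data[[y]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL,
                  y = if (normalized) expression(pi ~ "(normalized)") else
                    expression(pi)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heatmap of pairwise F_ST
#'
#' @param object A `poolpg_fst` tibble from [fst_pairwise()].
#' @param ... Unused.
#' @return A ggplot tile heatmap of the symmetric F_ST matrix.
#' @export
autoplot.poolpg_fst <- function(object, ...) {
  m <- fst_matrix(object)
  df <- as_tibble(m, rownames = "sample_a") %>%
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "fst") %>%
    mutate(sample_a = factor(.data$sample_a, levels = rownames(m)),
           sample_b = factor(.data$sample_b, levels = rownames(m)))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$fst)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(F[ST]), na.value =
                                    "grey85") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Gene-wise permutation test overview
#'
#' Scatter of each gene's actual F_ST against its FDR-adjusted permutation
#' p-value (-log10), highlighting genes below the significance threshold.
#'
#' @param object A `poolpg_fst_perm` tibble from [fst_permutation()].
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.poolpg_fst_perm <- function(object, alpha = 0.05, ...) {
  df <- tidy(object) %>%
    filter(!is.na(.data$p_value)) %>%
    mutate(significant = .data$q_value < alpha)
  ggplot2::ggplot(df, ggplot2::aes(.data$actual_fst,
                                   -log10(.data$q_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = sprintf("q < %.2g", alpha)) +
    ggplot2::labs(x = expression("gene-wise" ~ F[ST]),
                  y = expression(-log[10] ~ "(adjusted p)")) +
    ggplot2::theme_minimal()
}
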