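# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-genotype predictive performance
#'
#' Pointrange of mean Pearson r (+/- SD over iterations) per held-out
#' genotype, ordered by mean r.
#'
#' @param object A `performance_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.performance_summary <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     genotype = stats::reorder(.data$genotype, .data$mean_r))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$mean_r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "held-out genotype", y = "Pearson r (predicted vs observed)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (all(is.na(d$sd_r))) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                                              ymax = .data$mean_r + .data$sd_r))
  }
}

#' Plot top aggregated feature importances
#'
#' @param object An `importance_table`.
#' @param top_n Features shown (default 25).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_table <- function(object, top_n = 25, ...) {
  d <- utils::head(dplyr::arrange(tibble::as_tibble(object), .data$rank), top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$gene, .data$importance),
                                  y = .data$importance, fill = .data$shared_count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "summed gain across genotype models",
                  fill = "models\nsharing") +
    ggplot2::theme_minimal()
}

#' Plot regulator connectivity
#'
#' @param object A `tf_rank` table.
#' @param top_n Regulators shown (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tf_rank <- function(object, top_n = 20, ...) {
  d <- utils::head(dplyr::arrange(tibble::as_tibble(object), .data$rank), top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$regulator, .data$connectivity),
                                  y = .data$connectivity)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "connectivity (retained edges)") +
    ggplot2::theme_minimal()
}

#' Plot a two-way variance partition
#'
#' @param object A `variance_partition`.
#' @param ... Unused.
#' @return A ggplot (single stacked bar of variance fractions).
#' @export
autoplot.variance_partition <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(d, ggplot2::aes(x = "trait", y = .data$fraction, fill = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of total sum of squares", fill = NULL) +
    ggplot2::theme_minimal()
}
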