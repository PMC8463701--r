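# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-gene NB GLM fit
#'
#' @param x An `nb_glm_fit`.
#' @param ... Unused.
#' @return Long tibble: gene, term, estimate, plus per-gene dispersion and
#'   deviance.
#' @export
tidy.nb_glm_fit <- function(x, ...) {
  co <- tibble::as_tibble(x$coefficients, rownames = "gene")
  out <- tidyr::pivot_longer(co, -"gene", names_to = "term", values_to = "estimate")
  info <- tibble::tibble(gene = x$gene_ids, dispersion = x$dispersion, deviance = x$deviance)
  dplyr::left_join(out, info, by = "gene")
}

#' @rdname tidy.nb_glm_fit
#' @export
glance.nb_glm_fit <- function(x, ...) {
  tibble::tibble(n_genes = length(x$gene_ids), model = x$model, design_rank = x$rank,
                 df_residual = x$df_residual,
                 median_dispersion = stats::median(x$dispersion))
}

#' Tidy a gradient-boosted model
#'
#' @param x A `gbt_model`.
#' @param ... Unused.
#' @return Tibble of per-feature gain importance, descending.
#' @export
tidy.gbt_model <- function(x, ...) {
  out <- tibble::tibble(feature = names(x$importance), gain = unname(x$importance))
  dplyr::arrange(out, dplyr::desc(.data$gain), .data$feature)
}

#' @rdname tidy.gbt_model
#' @export
glance.gbt_model <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$hyperparams), objective = x$objective,
                n_features = length(x$feature_names), seed = x$seed)
}

#' Tidy a leave-one-genotype-out prediction result
#'
#' @param x A `prediction_result`.
#' @param ... Unused.
#' @return The per-sample predictions tibble.
#' @export
tidy.prediction_result <- function(x, ...) x$predictions

#' @rdname tidy.prediction_result
#' @export
glance.prediction_result <- function(x, ...) {
  pooled <- summarize_performance(x, mode = "pooled")
  tibble::tibble(n_folds = length(x$importance), iterations = x$iterations,
                 n_features = length(x$features),
                 provenance = x$provenance %||% NA_character_,
                 pooled_mean_r = attr(pooled, "overall_mean_r"))
}

#' Tidy a variance partition
#'
#' @param x A `variance_partition`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.variance_partition <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.variance_partition
#' @export
glance.variance_partition <- function(x, ...) {
  tibble::tibble(ss_total = sum(x$ss),
                 genotype_fraction = x$fraction[x$term == "genotype"],
                 condition_fraction = x$fraction[x$term == "condition"],
                 interaction_fraction = x$fraction[x$term == "genotype:condition"])
}
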