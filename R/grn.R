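# Tree-ensemble regulatory-network inference: random-forest regression of
# each target on the regulator panel, variance-reduction edge weights,
# top-fraction pruning and connectivity (hub) ranking.

#' GRN inference parameters
#'
#' @param n_trees Trees per target forest (default 1000).
#' @param edge_fraction Fraction of candidate regulator-target pairs kept
#'   after pruning, in (0, 1].
#' @param mtry Regulators tried per split; default `sqrt(#regulators)`.
#' @param seed Seed.
#' @return A validated `grn_params` list.
#' @export
grn_params <- function(n_trees = 1000, edge_fraction = 0.01, mtry = NULL, seed = 1) {
  if (n_trees < 1) stop_value("n_trees must be >= 1.")
  if (edge_fraction <= 0 || edge_fraction > 1) stop_value("edge_fraction must be in (0, 1].")
  structure(list(n_trees = as.integer(n_trees), edge_fraction = edge_fraction,
                 mtry = mtry, seed = as.integer(seed)), class = "grn_params")
}

#' Infer a regulatory network from expression
#'
#' For each target gene, a random-forest regression of its (per-gene
#' standardized) expression on all regulators except itself; the edge
#' weight from regulator to target is the forest's impurity
#' (variance-reduction) importance, clamped at zero and normalized to sum
#' to one per target. Deterministic given the seed.
#'
#' @param expr Expression matrix (genes x samples), e.g. `log2(CPM + 1)`.
#' @param regulators Regulator (TF) gene IDs.
#' @param targets Target gene IDs.
#' @param params A [grn_params()] object.
#' @return A `grn_edges` tibble (regulator, target, weight) with attributes
#'   `n_candidate` (candidate pair count excluding self-pairs) and
#'   `pruned = FALSE`.
#' @export
infer_grn <- function(expr, regulators, targets, params = grn_params()) {
  if (length(regulators) == 0) stop_value("Regulator list is empty.")
  missing_ids <- setdiff(c(regulators, targets), rownames(expr))
  if (length(missing_ids) > 0) {
    stop_value(sprintf("Gene(s) absent from expression matrix: %s.",
                       paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  if (ncol(expr) < 5) stop_size("Network inference needs >= 5 samples.")
  z <- t(apply(expr[unique(c(regulators, targets)), , drop = FALSE], 1, function(v) {
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else v * 0
  }))
  seeds <- derive_seeds(params$seed, length(targets))
  edges <- purrr::map_dfr(seq_along(targets), function(ti) {
    tg <- targets[ti]
    preds <- setdiff(regulators, tg)
    if (length(preds) == 0) {
      stop_value(sprintf("No regulator left for target '%s' after removing self.", tg))
    }
    X <- as.data.frame(t(z[preds, , drop = FALSE]))
    fit <- ranger::ranger(
      x = X, y = z[tg, ], num.trees = params$n_trees,
      mtry = params$mtry %||% max(1L, floor(sqrt(length(preds)))),
      importance = "impurity", seed = seeds[ti], num.threads = 1,
      verbose = FALSE
    )
    w <- pmax(fit$variable.importance, 0)
    if (sum(w) > 0) w <- w / sum(w)
    tibble::tibble(regulator = preds, target = tg, weight = unname(w))
  })
  n_candidate <- length(regulators) * length(targets) - sum(targets %in% regulators)
  structure(edges, class = c("grn_edges", class(edges)),
            regulators = regulators, targets = targets,
            n_candidate = n_candidate, pruned = FALSE)
}

#' Keep the top fraction of network edges
#'
#' Retains the `ceiling(fraction * n_candidate)` highest-weight edges,
#' where `n_candidate` counts all regulator-by-target pairs minus
#' self-pairs. Ties at the cutoff are broken by (regulator, target) ID so
#' the retained set is deterministic.
#'
#' @param edges A `grn_edges` tibble from [infer_grn()].
#' @param fraction Fraction of candidate pairs to keep (default 0.01).
#' @return Pruned `grn_edges`, attributes updated.
#' @export
prune_top_fraction <- function(edges, fraction = 0.01) {
  if (nrow(edges) == 0) stop_value("Edge list is empty.")
  n_candidate <- attr(edges, "n_candidate") %||% nrow(edges)
  n_keep <- ceiling(fraction * n_candidate)
  if (n_keep < 1) stop_value("Requested fraction keeps zero edges.")
  ord <- order(-edges$weight, edges$regulator, edges$target)
  out <- edges[ord[seq_len(min(n_keep, nrow(edges)))], ]
  attr(out, "regulators") <- attr(edges, "regulators")
  attr(out, "targets") <- attr(edges, "targets")
  attr(out, "n_candidate") <- n_candidate
  attr(out, "pruned") <- TRUE
  attr(out, "fraction") <- fraction
  out
}

#' Rank regulators by connectivity
#'
#' Connectivity is a regulator's out-degree in the (pruned) network;
#' regulators with no retained edge get connectivity zero when the
#' regulator panel is known.
#'
#' @param edges A `grn_edges` tibble (normally pruned).
#' @param regulators Optional regulator panel; defaults to the panel
#'   recorded on `edges`.
#' @return A `tf_rank` tibble: regulator, connectivity, rank (ties by ID).
#' @export
connectivity_ranking <- function(edges, regulators = NULL) {
  regulators <- regulators %||% attr(edges, "regulators") %||% unique(edges$regulator)
  deg <- table(factor(edges$regulator, levels = regulators))
  out <- tibble::tibble(regulator = regulators, connectivity = as.integer(deg[regulators]))
  out <- dplyr::arrange(out, dplyr::desc(.data$connectivity), .data$regulator)
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("tf_rank", class(out)))
}

#' Integrate importance and connectivity rankings into a candidate report
#'
#' Decision-support table listing each regulator's rank in the aggregated
#' model-importance table (where the TF is itself a model feature) and in
#' the network connectivity ranking, flagging TFs in the top `top_fraction`
#' of either list.
#'
#' @param importance An `importance_table`.
#' @param tf_ranks A `tf_rank` table.
#' @param regulators Regulator panel.
#' @param top_fraction Quantile defining "top" (default 0.1).
#' @return Tibble: regulator, importance_rank, connectivity_rank, flag in
#'   `both` / `importance_only` / `grn_only`; empty (with a warning) when
#'   no TF qualifies.
#' @export
integrate_candidates <- function(importance, tf_ranks, regulators, top_fraction = 0.1) {
  imp_cut <- ceiling(top_fraction * nrow(importance))
  grn_cut <- ceiling(top_fraction * nrow(tf_ranks))
  out <- tibble::tibble(regulator = regulators)
  out$importance_rank <- importance$rank[match(out$regulator, importance$gene)]
  out$connectivity_rank <- tf_ranks$rank[match(out$regulator, tf_ranks$regulator)]
  top_imp <- !is.na(out$importance_rank) & out$importance_rank <= imp_cut
  top_grn <- !is.na(out$connectivity_rank) & out$connectivity_rank <= grn_cut
  out$flag <- dplyr::case_when(
    top_imp & top_grn ~ "both",
    top_imp ~ "importance_only",
    top_grn ~ "grn_only",
    TRUE ~ NA_character_
  )
  out$best_rank <- pmin(out$importance_rank, out$connectivity_rank, na.rm = TRUE)
  out <- out[!is.na(out$flag), , drop = FALSE]
  if (nrow(out) == 0) rlang::warn("No regulator passes the candidate criteria.")
  dplyr::arrange(out, .data$flag, .data$best_rank)
}
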