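# Gradient-boosted trait prediction with genotype-level leave-one-out
# evaluation, internal CV hyperparameter tuning, multi-iteration scoring,
# feature-set benchmarking and importance aggregation.

#' Hyperparameter row constructor
#'
#' @param nrounds Number of trees (>= 1).
#' @param eta Learning rate in (0, 1].
#' @param subsample Row-subsampling fraction in (0, 1].
#' @param colsample_bytree Per-tree feature-subsampling fraction in (0, 1].
#' @param max_depth Maximum tree depth (>= 1).
#' @return One-row tibble of class `hyperparams`.
#' @export
hyperparams <- function(nrounds = 100, eta = 0.1, subsample = 1, colsample_bytree = 1,
                        max_depth = 3) {
  if (nrounds < 1 || max_depth < 1) stop_value("nrounds and max_depth must be >= 1.")
  if (eta <= 0 || eta > 1 || subsample <= 0 || subsample > 1 ||
      colsample_bytree <= 0 || colsample_bytree > 1) {
    stop_value("eta, subsample and colsample_bytree must lie in (0, 1].")
  }
  structure(tibble::tibble(nrounds = as.integer(nrounds), eta = eta, subsample = subsample,
                           colsample_bytree = colsample_bytree, max_depth = as.integer(max_depth)),
            class = c("hyperparams", class(tibble::tibble())))
}

#' Default tuning grid
#'
#' A small, honest grid over the four tuned knobs (number of trees,
#' learning rate, row subsampling, per-tree column subsampling) plus tree
#' depth.
#'
#' @return Tibble of candidate hyperparameter rows.
#' @export
default_hyperparam_grid <- function() {
  tidyr::expand_grid(nrounds = c(50L, 100L, 200L), eta = c(0.05, 0.1, 0.3),
                     subsample = c(0.7, 1.0), colsample_bytree = c(0.5, 1.0),
                     max_depth = c(2L, 3L))
}

xgb_params <- function(hp, seed, objective) {
  list(objective = objective, eta = hp$eta, max_depth = hp$max_depth,
       subsample = hp$subsample, colsample_bytree = hp$colsample_bytree,
       seed = as.integer(seed), nthread = 1)
}

#' Tune hyperparameters by internal k-fold cross-validation
#'
#' Returns the grid row minimizing mean CV squared error. For efficiency,
#' grid rows sharing everything but `nrounds` are scored from one boosting
#' run truncated at each candidate round count. Deterministic given `seed`
#' (fold assignment and boosting randomness both derive from it); ties are
#' broken by grid order.
#'
#' @param X Sample-by-feature numeric matrix.
#' @param y Response vector.
#' @param grid Candidate rows, e.g. [default_hyperparam_grid()].
#' @param folds Number of internal CV folds (default 5).
#' @param seed Seed.
#' @param groups Optional grouping labels (one per sample, e.g. genotype):
#'   CV folds then split whole groups, so tuning scores cross-group
#'   transfer instead of within-group memorization — the same logic as the
#'   outer leave-one-genotype-out protocol.
#' @param objective XGBoost objective.
#' @return The selected row as a `hyperparams` tibble, with the CV score in
#'   attribute `cv_mse`.
#' @export
tune_hyperparameters <- function(X, y, grid = default_hyperparam_grid(), folds = 5, seed = 1,
                                 groups = NULL, objective = "reg:squarederror") {
  if (nrow(grid) == 0) stop_value("Empty hyperparameter grid.")
  if (nrow(X) < folds) {
    stop_size(sprintf("Fewer samples (%d) than CV folds (%d).", nrow(X), folds))
  }
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 1) {
    out <- do.call(hyperparams, as.list(grid))
    attr(out, "cv_mse") <- NA_real_
    return(out)
  }
  fold_id <- if (is.null(groups)) {
    withr::with_seed(seed, sample(rep_len(seq_len(folds), nrow(X))))
  } else {
    lev <- unique(as.character(groups))
    if (length(lev) < 2) stop_size("Grouped CV needs at least 2 groups.")
    if (length(lev) < folds) {
      # small panels: one fold per group rather than failing
      folds <- length(lev)
    }
    grp_fold <- withr::with_seed(seed, sample(rep_len(seq_len(folds), length(lev))))
    grp_fold[match(as.character(groups), lev)]
  }
  combos <- dplyr::distinct(grid[, c("eta", "subsample", "colsample_bytree", "max_depth")])
  seeds <- derive_seeds(seed, nrow(combos) * folds)
  scores <- purrr::map_dfr(seq_len(nrow(combos)), function(ci) {
    combo <- combos[ci, ]
    rounds <- sort(unique(grid$nrounds[
      grid$eta == combo$eta & grid$subsample == combo$subsample &
        grid$colsample_bytree == combo$colsample_bytree & grid$max_depth == combo$max_depth
    ]))
    err <- matrix(0, folds, length(rounds))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr], nthread = 1)
      bst <- xgboost::xgb.train(
        params = xgb_params(combo, seeds[(ci - 1) * folds + f], objective),
        data = dtr, nrounds = max(rounds), verbose = 0
      )
      dte <- xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], nthread = 1)
      for (ri in seq_along(rounds)) {
        pred <- stats::predict(bst, dte, iterationrange = c(1, rounds[ri]))
        err[f, ri] <- mean((pred - y[!tr])^2)
      }
    }
    dplyr::mutate(combo, nrounds = list(rounds), mse = list(colMeans(err)))
  })
  scored <- tidyr::unnest(scores, c("nrounds", "mse"))
  # respect original grid order for deterministic tie-breaks
  key <- function(d) paste(d$nrounds, d$eta, d$subsample, d$colsample_bytree, d$max_depth)
  scored <- scored[match(key(grid), key(scored)), ]
  best <- which.min(scored$mse)
  out <- do.call(hyperparams, as.list(grid[best, ]))
  attr(out, "cv_mse") <- scored$mse[best]
  out
}

#' Fit a gradient-boosted tree model
#'
#' @param X Sample-by-feature matrix (no missing values).
#' @param y Response.
#' @param hp A [hyperparams()] row.
#' @param seed Seed controlling row/column subsampling.
#' @param objective XGBoost objective (`"reg:squarederror"` for traits,
#'   `"binary:logistic"` for outcome classification).
#' @return A `gbt_model`: the booster plus a full per-feature gain vector
#'   (zero for features never split on).
#' @export
fit_gbt <- function(X, y, hp = hyperparams(), seed = 1, objective = "reg:squarederror") {
  if (nrow(X) < 2) stop_size("Need at least 2 training samples.")
  if (anyNA(X)) stop_value("Feature matrix contains missing values.")
  d <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  bst <- xgboost::xgb.train(params = xgb_params(hp, seed, objective), data = d,
                            nrounds = hp$nrounds, verbose = 0)
  gain <- stats::setNames(numeric(ncol(X)), colnames(X))
  imp <- tryCatch(xgboost::xgb.importance(model = bst), error = function(e) NULL)
  if (!is.null(imp) && nrow(imp) > 0) gain[imp$Feature] <- imp$Gain
  structure(list(booster = bst, importance = gain, hyperparams = hp, seed = seed,
                 objective = objective, feature_names = colnames(X)),
            class = "gbt_model")
}

#' @export
predict.gbt_model <- function(object, newdata, ...) {
  stats::predict(object$booster,
                 xgboost::xgb.DMatrix(newdata[, object$feature_names, drop = FALSE], nthread = 1),
                 ...)
}

log2_cpm <- function(counts) log2(compute_cpm(counts) + 1)

#' Leave-one-genotype-out trait prediction
#'
#' For each genotype g: hyperparameters are tuned by internal CV on the
#' training genotypes (never g), a model is fitted and g's samples are
#' predicted; the whole loop is repeated `iterations` times with
#' iteration-specific seeds varying the boosting randomness. Tuning runs
#' once per fold (`tune = "per_fold"`, leakage-safe default) or once on the
#' first fold's training data (`tune = "once"`). Model inputs are
#' `log2(CPM + 1)`.
#'
#' @param counts Count matrix (genes x samples).
#' @param metadata Matched sample metadata.
#' @param phenotypes Tibble with `sample_id` and the trait column; rows
#'   with non-finite trait are excluded (logged).
#' @param trait Trait column name.
#' @param features A [feature_set()] or character vector of gene IDs; all
#'   must be present in `counts`.
#' @param iterations Repetitions (default 100).
#' @param seed Master seed.
#' @param grid Tuning grid.
#' @param tune `"per_fold"` or `"once"`.
#' @param objective XGBoost objective.
#' @return A `prediction_result`: `predictions` tibble (genotype,
#'   iteration, sample_id, predicted, observed), per-fold mean importance
#'   vectors, chosen hyperparameters per fold, seeds.
#' @export
loo_predict <- function(counts, metadata, phenotypes, trait = "trait", features,
                        iterations = 100, seed = 1, grid = default_hyperparam_grid(),
                        tune = c("per_fold", "once"), objective = "reg:squarederror") {
  tune <- match.arg(tune)
  metadata <- validate_metadata(metadata, counts, two_condition = FALSE)
  genes <- if (inherits(features, "feature_set")) features$genes else unique(as.character(features))
  missing_genes <- setdiff(genes, rownames(counts))
  if (length(missing_genes) > 0) {
    stop_value(sprintf("Feature(s) absent from expression matrix: %s.",
                       paste(utils::head(missing_genes, 5), collapse = ", ")))
  }
  phenotypes <- tibble::as_tibble(phenotypes)
  if (!trait %in% names(phenotypes)) {
    stop_lookup(sprintf("Trait '%s' not found in phenotype table.", trait))
  }
  ph <- dplyr::inner_join(metadata[, c("sample_id", "genotype")],
                          phenotypes[, c("sample_id", trait)], by = "sample_id")
  ph$y <- as.numeric(ph[[trait]])
  dropped <- sum(!is.finite(ph$y))
  if (dropped > 0) {
    rlang::inform(sprintf("loo_predict: excluding %d sample(s) with missing '%s'.", dropped, trait),
                  class = "evotrait_log")
    ph <- ph[is.finite(ph$y), , drop = FALSE]
  }
  genotypes <- unique(as.character(metadata$genotype))
  no_pheno <- setdiff(genotypes, ph$genotype)
  if (length(no_pheno) > 0) {
    stop_design(sprintf("Genotype(s) without phenotyped samples: %s.",
                        paste(no_pheno, collapse = ", ")))
  }

  expr <- t(log2_cpm(counts)[genes, , drop = FALSE])
  nfold <- length(genotypes)
  seeds <- matrix(derive_seeds(seed, nfold * (iterations + 1)), nfold)
  hp_once <- NULL
  preds <- vector("list", nfold)
  imps <- vector("list", nfold)
  hps <- vector("list", nfold)
  for (fi in seq_len(nfold)) {
    g <- genotypes[fi]
    tr <- ph[ph$genotype != g, ]
    te <- ph[ph$genotype == g, ]
    Xtr <- expr[tr$sample_id, , drop = FALSE]
    Xte <- expr[te$sample_id, , drop = FALSE]
    hp <- if (tune == "once") {
      if (is.null(hp_once)) {
        hp_once <- tune_hyperparameters(Xtr, tr$y, grid, seed = seeds[fi, 1],
                                        groups = tr$genotype, objective = objective)
      }
      hp_once
    } else {
      tune_hyperparameters(Xtr, tr$y, grid, seed = seeds[fi, 1],
                           groups = tr$genotype, objective = objective)
    }
    hp_row <- tibble::as_tibble(hp)
    attr(hp_row, "cv_mse") <- NULL
    hps[[fi]] <- dplyr::mutate(hp_row, genotype = g, .before = 1)
    gain_sum <- stats::setNames(numeric(length(genes)), genes)
    fold_preds <- vector("list", iterations)
    for (it in seq_len(iterations)) {
      model <- fit_gbt(Xtr, tr$y, hp, seed = seeds[fi, it + 1], objective = objective)
      fold_preds[[it]] <- tibble::tibble(
        genotype = g, iteration = it, sample_id = te$sample_id,
        predicted = as.numeric(predict(model, Xte)), observed = te$y
      )
      gain_sum <- gain_sum + model$importance
    }
    preds[[fi]] <- dplyr::bind_rows(fold_preds)
    imps[[fi]] <- gain_sum / iterations
  }
  names(imps) <- genotypes
  structure(list(
    predictions = dplyr::bind_rows(preds), importance = imps,
    hyperparams = dplyr::bind_rows(hps), features = genes, iterations = iterations,
    seed = seed, trait = trait, tune = tune,
    provenance = if (inherits(features, "feature_set")) features$provenance else NA_character_
  ), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %d folds x %d iterations, %d features (%s), trait '%s'\n",
              length(x$importance), x$iterations, length(x$features),
              x$provenance %||% "unspecified", x$trait))
  invisible(x)
}

#' Summarize predictive performance
#'
#' Per-genotype mode computes Pearson r for every (genotype, iteration)
#' pair of predicted vs observed values, then mean and SD over iterations
#' per genotype; it needs >= 3 test values per fold. Pooled mode pools all
#' iterations' (predicted, observed) pairs within a genotype into a single
#' r, for designs with too few test points per fold.
#'
#' @param result A `prediction_result`.
#' @param mode `"per_genotype"` or `"pooled"`.
#' @return A `performance_summary` tibble (genotype, mean_r, sd_r, n_test)
#'   with attributes `overall_mean_r` and `mode`.
#' @export
summarize_performance <- function(result, mode = c("per_genotype", "pooled")) {
  mode <- match.arg(mode)
  pr <- result$predictions
  n_test <- dplyr::summarise(dplyr::group_by(pr[pr$iteration == 1, ], .data$genotype),
                             n = dplyr::n())
  if (mode == "per_genotype") {
    if (any(n_test$n < 3)) {
      stop_mode("per_genotype mode needs >= 3 test values per fold; consider mode = 'pooled'.")
    }
    per_it <- dplyr::summarise(
      dplyr::group_by(pr, .data$genotype, .data$iteration),
      r = suppressWarnings(stats::cor(.data$predicted, .data$observed)), .groups = "drop"
    )
    out <- dplyr::summarise(
      dplyr::group_by(per_it, .data$genotype),
      mean_r = mean(.data$r, na.rm = TRUE), sd_r = stats::sd(.data$r, na.rm = TRUE),
      .groups = "drop"
    )
  } else {
    if (nrow(pr) < 3) stop_mode("pooled mode needs >= 3 prediction records.")
    out <- dplyr::summarise(
      dplyr::group_by(pr, .data$genotype),
      mean_r = suppressWarnings(stats::cor(.data$predicted, .data$observed)),
      sd_r = NA_real_, .groups = "drop"
    )
  }
  out <- dplyr::left_join(out, n_test, by = "genotype")
  out <- dplyr::rename(out, n_test = "n")
  structure(out, class = c("performance_summary", class(out)),
            overall_mean_r = mean(out$mean_r, na.rm = TRUE), mode = mode,
            provenance = result$provenance)
}

#' Benchmark feature sets against each other
#'
#' Pairwise one-tailed Mann-Whitney U tests on the per-genotype r values
#' (alternative: row set better than column set). Exact enumeration when
#' both groups have <= 10 values and no ties; normal approximation with tie
#' and continuity correction otherwise.
#'
#' @param summaries Named list of `performance_summary` objects.
#' @return Tibble: set_a, set_b, mean_r_a, mean_r_b, statistic (U), p_value,
#'   method.
#' @export
compare_feature_sets <- function(summaries) {
  if (length(summaries) < 2) stop_value("Need >= 2 feature sets to compare.")
  if (is.null(names(summaries)) || any(!nzchar(names(summaries)))) {
    stop_value("`summaries` must be a named list.")
  }
  rs <- purrr::map(summaries, function(s) {
    r <- s$mean_r[is.finite(s$mean_r)]
    if (length(r) < 2) stop_value("A feature set has fewer than 2 finite r values.")
    r
  })
  combos <- tidyr::expand_grid(set_a = names(rs), set_b = names(rs))
  combos <- combos[combos$set_a != combos$set_b, ]
  purrr::pmap_dfr(combos, function(set_a, set_b) {
    x <- rs[[set_a]]; y <- rs[[set_b]]
    exact <- length(x) <= 10 && length(y) <= 10 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater", exact = exact, correct = TRUE)
    )
    tibble::tibble(set_a = set_a, set_b = set_b,
                   mean_r_a = mean(x), mean_r_b = mean(y),
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   method = if (exact) "exact" else "normal_approx")
  })
}

#' Aggregate feature importance across genotype models
#'
#' Sums each gene's mean (over iterations) gain across all genotype folds,
#' counts the folds where the gene received positive importance, and ranks
#' descending (ties by gene ID). Supplying `universe` extends the table
#' with genes the models never saw (importance 0, last ranks), so ranks are
#' interpretable against a reference gene universe.
#'
#' @param result A `prediction_result`.
#' @param universe Optional gene universe to rank within.
#' @return An `importance_table` tibble: gene, importance, shared_count,
#'   rank.
#' @export
aggregate_importance <- function(result, universe = NULL) {
  mat <- do.call(cbind, result$importance)
  tbl <- tibble::tibble(
    gene = rownames(mat),
    importance = unname(rowSums(mat)),
    shared_count = as.integer(rowSums(mat > 0))
  )
  if (!is.null(universe)) {
    extra <- setdiff(universe, tbl$gene)
    if (length(extra) > 0) {
      tbl <- dplyr::bind_rows(tbl, tibble::tibble(gene = extra, importance = 0,
                                                  shared_count = 0L))
    }
  }
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$importance), .data$gene)
  tbl$rank <- seq_len(nrow(tbl))
  structure(tbl, class = c("importance_table", class(tbl)),
            n_models = length(result$importance))
}

#' Spearman rank correlation between two gene rankings
#'
#' @param rank_a,rank_b Named numeric vectors of ranks (or scores) over a
#'   shared gene universe; unnamed vectors of equal length are matched by
#'   position.
#' @return Spearman rho (average-rank tie handling).
#' @export
rank_correlation <- function(rank_a, rank_b) {
  if (!is.null(names(rank_a)) && !is.null(names(rank_b))) {
    shared <- intersect(names(rank_a), names(rank_b))
    if (length(shared) < 3) stop_value("Fewer than 3 shared genes between rankings.")
    rank_a <- rank_a[shared]; rank_b <- rank_b[shared]
  } else if (length(rank_a) != length(rank_b) || length(rank_a) < 3) {
    stop_value("Unnamed rankings must have equal length >= 3.")
  }
  stats::cor(rank_a, rank_b, method = "spearman")
}
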