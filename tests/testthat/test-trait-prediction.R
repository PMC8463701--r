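test_that("tuning: identity on one-point grids, determinism, and signal beats stump count 1", {
  X <- withr::with_seed(2, matrix(rnorm(60 * 8), 60, 8,
                                  dimnames = list(NULL, paste0("f", 1:8))))
  y <- ifelse(X[, 1] > 0, 5, -5) # noiseless tree-friendly step of feature 1
  one <- hyperparams(nrounds = 7, eta = 0.2)
  expect_equal(tune_hyperparameters(X, y, one, seed = 1)$nrounds, 7L)
  grid <- dplyr::bind_rows(hyperparams(nrounds = 1, eta = 0.01),
                           hyperparams(nrounds = 50, eta = 0.3))
  pick1 <- tune_hyperparameters(X, y, grid, seed = 3)
  pick2 <- tune_hyperparameters(X, y, grid, seed = 3)
  expect_identical(pick1, pick2)
  expect_gt(pick1$nrounds, 1)
  expect_error(tune_hyperparameters(X[1:3, ], y[1:3], grid, folds = 5),
               class = "evotrait_size_error")
})

test_that("gradient-boosted fits: constants, dominant features, determinism", {
  X <- withr::with_seed(5, matrix(rnorm(80 * 51), 80, 51,
                                  dimnames = list(NULL, paste0("f", 1:51))))
  hp <- hyperparams(nrounds = 60, eta = 0.3)

  m0 <- fit_gbt(X, rep(3.5, 80), hp, seed = 1)
  expect_true(all(abs(predict(m0, X) - 3.5) < 1e-6))
  expect_true(all(m0$importance == 0))

  y <- X[, 1] + withr::with_seed(6, rnorm(80, 0, 0.05))
  m1 <- fit_gbt(X, y, hp, seed = 1)
  expect_equal(names(which.max(m1$importance)), "f1")
  expect_true(all(m1$importance >= 0))

  m2 <- fit_gbt(X, y, hyperparams(nrounds = 40, eta = 0.2, subsample = 0.7,
                                  colsample_bytree = 0.5), seed = 9)
  m3 <- fit_gbt(X, y, hyperparams(nrounds = 40, eta = 0.2, subsample = 0.7,
                                  colsample_bytree = 0.5), seed = 9)
  expect_identical(predict(m2, X), predict(m3, X))

  expect_error(fit_gbt(X[1, , drop = FALSE], y[1], hp), class = "evotrait_size_error")
})

# Shared LOO prediction on a small bundle (causal features vs pure noise).
tp_bundle <- easy_bundle(43)
tp_sp <- tp_bundle$species_a
tp_features <- tp_bundle$truth$conserved_pairs$gene_a
tp_result <- suppressMessages(loo_predict(
  tp_sp$counts, tp_sp$metadata, tp_sp$phenotypes, trait = "trait",
  features = tp_features, iterations = 3, seed = 11, grid = small_grid()
))

test_that("leave-one-genotype-out bookkeeping and predictive signal", {
  n_g <- length(unique(tp_sp$metadata$genotype))
  expect_equal(dplyr::n_distinct(tp_result$predictions$genotype), n_g)
  expect_equal(dplyr::n_distinct(tp_result$predictions$iteration), 3)
  # each fold's test rows are exactly that genotype's samples
  for (g in unique(tp_result$predictions$genotype)) {
    rows <- tp_result$predictions[tp_result$predictions$genotype == g, ]
    expect_setequal(unique(rows$sample_id),
                    tp_sp$metadata$sample_id[tp_sp$metadata$genotype == g])
  }
  perf <- summarize_performance(tp_result, "per_genotype")
  expect_gt(attr(perf, "overall_mean_r"), 0.5) # causal features predict the trait
  expect_true(all(perf$mean_r >= -1 & perf$mean_r <= 1))
  expect_true(all(perf$sd_r >= 0, na.rm = TRUE))
})

test_that("a pure-noise trait yields correlations near zero", {
  noisy <- tp_sp$phenotypes
  noisy$trait <- withr::with_seed(3, rnorm(nrow(noisy), 40, 5))
  res <- suppressMessages(loo_predict(tp_sp$counts, tp_sp$metadata, noisy,
                                      features = tp_features, iterations = 2,
                                      seed = 4, grid = small_grid()))
  perf <- summarize_performance(res, "per_genotype")
  expect_lt(abs(mean(perf$mean_r)), 0.3)
})

test_that("missing features are named; missing phenotypes are excluded explicitly", {
  err <- tryCatch(
    loo_predict(tp_sp$counts, tp_sp$metadata, tp_sp$phenotypes,
                features = c(tp_features[1], "nonexistent_gene"), iterations = 1,
                seed = 1, grid = small_grid()),
    error = identity
  )
  expect_s3_class(err, "evotrait_value_error")
  expect_match(conditionMessage(err), "nonexistent_gene")

  gone <- tp_sp$phenotypes
  gone$trait[gone$genotype == gone$genotype[1]] <- NA
  expect_error(
    suppressMessages(loo_predict(tp_sp$counts, tp_sp$metadata, gone,
                                 features = tp_features[1:3], iterations = 1,
                                 seed = 1, grid = small_grid())),
    class = "evotrait_design_error"
  )
})

test_that("performance summaries: exact r values and mode preconditions", {
  mk <- function(pred, obs) {
    structure(list(predictions = tibble::tibble(
      genotype = "g1", iteration = 1L, sample_id = paste0("s", seq_along(pred)),
      predicted = pred, observed = obs
    ), importance = list(g1 = c(a = 1)), iterations = 1L, provenance = NA_character_),
    class = "prediction_result")
  }
  expect_equal(summarize_performance(mk(1:4, 1:4), "per_genotype")$mean_r, 1)
  expect_equal(summarize_performance(mk(-(1:4), 1:4), "per_genotype")$mean_r, -1)
  # hand product-moment computation for pred (1,2,3,5) vs obs (1,2,4,5)
  p <- c(1, 2, 3, 5); o <- c(1, 2, 4, 5)
  r_hand <- sum((p - mean(p)) * (o - mean(o))) /
    sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
  expect_equal(summarize_performance(mk(p, o), "per_genotype")$mean_r, r_hand)
  expect_error(summarize_performance(mk(1:2, 2:1), "per_genotype"),
               class = "evotrait_mode_error")
  expect_equal(summarize_performance(mk(p, o), "pooled")$mean_r, r_hand)
})

test_that("Pearson r is invariant to positive affine transforms of predictions", {
  shifted <- tp_result
  shifted$predictions$predicted <- 3 + 2 * shifted$predictions$predicted
  expect_equal(summarize_performance(shifted, "per_genotype")$mean_r,
               summarize_performance(tp_result, "per_genotype")$mean_r)
})

test_that("feature-set comparison: exact Mann-Whitney enumeration and edge cases", {
  mk_sum <- function(r) {
    structure(tibble::tibble(genotype = paste0("g", seq_along(r)), mean_r = r,
                             sd_r = 0, n_test = 3L),
              class = c("performance_summary", "tbl_df", "tbl", "data.frame"))
  }
  out <- compare_feature_sets(list(A = mk_sum(c(3, 4, 5)), B = mk_sum(c(1, 2))))
  row <- out[out$set_a == "A" & out$set_b == "B", ]
  expect_equal(row$statistic, 6)
  expect_equal(row$p_value, 0.1) # 1 / choose(5, 2), enumerated below
  # independent enumeration over all rank assignments
  combos <- utils::combn(5, 2)
  u_obs <- 6
  u_all <- apply(combos, 2, function(ix) sum(outer(setdiff(1:5, ix), ix, ">")))
  expect_equal(mean(u_all >= u_obs), 0.1)
  expect_equal(row$method, "exact")

  same <- compare_feature_sets(list(A = mk_sum(c(1, 2, 3)), B = mk_sum(c(1, 2, 3))))
  expect_true(all(same$p_value >= 0.5))
  expect_true(all(same$method == "normal_approx")) # ties force the approximation
  expect_error(compare_feature_sets(list(A = mk_sum(1), B = mk_sum(c(1, 2)))),
               class = "evotrait_value_error")
  expect_error(compare_feature_sets(list(mk_sum(1:3), mk_sum(1:3))),
               class = "evotrait_value_error")
})

test_that("importance aggregation sums fold means, counts sharing, ranks universe", {
  res <- structure(list(importance = list(
    f1 = c(gene_a = 0.1, gene_b = 0.05, gene_c = 0),
    f2 = c(gene_a = 0.2, gene_b = 0, gene_c = 0),
    f3 = c(gene_a = 0, gene_b = 0.5, gene_c = 0)
  )), class = "prediction_result")
  tab <- aggregate_importance(res)
  expect_equal(tab$importance[tab$gene == "gene_a"], 0.3)
  expect_equal(tab$shared_count[tab$gene == "gene_a"], 2L)
  expect_equal(tab$shared_count[tab$gene == "gene_c"], 0L)
  expect_equal(tab$rank, seq_len(nrow(tab)))
  # never-used genes from the universe get zero importance and last ranks
  tab2 <- aggregate_importance(res, universe = c("gene_a", "gene_b", "gene_c", "gene_z"))
  expect_equal(tab2$importance[tab2$gene == "gene_z"], 0)
  expect_gte(tab2$rank[tab2$gene == "gene_z"], 3)
})

test_that("Spearman rank correlation matches the d-squared formula", {
  expect_equal(rank_correlation(c(a = 1, b = 2, c = 3), c(a = 1, b = 2, c = 3)), 1)
  expect_equal(rank_correlation(c(a = 1, b = 2, c = 3), c(a = 3, b = 2, c = 1)), -1)
  a <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  b <- c(g1 = 2, g2 = 1, g3 = 4, g4 = 3)
  d2 <- sum((a - b)^2)
  expect_equal(rank_correlation(a, b), 1 - 6 * d2 / (4 * (16 - 1))) # = 0.6
  expect_equal(rank_correlation(a, b), 0.6)
  expect_error(rank_correlation(c(x = 1, y = 2), c(x = 2, y = 1)),
               class = "evotrait_value_error")
})

test_that("mutating the held-out genotype leaves its fold's model untouched", {
  g <- names(tp_result$importance)[1]
  counts2 <- tp_sp$counts
  idx <- tp_sp$metadata$sample_id[tp_sp$metadata$genotype == g]
  counts2[, idx] <- withr::with_seed(8, matrix(
    rpois(nrow(counts2) * length(idx), 300), nrow(counts2)))
  ph2 <- tp_sp$phenotypes
  ph2$trait[ph2$genotype == g] <- 999
  res2 <- suppressMessages(loo_predict(counts2, tp_sp$metadata, ph2,
                                       features = tp_features, iterations = 3,
                                       seed = 11, grid = small_grid()))
  expect_identical(res2$importance[[g]], tp_result$importance[[g]])
  expect_identical(res2$hyperparams[res2$hyperparams$genotype == g, ],
                   tp_result$hyperparams[tp_result$hyperparams$genotype == g, ])
})
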