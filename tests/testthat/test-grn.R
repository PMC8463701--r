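grn_net <- simulate_linear_network(n_regulators = 12, n_targets = 25, n_edges = 6,
                                   n_samples = 60, noise_sd = 0.5, seed = 21)
grn_edges_full <- infer_grn(grn_net$expr, grn_net$regulators, grn_net$targets,
                            grn_params(n_trees = 300, seed = 2))

test_that("edge weights are per-target normalized and self-edges excluded", {
  sums <- tapply(grn_edges_full$weight, grn_edges_full$target, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(grn_edges_full$weight >= 0))
  expect_false(any(grn_edges_full$regulator == grn_edges_full$target))

  # a TF that is also a target never gets a self-edge
  expr <- grn_net$expr
  both <- c(grn_net$regulators[1:5], grn_net$regulators[1])
  e2 <- infer_grn(expr, grn_net$regulators[1:5], c(grn_net$regulators[1], grn_net$targets[1:3]),
                  grn_params(n_trees = 100, seed = 3))
  expect_false(any(e2$regulator == e2$target))
})

test_that("the true parent gets the top weight for a strongly driven target", {
  wired <- grn_net$true_edges[1, ]
  sub <- grn_edges_full[grn_edges_full$target == wired$target, ]
  expect_equal(sub$regulator[which.max(sub$weight)], wired$regulator)
})

test_that("network inference is deterministic given a seed", {
  again <- infer_grn(grn_net$expr, grn_net$regulators, grn_net$targets,
                     grn_params(n_trees = 300, seed = 2))
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(grn_edges_full))
})

test_that("top-fraction pruning counts candidate pairs and breaks ties lexically", {
  # 12 regulators x 25 targets, no overlap -> 300 candidate pairs
  expect_equal(attr(grn_edges_full, "n_candidate"), 300)
  pruned <- prune_top_fraction(grn_edges_full, 0.01)
  expect_equal(nrow(pruned), ceiling(0.01 * 300))
  all_kept <- prune_top_fraction(grn_edges_full, 1.0)
  expect_equal(nrow(all_kept), nrow(grn_edges_full))
  # monotone: smaller fraction is a subset of larger
  p5 <- prune_top_fraction(grn_edges_full, 0.05)
  key <- function(d) paste(d$regulator, d$target)
  expect_true(all(key(pruned) %in% key(p5)))

  tied <- structure(tibble::tibble(
    regulator = c("tfB", "tfA", "tfC"), target = c("t1", "t1", "t2"),
    weight = c(0.5, 0.5, 0.9)
  ), n_candidate = 100, class = c("grn_edges", class(tibble::tibble())))
  kept <- prune_top_fraction(tied, 0.02) # keeps 2 of 3; tie at 0.5 -> tfA wins
  expect_setequal(key(kept), c("tfC t2", "tfA t1"))
})

test_that("connectivity ranking counts out-degrees with zero-edge regulators", {
  edges <- structure(tibble::tibble(
    regulator = c("tf1", "tf1", "tf2"), target = c("g1", "g2", "g1"), weight = 1
  ), class = c("grn_edges", class(tibble::tibble())))
  ranks <- connectivity_ranking(edges, regulators = c("tf1", "tf2", "tf3"))
  expect_equal(ranks$connectivity[ranks$regulator == "tf1"], 2L)
  expect_equal(ranks$rank[ranks$regulator == "tf1"], 1L)
  expect_equal(ranks$connectivity[ranks$regulator == "tf3"], 0L)
})

test_that("true edges are strongly enriched after pruning; hub is rank 1", {
  net <- simulate_linear_network(n_regulators = 20, n_targets = 40, n_edges = 10,
                                 n_samples = 80, noise_sd = 0.5, seed = 31)
  # plant a hub: one regulator drives 8 targets
  hub <- "tf001"
  hub_targets <- sprintf("tg%03d", 31:38)
  expr <- net$expr
  expr[hub_targets, ] <- 1.5 * matrix(rep(expr[hub, ], length(hub_targets)),
                                      nrow = length(hub_targets), byrow = TRUE) +
    withr::with_seed(4, matrix(rnorm(length(hub_targets) * ncol(expr), 0, 0.5),
                               length(hub_targets)))
  edges <- infer_grn(expr, net$regulators, net$targets, grn_params(n_trees = 300, seed = 5))
  pruned <- prune_top_fraction(edges, 0.02) # 16 of 800 pairs
  truth_keys <- paste(net$true_edges$regulator, net$true_edges$target)
  truth_keys <- c(truth_keys, paste(hub, hub_targets))
  precision <- mean(paste(pruned$regulator, pruned$target) %in% truth_keys)
  random_expectation <- length(truth_keys) / 800
  expect_gte(precision / random_expectation, 5)
  ranks <- connectivity_ranking(pruned)
  expect_equal(ranks$regulator[1], hub)
})

test_that("candidate integration flags top members of either ranking", {
  imp <- structure(tibble::tibble(gene = paste0("g", 1:20), importance = 20:1,
                                  shared_count = 1L, rank = 1:20),
                   class = c("importance_table", class(tibble::tibble())))
  tf <- structure(tibble::tibble(regulator = c("g1", "g19", "tfX", "tfY"),
                                 connectivity = c(5L, 4L, 3L, 0L), rank = 1:4),
                  class = c("tf_rank", class(tibble::tibble())))
  # cuts: importance top ceiling(0.5*20) = 10, connectivity top ceiling(0.5*4) = 2
  out <- integrate_candidates(imp, tf, regulators = c("g1", "g19", "tfX", "tfY"),
                              top_fraction = 0.5)
  expect_equal(out$flag[out$regulator == "g1"], "both")
  expect_equal(out$flag[out$regulator == "g19"], "grn_only") # importance rank 19 misses the cut
  expect_false("tfX" %in% out$regulator) # connectivity rank 3 misses; not a feature
  empty <- suppressWarnings(
    integrate_candidates(imp, tf, regulators = "absent_tf", top_fraction = 0.1)
  )
  expect_equal(nrow(empty), 0)
})
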