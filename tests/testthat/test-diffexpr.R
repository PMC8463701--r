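test_that("CPM is counts over library size times a million", {
  counts <- matrix(c(5, 10,
                     1e6 - 5, 2e6 - 10), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- compute_cpm(counts)
  expect_equal(cpm["g1", "s1"], 5)
  expect_equal(cpm["g1", "s2"], 5)
  zero <- matrix(c(1, 2, 0, 0), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  err <- tryCatch(compute_cpm(zero), error = identity)
  expect_s3_class(err, "evotrait_value_error")
  expect_match(conditionMessage(err), "s2")
})

test_that("expression filter respects the min-samples boundary exactly", {
  ns <- 12
  lib <- 1e6
  # gene "nine": CPM > 1 in 9 samples; gene "ten": in 10; "zero": never
  counts <- rbind(
    nine = c(rep(5, 9), rep(0, 3)),
    ten = c(rep(5, 10), rep(0, 2)),
    zero = rep(0, ns),
    filler = rep(lib, ns)
  )
  colnames(counts) <- sprintf("s%02d", 1:ns)
  kept <- suppressMessages(filter_expressed(counts, deg_params(min_samples = 10)))
  expect_false("nine" %in% rownames(kept))
  expect_true("ten" %in% rownames(kept))
  expect_false("zero" %in% rownames(kept))
  expect_equal(ncol(kept), ns)
})

test_that("upper-quartile offsets: symmetry, scaling, and a hand-computed toy", {
  ex <- sim_nb(1, n_genotypes = 2, n_rep = 2, n_genes = 100)
  counts <- ex$counts
  # identical samples get equal offsets
  dup <- cbind(counts, dup = counts[, 1])
  off <- upper_quartile_offsets(dup)
  expect_equal(unname(off["dup"]), unname(off[1]))
  # doubling one sample elementwise shifts its offset by log 2
  doubled <- counts
  doubled[, 2] <- counts[, 2] * 2
  colnames(doubled)[2] <- "twice"
  off1 <- upper_quartile_offsets(counts)
  off2 <- upper_quartile_offsets(doubled)
  expect_equal(unname(off2["twice"] - off1[2]), log(2), tolerance = 1e-12)

  # 4-sample toy with 5 nonzero counts per sample: with linear-interpolation
  # percentiles the 75th of 5 values is exactly the 4th order statistic, so
  # the UQs are 10, 10, 20, 40 by hand and exp(offset) must follow 1:1:2:4
  toy <- cbind(
    s1 = c(1, 2, 5, 10, 12),
    s2 = c(2, 3, 4, 10, 11),
    s3 = c(1, 2, 3, 20, 24),
    s4 = c(2, 3, 5, 40, 44)
  )
  rownames(toy) <- paste0("g", 1:5)
  offs <- upper_quartile_offsets(toy)
  expect_equal(exp(offs - offs[["s1"]]), c(s1 = 1, s2 = 1, s3 = 2, s4 = 4))
  # centering: mean offset equals mean log library size
  expect_equal(mean(offs), mean(log(colSums(toy))))
  # sample of all zeros
  bad <- toy
  bad[, 2] <- 0
  expect_error(compute_cpm(bad), class = "evotrait_value_error")
})

test_that("BH adjustment matches brute force and base behavior", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "evotrait_value_error")
  # property: equality with an independent brute-force BH on random vectors
  for (seed in 1:20) {
    p <- withr::with_seed(seed, round(runif(7), 3))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  # monotone in p and q >= p elementwise
  p <- withr::with_seed(99, runif(50))
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("NB GLM recovers planted condition effects and null coefficients", {
  ex <- sim_nb(7, n_genotypes = 4, n_rep = 3, n_genes = 400, responsive = 1:40,
               lfc = 2, phi = 0.1)
  res <- suppressMessages(call_degs(ex$counts, ex$metadata))
  called <- res$table[res$table$gene %in% ex$responsive, ]
  # |log2FC| = 2 planted (4-fold); recovered within 15%
  expect_equal(mean(abs(called$log2fc)), 2, tolerance = 0.15)
  # genes with no effect have coefficients near 0 on average
  nulls <- res$table[!res$table$gene %in% ex$responsive, ]
  expect_lt(abs(mean(nulls$log2fc)), 0.05)
})

test_that("dispersion estimates are near zero for Poisson data", {
  ex <- sim_nb(3, n_genotypes = 5, n_rep = 5, n_genes = 300, phi = 0)
  filtered <- suppressMessages(filter_expressed(ex$counts, deg_params()))
  fit <- fit_nb_glm(filtered, ex$metadata, offsets = upper_quartile_offsets(filtered))
  expect_lt(median(fit$dispersion), 0.05)
})

test_that("identical designs give zero statistics; non-nested designs error", {
  ex <- sim_nb(5, n_genes = 60)
  filtered <- suppressMessages(filter_expressed(ex$counts, deg_params()))
  off <- upper_quartile_offsets(filtered)
  fit <- fit_nb_glm(filtered, ex$metadata, offsets = off)
  tab <- test_contrast(fit, fit)
  expect_true(all(tab$stat == 0))
  expect_true(all(tab$pvalue == 1))
  red <- fit_nb_glm(filtered, ex$metadata, model = "genotype_only", offsets = off,
                    dispersion = fit$dispersion)
  expect_error(test_contrast(red, fit), class = "evotrait_design_error")
})

test_that("LRT matches an independent Poisson IRLS in the dispersion-zero limit", {
  ex <- sim_nb(11, n_genotypes = 3, n_rep = 2, n_genes = 5, responsive = 1:2,
               lfc = 1, phi = 0)
  filtered <- ex$counts # no filtering: keep all 5 genes
  off <- upper_quartile_offsets(filtered)
  full <- fit_nb_glm(filtered, ex$metadata, offsets = off, dispersion = 0)
  red <- fit_nb_glm(filtered, ex$metadata, model = "genotype_only", offsets = off,
                    dispersion = 0)
  tab <- test_contrast(full, red)
  Xf <- full$design
  Xr <- red$design
  for (g in rownames(filtered)) {
    y <- filtered[g, ]
    lrt <- pois_irls(Xr, y, off)$deviance - pois_irls(Xf, y, off)$deviance
    expect_equal(tab$stat[tab$gene == g], max(lrt, 0), tolerance = 1e-6)
  }
})

test_that("null simulations are calibrated and planted genes are recovered", {
  # null: approximately uniform p-values, few discoveries
  null <- sim_nb(21, n_genes = 600)
  res0 <- suppressMessages(call_degs(null$counts, null$metadata))
  expect_gt(ks.test(res0$table$pvalue, "punif")$p.value, 0.01)
  expect_lte(length(res0$genes), 0.01 * nrow(res0$table))

  # alternative at the stated settings: 100 planted among 2000, 24 samples
  alt <- sim_nb(22, n_genotypes = 4, n_rep = 3, n_genes = 2000, responsive = 1:100,
                lfc = 2, phi = 0.1)
  res1 <- suppressMessages(call_degs(alt$counts, alt$metadata))
  expect_gte(sum(alt$responsive %in% res1$genes), 80)

  # shuffled condition labels behave like a null
  perm <- alt
  perm$metadata$condition <- withr::with_seed(77, sample(perm$metadata$condition))
  # keep the design estimable: reshuffle until every genotype has both conditions
  res2 <- suppressMessages(call_degs(perm$counts, perm$metadata))
  expect_lte(length(res2$genes), 0.02 * nrow(res2$table))

  # fdr threshold zero calls nothing
  res3 <- suppressMessages(call_degs(null$counts, null$metadata, deg_params(fdr_threshold = 0)))
  expect_length(res3$genes, 0)
})

test_that("interaction contrast finds genotype-modulated responders", {
  ex <- sim_nb(31, n_genotypes = 6, n_rep = 3, n_genes = 800, responsive = 1:40,
               lfc = 2, phi = 0.1, gxn = TRUE)
  res <- suppressMessages(call_degs(ex$counts, ex$metadata,
                                    deg_params(model = "condition_by_genotype_interaction")))
  expect_gte(mean(ex$responsive %in% res$genes), 0.8)
})

test_that("rank-deficient interaction designs name the confounded genotype", {
  ex <- tiny_experiment()
  md <- ex$metadata
  md$condition <- c("low", "low", "low", "high") # genotype A in one condition only
  counts <- matrix(rpois(40, 50), 10, 4,
                   dimnames = list(paste0("g", 1:10), md$sample_id))
  err <- tryCatch(
    fit_nb_glm(counts, md, model = "condition_by_genotype_interaction",
               offsets = setNames(rep(0, 4), md$sample_id)),
    error = identity
  )
  expect_s3_class(err, "evotrait_design_error")
  expect_match(conditionMessage(err), "A")
})

test_that("edgeR agrees qualitatively on which genes respond", {
  skip_if_not_installed("edgeR")
  ex <- sim_nb(41, n_genotypes = 4, n_rep = 3, n_genes = 500, responsive = 1:30,
               lfc = 2, phi = 0.1)
  ours <- suppressMessages(call_degs(ex$counts, ex$metadata))
  y <- edgeR::DGEList(ex$counts)
  y <- y[rowSums(edgeR::cpm(y) > 1) >= 10, , keep.lib.sizes = FALSE]
  y <- edgeR::calcNormFactors(y, method = "upperquartile")
  design <- model.matrix(~ genotype + condition, ex$metadata)
  y <- edgeR::estimateDisp(y, design)
  lrt <- edgeR::glmLRT(edgeR::glmFit(y, design))
  theirs <- rownames(y)[p.adjust(lrt$table$PValue, "BH") < 0.05]
  shared <- length(intersect(ours$genes, theirs))
  expect_gt(shared / max(length(ours$genes), length(theirs)), 0.8)
})
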