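# Differential expression: CPM filtering, upper-quartile normalization,
# negative-binomial GLM fits and likelihood-ratio contrasts with BH control.

#' Differential-expression parameters
#'
#' @param cpm_threshold Expression floor in counts per million (default 1).
#' @param min_samples Minimum number of samples in which a gene must exceed
#'   `cpm_threshold` to be considered expressed (default 10).
#' @param fdr_threshold BH-adjusted significance cut, in (0, 1).
#' @param model Design for the tested contrast: `"condition_plus_genotype"`
#'   tests the treatment main effect (additive genotype adjustment);
#'   `"condition_by_genotype_interaction"` tests genotype-dependent
#'   treatment response.
#' @return A validated `deg_params` list.
#' @export
deg_params <- function(cpm_threshold = 1, min_samples = 10, fdr_threshold = 0.05,
                       model = c("condition_plus_genotype", "condition_by_genotype_interaction")) {
  model <- match.arg(model)
  if (cpm_threshold <= 0 || min_samples <= 0) stop_value("Thresholds must be positive.")
  if (fdr_threshold < 0 || fdr_threshold >= 1) stop_value("fdr_threshold must be in [0, 1).")
  structure(list(cpm_threshold = cpm_threshold, min_samples = as.integer(min_samples),
                 fdr_threshold = fdr_threshold, model = model),
            class = "deg_params")
}

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / library_size[s] * 1e6`, with library size the
#' raw column sum.
#'
#' @param counts Count matrix (genes x samples).
#' @return Real matrix of the same shape.
#' @export
compute_cpm <- function(counts) {
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero)) {
    stop_value(sprintf("Sample(s) with all-zero counts: %s.",
                       paste(colnames(counts)[zero], collapse = ", ")))
  }
  sweep(counts, 2L, lib, "/") * 1e6
}

#' Filter lowly expressed genes
#'
#' Retains genes with CPM above `cpm_threshold` in at least `min_samples`
#' samples; the sample set is unchanged.
#'
#' @param counts Count matrix.
#' @param params A [deg_params()] object.
#' @return Filtered count matrix.
#' @export
filter_expressed <- function(counts, params = deg_params()) {
  cpm <- compute_cpm(counts)
  keep <- rowSums(cpm > params$cpm_threshold) >= params$min_samples
  if (!any(keep)) {
    stop_value("No gene passes the expression filter; review cpm_threshold/min_samples.")
  }
  rlang::inform(sprintf("filter_expressed: retained %d of %d genes.", sum(keep), length(keep)),
                class = "evotrait_log")
  counts[keep, , drop = FALSE]
}

#' Upper-quartile log-offsets
#'
#' Per sample, the normalization quantile is the 75th percentile (linear
#' interpolation) of that sample's nonzero counts. The relative factor
#' `UQ / library_size` is scaled to unit geometric mean, so the offset is
#' `log(library_size * factor)` and the mean offset equals the mean log
#' library size. Doubling every count of one sample shifts its offset by
#' exactly `log 2`.
#'
#' @param counts Count matrix.
#' @return Named per-sample log-offset vector.
#' @export
upper_quartile_offsets <- function(counts) {
  lib <- colSums(counts)
  uq <- vapply(seq_len(ncol(counts)), function(s) {
    x <- counts[, s]
    x <- x[x > 0]
    if (length(x) == 0) {
      stop_value(sprintf("Sample '%s' has no nonzero count.", colnames(counts)[s]))
    }
    stats::quantile(x, 0.75, names = FALSE, type = 7)
  }, numeric(1))
  f <- uq / lib
  f <- f / exp(mean(log(f)))
  stats::setNames(log(lib * f), colnames(counts))
}

# Design matrices for the supported models; condition/genotype become
# factors with sorted levels unless already factors.
build_design <- function(metadata, model) {
  g <- metadata$genotype
  n <- metadata$condition
  g <- if (is.factor(g)) droplevels(g) else factor(g)
  n <- if (is.factor(n)) droplevels(n) else factor(n)
  df <- data.frame(genotype = g, condition = n)
  form <- switch(model,
    genotype_only = ~genotype,
    condition_plus_genotype = ~ genotype + condition,
    condition_by_genotype_interaction = ~ genotype * condition
  )
  if (is.null(form)) stop_value(sprintf("Unknown model '%s'.", model))
  stats::model.matrix(form, df)
}

check_full_rank <- function(design, metadata, model) {
  r <- qr(design)$rank
  if (r < ncol(design)) {
    tab <- table(metadata$genotype, metadata$condition)
    bad <- rownames(tab)[rowSums(tab > 0) < ncol(tab)]
    hint <- if (length(bad) > 0) {
      sprintf(" Genotype(s) observed in only one condition: %s.", paste(bad, collapse = ", "))
    } else ""
    stop_design(sprintf("Design for model '%s' is rank deficient (rank %d < %d columns).%s",
                        model, r, ncol(design), hint))
  }
  r
}

#' Fit per-gene negative-binomial log-linear models
#'
#' Fits every gene by iteratively reweighted least squares at a fixed
#' per-gene dispersion. When `dispersion` is not supplied it is estimated
#' as a per-gene method-of-moments value (Pearson-style, from a Poisson
#' pre-fit) shrunk toward a lowess mean-dispersion trend with trend weight
#' `20 / (20 + residual df)`, then clamped at zero. Genes with dispersion
#' numerically zero are fitted as Poisson.
#'
#' @param counts Count matrix (already expression-filtered).
#' @param metadata Matched sample metadata.
#' @param model One of `"genotype_only"`, `"condition_plus_genotype"`,
#'   `"condition_by_genotype_interaction"`.
#' @param offsets Per-sample log-offsets, e.g. [upper_quartile_offsets()].
#' @param dispersion Optional fixed per-gene dispersion vector (recycled);
#'   used to share dispersions between nested fits.
#' @param nuisance Optional data frame of nuisance covariates appended to
#'   the design (hook for user-supplied unwanted-variation factors).
#' @return An `nb_glm_fit` object: coefficient matrix, dispersions,
#'   deviances, design, residual df.
#' @export
fit_nb_glm <- function(counts, metadata, model = "condition_plus_genotype",
                       offsets, dispersion = NULL, nuisance = NULL) {
  metadata <- validate_metadata(metadata, counts, two_condition = FALSE)
  design <- build_design(metadata, model)
  if (!is.null(nuisance)) {
    nm <- stats::model.matrix(~., data.frame(nuisance))[, -1, drop = FALSE]
    design <- cbind(design, nm)
  }
  rank <- check_full_rank(design, metadata, model)
  df_resid <- nrow(design) - rank
  if (df_resid < 1) stop_design("No residual degrees of freedom.")
  if (missing(offsets)) offsets <- upper_quartile_offsets(counts)
  offsets <- offsets[colnames(counts)]
  if (anyNA(offsets) || any(!is.finite(offsets))) stop_value("Offsets must be finite for every sample.")

  ng <- nrow(counts)
  mean_cpm <- rowMeans(compute_cpm(counts))

  pois_fit <- function(y) {
    stats::glm.fit(design, y, family = stats::poisson(), offset = offsets,
                   control = list(maxit = 50))
  }

  if (is.null(dispersion)) {
    # Pearson-matching moment estimator with residual-df correction: the phi
    # at which the Pearson statistic under NB variance mu + phi*mu^2 equals
    # the residual df. Without the df correction phi is biased low and the
    # downstream LRT is anti-conservative.
    phi_mom <- numeric(ng)
    for (g in seq_len(ng)) {
      y <- counts[g, ]
      fit <- pois_fit(y)
      mu <- pmax(fit$fitted.values, 1e-8)
      fn <- function(phi) sum((y - mu)^2 / (mu + phi * mu^2)) - df_resid
      phi_mom[g] <- if (fn(0) <= 0) 0 else stats::uniroot(fn, c(0, 1e3), extendInt = "downX")$root
    }
    trend <- if (ng >= 10) {
      lo <- stats::lowess(log(mean_cpm + 0.5), phi_mom, f = 0.5)
      stats::approx(lo$x, lo$y, xout = log(mean_cpm + 0.5), rule = 2, ties = mean)$y
    } else {
      rep(mean(phi_mom), ng)
    }
    trend <- pmax(trend, 0)
    w <- 20 / (20 + df_resid)
    dispersion <- pmax(w * trend + (1 - w) * phi_mom, 0)
  } else {
    dispersion <- rep_len(dispersion, ng)
    if (any(dispersion < 0)) stop_value("Dispersions must be non-negative.")
  }

  coefs <- matrix(0, ng, ncol(design), dimnames = list(rownames(counts), colnames(design)))
  devs <- numeric(ng)
  for (g in seq_len(ng)) {
    phi <- dispersion[g]
    fam <- if (phi < 1e-8) stats::poisson() else MASS::negative.binomial(theta = 1 / phi)
    fit <- suppressWarnings(
      stats::glm.fit(design, counts[g, ], family = fam, offset = offsets,
                     control = list(maxit = 50))
    )
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    coefs[g, ] <- cf
    devs[g] <- fit$deviance
  }

  structure(list(
    coefficients = coefs, dispersion = dispersion, deviance = devs,
    design = design, rank = rank, df_residual = df_resid, model = model,
    offsets = offsets, gene_ids = rownames(counts), mean_cpm = mean_cpm
  ), class = "nb_glm_fit")
}

#' @export
print.nb_glm_fit <- function(x, ...) {
  cat(sprintf("<nb_glm_fit> %d genes, model '%s', design rank %d, median dispersion %.4g\n",
              length(x$gene_ids), x$model, x$rank, stats::median(x$dispersion)))
  invisible(x)
}

#' Likelihood-ratio contrast between nested fits
#'
#' Per gene, `stat = deviance(reduced) - deviance(full)` referred to a
#' chi-square with df equal to the difference in design rank; both fits must
#' share dispersions for the statistic to be a likelihood ratio.
#'
#' @param fit_full,fit_reduced `nb_glm_fit` objects on the same genes;
#'   the reduced design must be nested in the full design.
#' @return A `deg_table` tibble: gene, log2fc (condition effect where the
#'   full design has one), stat, pvalue, fdr, mean_cpm; sorted by fdr, then
#'   pvalue, then gene ID.
#' @export
test_contrast <- function(fit_full, fit_reduced) {
  if (!identical(fit_full$gene_ids, fit_reduced$gene_ids)) {
    stop_consistency("Fits cover different gene sets.")
  }
  rank_joint <- qr(cbind(fit_full$design, fit_reduced$design))$rank
  if (rank_joint > fit_full$rank) {
    stop_design("Reduced design is not nested in the full design.")
  }
  df <- fit_full$rank - fit_reduced$rank
  stat <- pmax(fit_reduced$deviance - fit_full$deviance, 0)
  pvalue <- if (df == 0) rep(1, length(stat)) else stats::pchisq(stat, df, lower.tail = FALSE)

  cond_cols <- grepl("^condition", colnames(fit_full$coefficients)) &
    !grepl(":", colnames(fit_full$coefficients))
  log2fc <- if (sum(cond_cols) == 1) {
    fit_full$coefficients[, which(cond_cols)] / log(2)
  } else {
    rep(NA_real_, length(stat))
  }

  tbl <- tibble::tibble(
    gene = fit_full$gene_ids, log2fc = unname(log2fc), stat = stat,
    pvalue = pvalue, fdr = bh_adjust(pvalue), mean_cpm = unname(fit_full$mean_cpm)
  )
  tbl <- dplyr::arrange(tbl, .data$fdr, .data$pvalue, .data$gene)
  structure(tbl, class = c("deg_table", class(tbl)), df = df)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()] with `method = "BH"`:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Vector of q-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop_value("p-values must lie in [0, 1].")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes
#'
#' Full pipeline: expression filter, upper-quartile offsets, shared
#' dispersion estimation under the full design, nested NB GLM fits,
#' likelihood-ratio test and BH control.
#'
#' @param counts Count matrix.
#' @param metadata Matched sample metadata (two condition levels).
#' @param params A [deg_params()] object; `params$model` picks the contrast.
#' @param nuisance Optional nuisance covariates (see [fit_nb_glm()]).
#' @return List with `table` (full `deg_table`) and `genes` (IDs with
#'   `fdr < params$fdr_threshold`).
#' @export
call_degs <- function(counts, metadata, params = deg_params(), nuisance = NULL) {
  metadata <- validate_metadata(metadata, counts, two_condition = TRUE)
  filtered <- filter_expressed(counts, params)
  offsets <- upper_quartile_offsets(filtered)
  full_model <- params$model
  reduced_model <- switch(full_model,
    condition_plus_genotype = "genotype_only",
    condition_by_genotype_interaction = "condition_plus_genotype"
  )
  fit_full <- fit_nb_glm(filtered, metadata, model = full_model, offsets = offsets,
                         nuisance = nuisance)
  fit_reduced <- fit_nb_glm(filtered, metadata, model = reduced_model, offsets = offsets,
                            dispersion = fit_full$dispersion, nuisance = nuisance)
  table <- test_contrast(fit_full, fit_reduced)
  genes <- table$gene[table$fdr < params$fdr_threshold]
  list(table = table, genes = genes)
}
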