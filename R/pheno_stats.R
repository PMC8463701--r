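# Phenotype-panel characterization: coefficient of variation, trait
# correlation matrices, two-way ANOVA variance partition.

#' Coefficient of variation
#'
#' Sample SD over mean. The aggregation level matters scientifically:
#' `aggregate_by` averages values within groups (e.g. genotype means,
#' describing panel-level variation) before computing the CV; the default
#' uses the values as given (per-plant).
#'
#' @param values Numeric trait vector.
#' @param aggregate_by Optional grouping vector (e.g. genotype labels);
#'   values are averaged per group first.
#' @param na_rm Drop non-finite values first.
#' @return The CV (dimensionless).
#' @export
coefficient_of_variation <- function(values, aggregate_by = NULL, na_rm = FALSE) {
  if (!is.null(aggregate_by)) {
    if (length(aggregate_by) != length(values)) {
      stop_value("`aggregate_by` must match `values` in length.")
    }
    values <- tapply(values, aggregate_by, mean, na.rm = na_rm)
  }
  if (na_rm) values <- values[is.finite(values)]
  if (length(values) < 2 || anyNA(values) || any(!is.finite(values))) {
    stop_value("CV needs >= 2 finite values.")
  }
  m <- mean(values)
  if (m == 0) stop_value("CV undefined: mean is zero.")
  stats::sd(values) / m
}

#' Pairwise trait correlation matrix
#'
#' Pearson correlations with pairwise-complete observations; symmetric with
#' unit diagonal. Pairs with fewer than 3 complete observations or a
#' constant trait are flagged `NA` with a warning.
#'
#' @param table Phenotype data frame.
#' @param traits Trait column names (>= 2).
#' @return Symmetric correlation matrix.
#' @export
trait_correlation_matrix <- function(table, traits) {
  table <- tibble::as_tibble(table)
  missing_tr <- setdiff(traits, names(table))
  if (length(missing_tr) > 0) {
    stop_lookup(sprintf("Trait(s) not found: %s.", paste(missing_tr, collapse = ", ")))
  }
  m <- as.matrix(table[, traits, drop = FALSE])
  out <- diag(1, length(traits))
  dimnames(out) <- list(traits, traits)
  for (i in seq_along(traits)) {
    for (j in seq_along(traits)) {
      if (i >= j) next
      ok <- is.finite(m[, i]) & is.finite(m[, j])
      if (sum(ok) < 3) {
        rlang::warn(sprintf("Fewer than 3 complete observations for %s vs %s.", traits[i], traits[j]))
        out[i, j] <- out[j, i] <- NA_real_
      } else if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) {
        rlang::warn(sprintf("Constant trait in pair %s vs %s; correlation undefined.", traits[i], traits[j]))
        out[i, j] <- out[j, i] <- NA_real_
      } else {
        out[i, j] <- out[j, i] <- stats::cor(m[ok, i], m[ok, j])
      }
    }
  }
  out
}

#' Two-way ANOVA variance partition
#'
#' Sequential (type-I) sums of squares for genotype, condition and their
#' interaction via least squares, with F tests against the residual mean
#' square. Fractions are SS over total SS. For unbalanced data the
#' sequential partition depends on factor order (genotype first, then
#' condition); a warning is emitted.
#'
#' @param trait Numeric response vector.
#' @param genotype,condition Factors (coerced).
#' @return A `variance_partition` tibble: term, df, ss, fraction,
#'   statistic, p_value; terms are genotype, condition,
#'   genotype:condition, residual.
#' @export
anova_two_way <- function(trait, genotype, condition) {
  g <- factor(genotype)
  n <- factor(condition)
  ok <- is.finite(trait)
  trait <- trait[ok]; g <- droplevels(g[ok]); n <- droplevels(n[ok])
  if (nlevels(g) < 2 || nlevels(n) < 2) stop_design("Both factors need >= 2 levels.")
  cells <- table(g, n)
  if (any(cells == 0)) {
    stop_design("Empty genotype-by-condition cell; interaction is inestimable.")
  }
  if (length(trait) - nlevels(g) * nlevels(n) < 1) {
    stop_design("No residual degrees of freedom.")
  }
  if (length(unique(as.vector(cells))) > 1) {
    rlang::warn("Unbalanced design: sequential SS depend on factor order (genotype, condition).")
  }
  fit <- stats::lm(trait ~ g * n)
  an <- stats::anova(fit)
  ss <- an$`Sum Sq`
  out <- tibble::tibble(
    term = c("genotype", "condition", "genotype:condition", "residual"),
    df = an$Df, ss = ss, fraction = ss / sum(ss),
    statistic = an$`F value`, p_value = an$`Pr(>F)`
  )
  structure(out, class = c("variance_partition", class(out)))
}
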