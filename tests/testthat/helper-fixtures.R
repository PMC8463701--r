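# Shared fixtures and independent oracles used across the suite.

# Tiny deterministic counts + metadata for IO and bookkeeping tests.
tiny_experiment <- function() {
  counts <- matrix(c(
    5, 10, 0, 8,
    100, 220, 90, 150,
    3, 0, 1, 2
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3", "s4")))
  metadata <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    genotype = c("A", "A", "B", "B"),
    condition = c("low", "high", "low", "high"),
    replicate = c(1L, 1L, 1L, 1L)
  )
  list(counts = counts, metadata = metadata)
}

# Direct NB simulator, independent of the package generator: balanced
# genotype x condition design with optional planted condition effects
# (genotype-modulated when gxn = TRUE).
sim_nb <- function(seed, n_genotypes = 4, n_rep = 3, n_genes = 500,
                   responsive = integer(0), lfc = 2, phi = 0.1, gxn = FALSE) {
  withr::with_seed(seed, {
    ns <- n_genotypes * 2 * n_rep
    metadata <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(ns)),
      genotype = rep(sprintf("g%d", seq_len(n_genotypes)), each = 2 * n_rep),
      condition = rep(rep(c("low", "high"), each = n_rep), n_genotypes),
      replicate = rep(seq_len(n_rep), n_genotypes * 2)
    )
    base <- exp(stats::rnorm(n_genes, log(100), 1))
    lib <- exp(stats::rnorm(ns, log(2e6), 0.2))
    eff <- matrix(0, n_genes, ns)
    if (length(responsive) > 0) {
      # alternate signs so planted effects stay composition-balanced
      signs <- rep_len(c(-1, 1), length(responsive))
      high <- metadata$condition == "high"
      if (gxn) {
        strong <- metadata$genotype %in% sprintf("g%d", seq_len(ceiling(n_genotypes / 2)))
        eff[responsive, high & strong] <- signs * lfc
      } else {
        eff[responsive, high] <- signs * lfc
      }
    }
    q <- base * 2^eff
    mu <- sweep(sweep(q, 2, colSums(q), "/"), 2, lib, "*")
    counts <- matrix(
      if (phi < 1e-12) stats::rpois(n_genes * ns, mu) else stats::rnbinom(n_genes * ns, mu = mu, size = 1 / phi),
      n_genes, ns, dimnames = list(sprintf("gene%04d", seq_len(n_genes)), metadata$sample_id)
    )
    list(counts = counts, metadata = metadata,
         responsive = sprintf("gene%04d", responsive))
  })
}

# Brute-force Benjamini-Hochberg: q_(i) = min_{j >= i} p_(j) * m / j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(ps[seq(i, m)] * m / seq(i, m)))
  }
  q
}

# Hand-written Poisson IRLS (Newton scoring), an implementation independent
# of glm.fit, for checking the LRT in the dispersion-zero limit.
pois_irls <- function(X, y, offset) {
  beta <- numeric(ncol(X))
  beta[1] <- log(mean(y) + 0.1) - mean(offset)
  for (it in 1:100) {
    eta <- as.vector(X %*% beta + offset)
    mu <- exp(eta)
    z <- eta - offset + (y - mu) / mu
    beta_new <- solve(crossprod(X, mu * X), crossprod(X, mu * z))
    if (max(abs(beta_new - beta)) < 1e-13) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  mu <- exp(as.vector(X %*% beta + offset))
  dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  list(beta = as.vector(beta), deviance = dev)
}

# A 3-point hyperparameter grid that keeps model-fitting tests fast.
small_grid <- function() {
  tibble::tibble(nrounds = c(20L, 50L, 50L), eta = c(0.3, 0.1, 0.3),
                 subsample = c(1, 0.8, 1), colsample_bytree = c(1, 1, 0.8),
                 max_depth = c(2L, 3L, 2L))
}

# Small two-species bundle reused by feature-selection/pipeline tests.
small_bundle <- function(seed = 42) {
  generate_dataset(synth_config(
    n_genotypes = 5, n_genes = 500, n_responsive = 50, conserved_fraction = 0.5,
    n_gxn = 20, n_causal = 5, n_tfs = 15, hub_out_degree = c(8, 5), seed = seed
  ))
}

# Same scale without genotype-modulated responders: the trait responds to
# the causal genes uniformly across genotypes, so even a 5-genotype panel
# supports accurate cross-genotype prediction — used where a test needs
# clear predictive signal rather than a hard benchmark.
easy_bundle <- function(seed = 42) {
  generate_dataset(synth_config(
    n_genotypes = 5, n_genes = 500, n_responsive = 50, conserved_fraction = 0.5,
    n_gxn = 0, n_causal = 5, n_tfs = 15, hub_out_degree = c(8, 5), seed = seed
  ))
}
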