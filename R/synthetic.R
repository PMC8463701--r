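# Ground-truthed synthetic data: two-species multi-genotype N-treatment
# designs with negative-binomial counts, planted condition-responsive genes
# partially conserved across species, genotype-dependent (GxN) responders,
# causal trait genes, and a planted TF->target regulatory structure.

#' Synthetic-dataset configuration
#'
#' Defaults describe the reference study design the pipeline is validated
#' on: two species, 16 genotypes each, two nitrogen conditions, 3
#' replicates, 2000 genes per species with 100 condition-responsive genes of
#' which 50 are conserved across species, 10 causal trait genes, NB
#' dispersion 0.1, planted effects of 2 on the log2 scale, and a trait with
#' signal-to-noise ratio 3 on the variance scale.
#'
#' @param n_genotypes Genotypes per species (scalar or length-2 vector).
#' @param n_replicates Replicates per genotype x condition.
#' @param n_genes Genes per species.
#' @param homology Named fractions `one_to_one`, `one_to_two`, `unmapped`
#'   of species-A genes in each homology class (must sum to 1).
#' @param n_responsive Planted condition-responsive genes per species.
#' @param conserved_fraction Fraction of responsive genes whose response is
#'   mirrored in the other species through the homolog map.
#' @param effect_log2fc Mean absolute planted log2 fold change.
#' @param effect_sd SD of planted log2 fold changes around the mean.
#' @param n_gxn Responsive genes whose condition effect is genotype-
#'   modulated: per (gene, genotype) the log2 effect is scaled by a uniform
#'   multiplier in \[0.25, 1.75\], planting a detectable interaction on top
#'   of a preserved main effect.
#' @param n_causal Causal trait genes (drawn from the conserved responsive
#'   set when homology is enabled, otherwise from the responsive set).
#' @param dispersion NB dispersion phi (variance `mu + phi mu^2`); 0 gives
#'   Poisson counts.
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size model.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline abundances;
#'   planted genes are drawn from a higher floor so they survive the
#'   expression filter.
#' @param genotype_block_sd SD of log-normal per-(genotype, gene-block)
#'   baseline multipliers; creates genotype clustering.
#' @param block_size Genes per genotype-effect block.
#' @param trait List: `snr` (variance signal-to-noise ratio), `family`
#'   (`"saturating"` passes the causal score through tanh, `"linear"` does
#'   not), `type` (`"continuous"` or `"binary"`).
#' @param n_tfs Regulators (transcription factors) per species, drawn from
#'   the responsive set.
#' @param hub_out_degree Out-degrees of planted hub TFs (one entry per hub).
#' @param tf_effect Multiplicative strength of TF influence on its targets'
#'   expected expression.
#' @param seed Master seed; every draw derives from it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_genotypes = 16, n_replicates = 3, n_genes = 2000,
                         homology = c(one_to_one = 0.7, one_to_two = 0.15, unmapped = 0.15),
                         n_responsive = 100, conserved_fraction = 0.5,
                         effect_log2fc = 2, effect_sd = 0.25,
                         n_gxn = 50, n_causal = 10, dispersion = 0.1,
                         libsize_meanlog = log(3e6), libsize_sdlog = 0.25,
                         baseline_meanlog = log(100), baseline_sdlog = 1.2,
                         genotype_block_sd = 0.2, block_size = 50,
                         trait = list(snr = 3, family = "saturating", type = "continuous"),
                         n_tfs = 40, hub_out_degree = c(20, 10, 10), tf_effect = 0.4,
                         seed = 1) {
  n_genotypes <- rep_len(as.integer(n_genotypes), 2)
  if (any(n_genotypes < 2) || n_replicates < 1 || n_genes < 10) {
    stop_config("Need >= 2 genotypes, >= 1 replicate and >= 10 genes.")
  }
  if (abs(sum(homology) - 1) > 1e-8 || any(homology < 0)) {
    stop_config("Homology fractions must be non-negative and sum to 1.")
  }
  n_conserved <- round(n_responsive * conserved_fraction)
  causal_pool <- if (homology[["unmapped"]] >= 1 || n_conserved == 0) n_responsive else n_conserved
  if (n_causal > causal_pool) {
    stop_config(sprintf("n_causal (%d) exceeds the causal pool (%d conserved responsive genes).",
                        n_causal, causal_pool))
  }
  if (n_responsive > n_genes || n_gxn > n_genes) stop_config("Planted sets exceed n_genes.")
  trait <- utils::modifyList(list(snr = 3, family = "saturating", type = "continuous"), trait)
  structure(list(
    n_genotypes = n_genotypes, n_replicates = as.integer(n_replicates),
    n_genes = as.integer(n_genes), homology = homology,
    n_responsive = as.integer(n_responsive), conserved_fraction = conserved_fraction,
    effect_log2fc = effect_log2fc, effect_sd = effect_sd,
    n_gxn = as.integer(n_gxn), n_causal = as.integer(n_causal),
    dispersion = dispersion, libsize_meanlog = libsize_meanlog,
    libsize_sdlog = libsize_sdlog, baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog, genotype_block_sd = genotype_block_sd,
    block_size = as.integer(block_size), trait = trait,
    n_tfs = as.integer(n_tfs), hub_out_degree = hub_out_degree,
    tf_effect = tf_effect, seed = as.integer(seed)
  ), class = "synth_config")
}

rnb <- function(n, mu, phi) {
  if (phi < 1e-12) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

# One species' count matrix, metadata, trait table and per-species truth.
# `planted` carries gene-level effects decided upstream (so conservation
# can be mirrored through the homolog map before any counts are drawn).
generate_species_counts <- function(genes, planted, config, prefix, n_genotypes) {
  n_rep <- config$n_replicates
  genotypes <- sprintf("%s%02d", prefix, seq_len(n_genotypes))
  metadata <- tidyr::expand_grid(
    genotype = genotypes, condition = c("low", "high"), replicate = seq_len(n_rep)
  )
  metadata$condition <- factor(metadata$condition, levels = c("low", "high"))
  metadata$sample_id <- sprintf("%s_%s_r%d", metadata$genotype, metadata$condition, metadata$replicate)
  metadata <- metadata[, c("sample_id", "genotype", "condition", "replicate")]
  ns <- nrow(metadata)
  ng <- length(genes)

  is_planted <- genes %in% c(planted$responsive$gene, planted$gxn$gene,
                             planted$tfs, planted$causal$gene)
  baseline <- ifelse(
    is_planted,
    exp(stats::rnorm(ng, config$baseline_meanlog + log(2), 0.8)),
    exp(stats::rnorm(ng, config$baseline_meanlog, config$baseline_sdlog))
  )

  # genotype-block baseline multipliers
  block <- ceiling(seq_len(ng) / config$block_size)
  block_eff <- matrix(exp(stats::rnorm(max(block) * n_genotypes, 0, config$genotype_block_sd)),
                      max(block), n_genotypes, dimnames = list(NULL, genotypes))
  q <- baseline * block_eff[block, match(metadata$genotype, genotypes), drop = FALSE]
  dimnames(q) <- list(genes, metadata$sample_id)

  # condition effects (responsive genes); GxN genes are responsive genes
  # whose condition effect is multiplied by a per-(gene, genotype) factor,
  # so the panel mixes strong, weak and near-silent responders per gene --
  # the genotype-by-treatment structure the feature-selection funnel and
  # the prediction benchmark both rely on
  high <- metadata$condition == "high"
  ridx <- match(planted$responsive$gene, genes)
  eff_mat <- matrix(planted$responsive$log2fc, length(ridx), sum(high))
  if (nrow(planted$gxn) > 0) {
    gx_rows <- match(planted$gxn$gene, planted$responsive$gene)
    mult <- planted$gxn_mult[, match(metadata$genotype[high], colnames(planted$gxn_mult)),
                             drop = FALSE]
    eff_mat[gx_rows, ] <- eff_mat[gx_rows, ] * mult
  }
  q[ridx, high] <- q[ridx, high] * 2^eff_mat

  lib <- exp(stats::rnorm(ns, config$libsize_meanlog, config$libsize_sdlog))
  mu_of <- function(qm) sweep(sweep(qm, 2, colSums(qm), "/"), 2, lib, "*")

  # two-pass generation so targets can depend on realized TF expression
  mu0 <- mu_of(q)
  counts <- matrix(0L, ng, ns, dimnames = dimnames(q))
  tf_idx <- match(planted$tfs, genes)
  non_tf <- setdiff(seq_len(ng), tf_idx)
  counts[tf_idx, ] <- rnb(length(tf_idx) * ns, mu0[tf_idx, ], config$dispersion)
  if (nrow(planted$tf_edges) > 0) {
    tf_cpm <- log2(sweep(counts[tf_idx, , drop = FALSE], 2, colSums(counts[tf_idx, , drop = FALSE]) + 1, "/") * 1e6 + 1)
    for (tf in unique(planted$tf_edges$regulator)) {
      z <- as.numeric(scale(tf_cpm[match(tf, planted$tfs), ]))
      z[is.na(z)] <- 0
      tg <- match(planted$tf_edges$target[planted$tf_edges$regulator == tf], genes)
      q[tg, ] <- q[tg, ] * rep(exp(config$tf_effect * z), each = length(tg))
    }
    mu0 <- mu_of(q)
  }
  counts[non_tf, ] <- rnb(length(non_tf) * ns, mu0[non_tf, ], config$dispersion)
  storage.mode(counts) <- "double"

  # trait: weighted causal score through an optional saturating nonlinearity
  score <- if (nrow(planted$causal) == 0) {
    rep(0, ns)
  } else {
    cpm <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6
    cz <- log2(cpm[match(planted$causal$gene, genes), , drop = FALSE] + 1)
    cz <- t(apply(cz, 1, function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0))
    as.numeric(planted$causal$weight %*% cz) / sqrt(nrow(planted$causal))
  }
  # saturation scaled so typical scores stay in the responsive range: the
  # gene-trait map is genuinely nonlinear without flattening whole genotypes
  signal <- if (identical(config$trait$family, "saturating")) 2 * tanh(score / 2) else score
  # noise is scaled to the within-(genotype x condition) signal: measurement
  # error on a trait does not grow with panel diversity, and this is the
  # repeatable per-plant variation a matched design can actually exploit
  cell <- interaction(metadata$genotype, metadata$condition)
  within <- signal - stats::ave(signal, cell)
  ref_sd <- stats::sd(within)
  if (!is.finite(ref_sd) || ref_sd == 0) ref_sd <- max(stats::sd(signal), 1e-8)
  noise_sd <- ref_sd / sqrt(config$trait$snr)
  latent <- signal + stats::rnorm(ns, 0, noise_sd)
  trait_value <- 40 + 12 * latent
  phenotypes <- dplyr::mutate(metadata, trait = trait_value)
  if (identical(config$trait$type, "binary")) {
    phenotypes$outcome <- as.integer(latent > stats::median(latent))
  }

  list(counts = counts, metadata = metadata, phenotypes = phenotypes, library_sizes = lib)
}

#' Generate a ground-truthed two-species dataset
#'
#' Emulates a matched transcriptome/phenotype design: two species profiled
#' under two nitrogen conditions across multi-genotype panels, with
#' negative-binomial counts, planted condition-responsive genes whose
#' response is partially conserved through a many-to-many homolog map,
#' genotype-dependent responders, causal trait genes driving a per-sample
#' trait at a stated signal-to-noise ratio, and hub TFs whose realized
#' expression propagates to their targets. Fully reproducible from the
#' master seed.
#'
#' @param config A [synth_config()] object.
#' @return A `synthetic_bundle` list: `species_a`, `species_b` (each with
#'   `counts`, `metadata`, `phenotypes`), `homolog_map`, `regulators_a`,
#'   `regulators_b`, `truth`, `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) stop_config("`config` must come from synth_config().")
  withr::with_seed(config$seed, {
    ng <- config$n_genes
    genes_a <- sprintf("atg%04d", seq_len(ng))

    # homolog map
    cls <- sample(names(config$homology), ng, replace = TRUE, prob = config$homology)
    n_b_mapped <- sum(cls == "one_to_one") + 2L * sum(cls == "one_to_two")
    pairs <- tibble::tibble(
      gene_a = rep(genes_a, ifelse(cls == "one_to_one", 1L, ifelse(cls == "one_to_two", 2L, 0L)))
    )
    n_extra_b <- max(ng - n_b_mapped, 0L)
    b_ids <- sprintf("zmg%04d", seq_len(n_b_mapped + n_extra_b))
    pairs$gene_b <- sample(b_ids, n_b_mapped)
    genes_b <- b_ids
    map <- new_homolog_map(pairs)

    # planted responsive sets, conservation mirrored through the map
    n_cons <- round(config$n_responsive * config$conserved_fraction)
    mapped_a <- unique(pairs$gene_a)
    if (n_cons > length(mapped_a)) stop_config("Not enough mapped genes for the conserved set.")
    conserved_a <- sample(mapped_a, n_cons)
    other_a <- sample(setdiff(genes_a, conserved_a), config$n_responsive - n_cons)
    eff <- function(n) sample(c(-1, 1), n, replace = TRUE) *
      pmax(stats::rnorm(n, config$effect_log2fc, config$effect_sd), 0.5)
    responsive_a <- tibble::tibble(gene = c(conserved_a, other_a), log2fc = eff(config$n_responsive),
                                   conserved = c(rep(TRUE, n_cons), rep(FALSE, config$n_responsive - n_cons)))

    first_homolog <- function(a) pairs$gene_b[match(a, pairs$gene_a)]
    conserved_b <- first_homolog(conserved_a)
    conserved_pairs <- tibble::tibble(gene_a = conserved_a, gene_b = conserved_b)
    # B-only responders avoid homologs of any A responder so the planted
    # conserved set is exactly the cross-species truth
    forbidden_b <- pairs$gene_b[pairs$gene_a %in% responsive_a$gene]
    pool_b <- setdiff(genes_b, c(conserved_b, forbidden_b))
    other_b <- sample(pool_b, config$n_responsive - n_cons)
    responsive_b <- tibble::tibble(
      gene = c(conserved_b, other_b),
      log2fc = c(responsive_a$log2fc[seq_len(n_cons)] * stats::runif(n_cons, 0.9, 1.1),
                 eff(config$n_responsive - n_cons)),
      conserved = c(rep(TRUE, n_cons), rep(FALSE, config$n_responsive - n_cons))
    )

    # GxN genes: responsive genes whose per-genotype condition effect is
    # scaled by a continuous multiplier in [0.25, 1.75], planting the
    # genotype-by-treatment interaction the study design emphasizes.
    plant_species <- function(genes, responsive, n_genotypes, prefix, gxn_seed = NULL) {
      if (config$n_gxn > nrow(responsive)) {
        stop_config("n_gxn exceeds n_responsive: GxN genes are genotype-modulated responders.")
      }
      gxn_seed <- utils::head(intersect(gxn_seed, responsive$gene), config$n_gxn)
      extra <- sample(setdiff(responsive$gene, gxn_seed),
                      config$n_gxn - length(gxn_seed))
      gxn_genes <- c(gxn_seed, extra)
      gxn <- tibble::tibble(gene = gxn_genes,
                            log2fc = responsive$log2fc[match(gxn_genes, responsive$gene)])
      genotypes <- sprintf("%s%02d", prefix, seq_len(n_genotypes))
      gxn_mult <- matrix(stats::runif(config$n_gxn * n_genotypes, 0.25, 1.75),
                         config$n_gxn, n_genotypes,
                         dimnames = list(gxn_genes, genotypes))
      tfs <- sample(responsive$gene, min(config$n_tfs, nrow(responsive)))
      list(responsive = responsive, gxn = gxn, gxn_mult = gxn_mult, tfs = tfs)
    }
    pa <- plant_species(genes_a, responsive_a, config$n_genotypes[1], "At")
    # mirror conserved GxN genes into species B through the map, so the
    # conserved-and-interacting feature set has a cross-species truth
    conserved_gxn_a <- intersect(pa$gxn$gene, conserved_a)
    pb <- plant_species(genes_b, responsive_b, config$n_genotypes[2], "Zm",
                        gxn_seed = first_homolog(conserved_gxn_a))

    # causal genes: conserved genotype-modulated responders in A (topped up
    # from the conserved set if needed), their homologs in B
    causal_pool_a <- if (n_cons > 0) conserved_a else responsive_a$gene
    if (config$n_causal > length(causal_pool_a)) {
      stop_config("n_causal exceeds the available causal pool.")
    }
    preferred <- if (n_cons > 0) conserved_gxn_a else intersect(pa$gxn$gene, causal_pool_a)
    causal_genes_a <- if (length(preferred) >= config$n_causal) {
      sample(preferred, config$n_causal)
    } else {
      c(preferred, sample(setdiff(causal_pool_a, preferred),
                          config$n_causal - length(preferred)))
    }
    w <- stats::runif(config$n_causal, 0.5, 1.5) * sample(c(-1, 1), config$n_causal, replace = TRUE)
    pa$causal <- tibble::tibble(gene = causal_genes_a, weight = w)
    pb$causal <- if (n_cons > 0) {
      tibble::tibble(gene = first_homolog(causal_genes_a), weight = w)
    } else {
      tibble::tibble(gene = character(), weight = numeric())
    }

    # hub TF -> target edges among the conserved (feature-set) genes
    plant_edges <- function(p, feature_genes) {
      hubs <- p$tfs[seq_len(min(length(config$hub_out_degree), length(p$tfs)))]
      edges <- purrr::map2_dfr(hubs, config$hub_out_degree[seq_along(hubs)], function(tf, k) {
        pool <- setdiff(feature_genes, tf)
        tibble::tibble(regulator = tf, target = sample(pool, min(k, length(pool))))
      })
      p$tf_edges <- edges
      p
    }
    pa <- plant_edges(pa, if (n_cons > 0) conserved_a else responsive_a$gene)
    pb <- plant_edges(pb, if (n_cons > 0) conserved_b else responsive_b$gene)

    species_a <- generate_species_counts(genes_a, pa, config, "At", config$n_genotypes[1])
    species_b <- generate_species_counts(genes_b, pb, config, "Zm", config$n_genotypes[2])

    truth <- list(
      responsive_a = responsive_a, responsive_b = responsive_b,
      gxn_a = pa$gxn, gxn_b = pb$gxn,
      gxn_multipliers_a = pa$gxn_mult, gxn_multipliers_b = pb$gxn_mult,
      conserved_pairs = conserved_pairs,
      causal_a = pa$causal, causal_b = pb$causal,
      tf_edges_a = pa$tf_edges, tf_edges_b = pb$tf_edges
    )
    structure(list(
      species_a = species_a, species_b = species_b, homolog_map = map,
      regulators_a = pa$tfs, regulators_b = pb$tfs, truth = truth, config = config
    ), class = "synthetic_bundle")
  })
}

#' Generate a single-species dataset
#'
#' Homology is disabled (all genes unmapped, causal genes drawn from the
#' responsive set); otherwise identical in structure to the species-A half
#' of [generate_dataset()] with the same seed. With
#' `config$trait$type = "binary"` a thresholded latent trait yields a
#' near-balanced binary outcome column.
#'
#' @param config A [synth_config()] object; its homology settings are
#'   overridden.
#' @return List with `counts`, `metadata`, `phenotypes`, `regulators`,
#'   `truth`, `config`.
#' @export
generate_single_species <- function(config = synth_config()) {
  config$homology <- c(one_to_one = 0, one_to_two = 0, unmapped = 1)
  config$conserved_fraction <- 0
  bundle <- generate_dataset(config)
  list(
    counts = bundle$species_a$counts, metadata = bundle$species_a$metadata,
    phenotypes = bundle$species_a$phenotypes, regulators = bundle$regulators_a,
    truth = list(responsive = bundle$truth$responsive_a, gxn = bundle$truth$gxn_a,
                 causal = bundle$truth$causal_a, tf_edges = bundle$truth$tf_edges_a),
    config = config
  )
}

#' Simulate a sparse linear regulatory network
#'
#' Benchmark generator for network inference: regulator expression is
#' standard normal; each true edge makes one target a noisy linear function
#' of one regulator; remaining targets are pure noise.
#'
#' @param n_regulators,n_targets Network dimensions.
#' @param n_edges True regulator-to-target edges (one parent per wired
#'   target).
#' @param n_samples Samples (columns).
#' @param noise_sd Additive noise SD on wired targets.
#' @param seed Seed.
#' @return List: `expr` (genes x samples matrix over regulators then
#'   targets), `regulators`, `targets`, `true_edges` tibble.
#' @export
simulate_linear_network <- function(n_regulators = 50, n_targets = 100, n_edges = 20,
                                    n_samples = 100, noise_sd = 0.5, seed = 1) {
  withr::with_seed(as.integer(seed), {
    regs <- sprintf("tf%03d", seq_len(n_regulators))
    tars <- sprintf("tg%03d", seq_len(n_targets))
    R <- matrix(stats::rnorm(n_regulators * n_samples), n_regulators,
                dimnames = list(regs, sprintf("s%03d", seq_len(n_samples))))
    wired <- sample(tars, n_edges)
    parent <- sample(regs, n_edges, replace = TRUE)
    w <- stats::runif(n_edges, 1, 2) * sample(c(-1, 1), n_edges, replace = TRUE)
    TT <- matrix(stats::rnorm(n_targets * n_samples), n_targets,
                 dimnames = list(tars, colnames(R)))
    if (n_edges > 0) {
      TT[match(wired, tars), ] <- w * R[match(parent, regs), , drop = FALSE] +
        matrix(stats::rnorm(n_edges * n_samples, 0, noise_sd), n_edges)
    }
    list(expr = rbind(R, TT), regulators = regs, targets = tars,
         true_edges = tibble::tibble(regulator = parent, target = wired, weight = w))
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle> species A: %d genes x %d samples; species B: %d x %d; %d homolog pairs; %d conserved responsive; %d causal\n",
    nrow(x$species_a$counts), ncol(x$species_a$counts),
    nrow(x$species_b$counts), ncol(x$species_b$counts),
    nrow(x$homolog_map), nrow(x$truth$conserved_pairs), nrow(x$truth$causal_a)))
  invisible(x)
}
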