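# End-to-end orchestration: DEG derivation -> cross-species feature
# selection -> benchmarked trait prediction -> importance aggregation ->
# regulatory-network hub ranking -> candidate report, with TSV outputs and
# a YAML manifest.

write_stage_tsv <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  readr::write_tsv(tibble::as_tibble(x), file.path(out_dir, paste0(name, ".tsv")),
                   progress = FALSE)
}

#' Run the full evolutionarily informed prediction pipeline
#'
#' Executes, per species: expression filtering and leave-one-genotype-out
#' DEG derivation, within-species intersection; then cross-species homolog
#' conservation, the genotype-interaction filter on species B, control
#' feature-set construction (top-ranked DEGs, random expressed genes),
#' leave-one-genotype-out gradient-boosted trait prediction for every
#' feature set, pairwise Mann-Whitney benchmarking, importance aggregation
#' over the expressed universe, and tree-ensemble network inference over
#' the conserved targets with hub ranking and a candidate report.
#'
#' @param bundle A `synthetic_bundle`, or any list with the same shape
#'   (`species_a` / optionally `species_b`, each `counts`, `metadata`,
#'   `phenotypes`; `homolog_map`; `regulators_a` / `regulators_b`). A
#'   single-species bundle (`counts`, `metadata`, `phenotypes`,
#'   `regulators`) runs in single-species mode, where the feature set is
#'   the within-species consensus.
#' @param out_dir Optional output directory; all result tables are written
#'   there as TSV plus a YAML manifest.
#' @param trait Trait column in the phenotype tables.
#' @param iterations Prediction iterations per fold.
#' @param seed Master seed; all stage seeds derive from it.
#' @param params [deg_params()] for the condition contrast.
#' @param grid Hyperparameter grid.
#' @param grn [grn_params()] for network inference.
#' @param n_random_draws Random control sets per species.
#' @param predict_species Which species to run the prediction benchmark
#'   for (`"a"`, `"b"`, or both).
#' @param mode Performance summary mode (see [summarize_performance()]).
#' @return A list with the per-stage objects: fold sets, consensus and
#'   conserved gene sets, feature sets, prediction results, performance
#'   summaries, comparison table, importance tables, network objects,
#'   candidate reports and the funnel-count table.
#' @export
run_pipeline <- function(bundle, out_dir = NULL, trait = "trait", iterations = 100,
                         seed = 1, params = deg_params(), grid = default_hyperparam_grid(),
                         grn = grn_params(), n_random_draws = 1,
                         predict_species = c("a", "b"),
                         mode = c("per_genotype", "pooled")) {
  mode <- match.arg(mode)
  predict_species <- match.arg(predict_species, several.ok = TRUE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  two_species <- !is.null(bundle$species_b)
  sp <- if (two_species) {
    list(a = c(bundle$species_a, list(regulators = bundle$regulators_a)),
         b = c(bundle$species_b, list(regulators = bundle$regulators_b)))
  } else {
    list(a = list(counts = bundle$counts, metadata = bundle$metadata,
                  phenotypes = bundle$phenotypes, regulators = bundle$regulators))
  }
  seeds <- derive_seeds(seed, 8)

  # Stage 1: per-species round-robin DEGs and consensus
  stage1 <- purrr::imap(sp, function(s, nm) {
    folds <- loo_deg_rounds(s$counts, s$metadata, params)
    consensus <- intersect_folds(folds)
    full <- call_degs(s$counts, s$metadata, params)
    expressed <- full$table$gene
    list(folds = folds, consensus = consensus, full = full, expressed = expressed)
  })

  # Stage 2: feature selection
  if (two_species) {
    conserved <- cross_species_conserved(stage1$a$consensus, stage1$b$consensus,
                                         bundle$homolog_map)
    gxn_params <- params
    gxn_params$model <- "condition_by_genotype_interaction"
    gxn_b <- call_degs(sp$b$counts, sp$b$metadata, gxn_params)
    features <- list(
      a = feature_set(conserved$conserved_a, "cross_species_conserved"),
      b = feature_set(apply_interaction_filter(conserved$conserved_b, gxn_b$genes),
                      "cross_species_conserved")
    )
  } else {
    conserved <- NULL
    gxn_b <- NULL
    features <- list(a = feature_set(stage1$a$consensus, "within_species_consensus"))
  }

  # Stage 3: benchmarked prediction per requested species
  predictions <- list()
  for (nm in intersect(predict_species, names(sp))) {
    s <- sp[[nm]]
    fs <- features[[nm]]
    if (fs$k == 0) {
      rlang::warn(sprintf("Species %s has an empty feature set; skipping prediction.", nm))
      next
    }
    controls <- control_feature_sets(stage1[[nm]]$full$table, stage1[[nm]]$expressed,
                                     k = fs$k, n_random_draws = n_random_draws,
                                     seed = seeds[2])
    all_sets <- c(stats::setNames(list(fs), fs$provenance), controls)
    results <- purrr::imap(all_sets, function(set, set_name) {
      loo_predict(s$counts, s$metadata, s$phenotypes, trait = trait, features = set,
                  iterations = iterations, seed = seeds[3], grid = grid)
    })
    summaries <- purrr::map(results, summarize_performance, mode = mode)
    comparison <- compare_feature_sets(summaries)
    importance <- aggregate_importance(results[[fs$provenance]],
                                       universe = stage1[[nm]]$expressed)
    predictions[[nm]] <- list(feature_sets = all_sets, results = results,
                              summaries = summaries, comparison = comparison,
                              importance = importance)
  }

  # Stage 4: regulatory network + candidates per species with predictions
  networks <- purrr::imap(predictions, function(p, nm) {
    s <- sp[[nm]]
    regs <- intersect(s$regulators, stage1[[nm]]$expressed)
    if (length(regs) == 0) {
      rlang::warn(sprintf("Species %s has no expressed regulator; skipping GRN.", nm))
      return(NULL)
    }
    expr <- log2_cpm(s$counts[stage1[[nm]]$expressed, , drop = FALSE])
    edges <- infer_grn(expr, regs, features[[nm]]$genes, grn)
    pruned <- prune_top_fraction(edges, grn$edge_fraction)
    ranks <- connectivity_ranking(pruned)
    candidates <- integrate_candidates(p$importance, ranks, regs)
    list(edges = edges, pruned = pruned, tf_ranks = ranks, candidates = candidates)
  })

  funnel <- purrr::imap_dfr(stage1, function(s1, nm) {
    tibble::tibble(
      species = nm,
      stage = c("expressed", "per_fold_median_degs", "consensus_degs",
                "conserved", "features"),
      n = c(length(s1$expressed), as.integer(stats::median(lengths(s1$folds$sets))),
            length(s1$consensus),
            if (two_species) length(conserved[[paste0("conserved_", nm)]]) else NA_integer_,
            if (!is.null(features[[nm]])) features[[nm]]$k else NA_integer_)
    )
  })

  if (!is.null(out_dir)) {
    for (nm in names(stage1)) {
      write_stage_tsv(stage1[[nm]]$full$table, out_dir, paste0("deg_table_", nm))
      write_stage_tsv(tibble::tibble(fold = rep(names(stage1[[nm]]$folds$sets),
                                                lengths(stage1[[nm]]$folds$sets)),
                                     gene = unlist(stage1[[nm]]$folds$sets, use.names = FALSE)),
                      out_dir, paste0("fold_degs_", nm))
    }
    for (nm in names(predictions)) {
      p <- predictions[[nm]]
      write_stage_tsv(dplyr::bind_rows(purrr::imap(p$results, function(r, fs) {
        dplyr::mutate(r$predictions, feature_set = fs, .before = 1)
      })), out_dir, paste0("predictions_", nm))
      write_stage_tsv(dplyr::bind_rows(purrr::imap(p$summaries, function(s, fs) {
        dplyr::mutate(tibble::as_tibble(s), feature_set = fs, .before = 1)
      })), out_dir, paste0("performance_", nm))
      write_stage_tsv(p$comparison, out_dir, paste0("comparison_", nm))
      write_stage_tsv(p$importance, out_dir, paste0("importance_", nm))
      for (fs in names(p$feature_sets)) {
        set <- p$feature_sets[[fs]]
        writeLines(set$genes, file.path(out_dir, sprintf("features_%s_%s.txt", nm, fs)))
        yaml::write_yaml(list(provenance = set$provenance, k = set$k,
                              seed = if (is.na(set$seed)) NULL else set$seed),
                         file.path(out_dir, sprintf("features_%s_%s.yaml", nm, fs)))
      }
    }
    for (nm in names(networks)) {
      if (is.null(networks[[nm]])) next
      write_stage_tsv(networks[[nm]]$pruned, out_dir, paste0("grn_edges_", nm))
      write_stage_tsv(networks[[nm]]$tf_ranks, out_dir, paste0("tf_ranks_", nm))
      write_stage_tsv(networks[[nm]]$candidates, out_dir, paste0("candidates_", nm))
    }
    write_stage_tsv(funnel, out_dir, "funnel_counts")
    write_manifest(list(
      seed = seed, iterations = iterations, trait = trait, mode = mode,
      deg_params = unclass(params), grn_params = unclass(grn),
      n_random_draws = n_random_draws,
      grid_hash = rlang::hash(grid),
      stages = list(
        expressed = purrr::map_int(stage1, ~ length(.x$expressed)),
        consensus = purrr::map_int(stage1, ~ length(.x$consensus))
      )
    ), file.path(out_dir, "manifest.yaml"))
  }

  structure(list(stage1 = stage1, conserved = conserved, gxn_b = gxn_b,
                 features = features, predictions = predictions, networks = networks,
                 funnel = funnel, seed = seed, out_dir = out_dir),
            class = "evotrait_run")
}

#' @export
print.evotrait_run <- function(x, ...) {
  cat("<evotrait_run>\n")
  print(x$funnel, n = nrow(x$funnel))
  for (nm in names(x$predictions)) {
    ov <- purrr::map_dbl(x$predictions[[nm]]$summaries, ~ attr(.x, "overall_mean_r"))
    cat(sprintf("species %s mean r: %s\n", nm,
                paste(sprintf("%s = %.3f", names(ov), ov), collapse = ", ")))
  }
  invisible(x)
}
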