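# Round-robin leave-one-genotype-out DEG derivation, within-species
# intersection, cross-species homolog conservation, GxN filtering, and
# control feature sets for benchmarking.

#' Leave-one-genotype-out DEG rounds
#'
#' For every genotype g, calls differential expression on all samples
#' except those of g. The held-out genotype can never influence its own
#' fold's gene list, by construction: its samples are dropped before
#' filtering, normalization and fitting.
#'
#' @param counts Count matrix.
#' @param metadata Matched sample metadata.
#' @param params A [deg_params()] object.
#' @return A `fold_deg_sets` object: named list `sets` (gene IDs per
#'   held-out genotype) and `tables` (per-fold `deg_table`s).
#' @export
loo_deg_rounds <- function(counts, metadata, params = deg_params()) {
  metadata <- validate_metadata(metadata, counts)
  genotypes <- unique(as.character(metadata$genotype))
  if (length(genotypes) < 3) stop_design("Round-robin DEG derivation needs >= 3 genotypes.")
  both <- vapply(genotypes, function(g) {
    length(unique(metadata$condition[metadata$genotype == g])) == 2
  }, logical(1))
  if (!all(both)) {
    stop_design(sprintf("Genotype(s) with samples in only one condition: %s.",
                        paste(genotypes[!both], collapse = ", ")))
  }
  folds <- purrr::map(genotypes, function(g) {
    keep <- metadata$genotype != g
    call_degs(counts[, keep, drop = FALSE], metadata[keep, , drop = FALSE], params)
  })
  names(folds) <- genotypes
  structure(list(sets = purrr::map(folds, "genes"), tables = purrr::map(folds, "table")),
            class = "fold_deg_sets")
}

#' @export
print.fold_deg_sets <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("<fold_deg_sets> %d folds; DEG set sizes %d-%d (median %d); consensus %d\n",
              length(sizes), min(sizes), max(sizes), as.integer(stats::median(sizes)),
              length(intersect_folds(x))))
  invisible(x)
}

#' Intersect per-fold gene lists
#'
#' The consensus set: genes present in every fold's list.
#'
#' @param folds A `fold_deg_sets` object or a plain list of character
#'   vectors.
#' @return Sorted character vector (possibly empty, with a warning).
#' @export
intersect_folds <- function(folds) {
  sets <- if (inherits(folds, "fold_deg_sets")) folds$sets else folds
  if (length(sets) == 0) stop_value("No fold sets to intersect.")
  out <- sort(Reduce(intersect, sets))
  if (length(out) == 0) rlang::warn("Fold intersection is empty.")
  out
}

#' Cross-species conserved genes
#'
#' A gene is conserved if it is differential in its own species and linked
#' through the homolog map to a differential gene in the other species.
#' With `strictness = "any"` (default) one differential homolog suffices;
#' `"all"` requires every mapped homolog to be differential.
#'
#' @param set_a,set_b Gene sets (species A / species B IDs).
#' @param map A `homolog_map`.
#' @param strictness `"any"` or `"all"`.
#' @return List with sorted `conserved_a` and `conserved_b`.
#' @export
cross_species_conserved <- function(set_a, set_b, map, strictness = c("any", "all")) {
  strictness <- match.arg(strictness)
  if (nrow(map) == 0) stop_value("Homolog map is empty.")
  conserved_one_way <- function(set_self, set_other, self_col, other_col) {
    sub <- map[map[[self_col]] %in% set_self, , drop = FALSE]
    hit <- split(sub[[other_col]] %in% set_other, sub[[self_col]])
    ok <- vapply(hit, if (strictness == "any") any else all, logical(1))
    sort(names(ok)[ok])
  }
  n_unmapped_a <- length(setdiff(set_a, map$gene_a))
  n_unmapped_b <- length(setdiff(set_b, map$gene_b))
  rlang::inform(sprintf("cross_species_conserved: %d A / %d B input genes without any homolog.",
                        n_unmapped_a, n_unmapped_b), class = "evotrait_log")
  list(conserved_a = conserved_one_way(set_a, set_b, "gene_a", "gene_b"),
       conserved_b = conserved_one_way(set_b, set_a, "gene_b", "gene_a"))
}

#' Intersect a conserved set with a genotype-interaction set
#'
#' Second-round within-species filter: keeps conserved genes whose
#' condition response also depends on genotype.
#'
#' @param conserved,gxn_set Gene sets over the same species' ID space.
#' @return Sorted intersection (warned if empty).
#' @export
apply_interaction_filter <- function(conserved, gxn_set) {
  out <- sort(intersect(conserved, gxn_set))
  if (length(out) == 0) rlang::warn("Interaction filter left no genes.")
  out
}

#' Construct a feature set
#'
#' @param genes Gene IDs (unique).
#' @param provenance One of `cross_species_conserved`,
#'   `within_species_consensus`, `top_deg`, `random_expressed`.
#' @param seed Seed used for random sets (NA otherwise).
#' @return A `feature_set` object.
#' @export
feature_set <- function(genes, provenance, seed = NA_integer_) {
  genes <- unique(as.character(genes))
  provenance <- match.arg(provenance, c("cross_species_conserved", "within_species_consensus",
                                        "top_deg", "random_expressed"))
  structure(list(genes = genes, provenance = provenance, seed = seed, k = length(genes)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s, k = %d%s\n", x$provenance, x$k,
              if (!is.na(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  invisible(x)
}

#' Control feature sets for benchmarking
#'
#' Builds the comparison sets evaluated against the conserved features:
#' the `k` genes with smallest FDR (ties by p-value then gene ID), and
#' `n_random_draws` seeded draws of `k` expressed genes without
#' replacement.
#'
#' @param deg_table A `deg_table` covering the expressed genes.
#' @param expressed Expressed-gene universe (character vector).
#' @param k Set size.
#' @param n_random_draws Number of random sets.
#' @param seed Seed for the random draws.
#' @return Named list of [feature_set()] objects (`top_deg`, `random_1`,
#'   ...).
#' @export
control_feature_sets <- function(deg_table, expressed, k, n_random_draws = 1, seed = 1) {
  if (k > length(expressed)) {
    stop_size(sprintf("k = %d exceeds the expressed universe (%d genes).", k, length(expressed)))
  }
  ranked <- dplyr::arrange(dplyr::filter(tibble::as_tibble(deg_table), .data$gene %in% expressed),
                           .data$fdr, .data$pvalue, .data$gene)
  top <- feature_set(ranked$gene[seq_len(k)], "top_deg")
  draw_seeds <- derive_seeds(seed, n_random_draws)
  randoms <- purrr::imap(draw_seeds, function(s, i) {
    feature_set(withr::with_seed(s, sample(expressed, k)), "random_expressed", seed = s)
  })
  names(randoms) <- paste0("random_", seq_len(n_random_draws))
  c(list(top_deg = top), randoms)
}
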