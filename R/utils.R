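# Internal helpers: typed errors, validation, seed derivation.

abort_evotrait <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "evotrait_error"), ...)
}

stop_format <- function(message, ...) abort_evotrait(message, "evotrait_format_error", ...)
stop_consistency <- function(message, ...) abort_evotrait(message, "evotrait_consistency_error", ...)
stop_value <- function(message, ...) abort_evotrait(message, "evotrait_value_error", ...)
stop_lookup <- function(message, ...) abort_evotrait(message, "evotrait_lookup_error", ...)
stop_design <- function(message, ...) abort_evotrait(message, "evotrait_design_error", ...)
stop_size <- function(message, ...) abort_evotrait(message, "evotrait_size_error", ...)
stop_mode <- function(message, ...) abort_evotrait(message, "evotrait_mode_error", ...)
stop_config <- function(message, ...) abort_evotrait(message, "evotrait_config_error", ...)

#' Validate a genes-by-samples count matrix
#'
#' Checks the invariants the rest of the pipeline relies on: unique gene and
#' sample identifiers, non-negative integral counts, at least one gene and
#' two samples.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns, with
#'   `rownames` (gene IDs) and `colnames` (sample IDs).
#' @return The validated matrix (storage mode coerced to integer-valued
#'   numeric), invisibly usable in place.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop_format("`counts` must be a matrix with gene rownames and sample colnames.")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_format("`counts` must carry gene IDs as rownames and sample IDs as colnames.")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    stop_format(sprintf("Duplicate gene ID in counts: '%s'.", dup))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1]
    stop_format(sprintf("Duplicate sample ID in counts: '%s'.", dup))
  }
  if (nrow(counts) < 1 || ncol(counts) < 2) {
    stop_format("Counts need at least 1 gene and 2 samples.")
  }
  if (anyNA(counts)) stop_value("Counts contain missing values.")
  if (any(counts < 0)) stop_value("Counts contain negative values.")
  if (any(counts != round(counts))) stop_value("Counts contain non-integer values.")
  counts
}

#' Validate sample metadata against a count matrix
#'
#' @param metadata Data frame with columns `sample_id`, `genotype`,
#'   `condition`, `replicate`.
#' @param counts Matched count matrix; metadata rows are reordered to the
#'   column order of `counts`.
#' @param two_condition Require exactly two condition levels (the default,
#'   matching a low/high treatment design).
#' @return A tibble in count-column order.
#' @export
validate_metadata <- function(metadata, counts, two_condition = TRUE) {
  metadata <- tibble::as_tibble(metadata)
  needed <- c("sample_id", "genotype", "condition", "replicate")
  missing_cols <- setdiff(needed, names(metadata))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("Metadata is missing column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop_format("Metadata sample_id values must be unique.")
  }
  extra <- setdiff(metadata$sample_id, colnames(counts))
  absent <- setdiff(colnames(counts), metadata$sample_id)
  if (length(absent) > 0) {
    stop_consistency(sprintf("Sample(s) in counts but not metadata: %s.", paste(absent, collapse = ", ")))
  }
  if (length(extra) > 0) {
    stop_consistency(sprintf("Sample(s) in metadata but not counts: %s.", paste(extra, collapse = ", ")))
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  if (length(unique(metadata$genotype)) < 2) {
    stop_design("At least 2 genotypes are required.")
  }
  n_cond <- length(unique(metadata$condition))
  if (two_condition && n_cond != 2) {
    stop_design(sprintf("Exactly 2 condition levels required, found %d.", n_cond))
  }
  metadata
}

# Deterministic child seeds from one master seed; keeps everything < 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
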