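#' Read a count matrix and its sample metadata
#'
#' Reads a delimited genes-by-samples count table (gene IDs in the first
#' column, sample IDs in the header) together with a metadata table mapping
#' every sample to genotype, condition and replicate. Gene IDs are kept
#' verbatim: no case folding and no version-suffix stripping.
#'
#' @param counts_path Path to the count table.
#' @param metadata_path Path to the metadata table; must contain columns
#'   `sample_id`, `genotype`, `condition`, `replicate`.
#' @param delim Field delimiter, tab by default; pass `","` for CSV exports.
#' @param two_condition Require exactly two condition levels.
#' @return A list with elements `counts` (validated matrix) and `metadata`
#'   (tibble in count-column order).
#' @export
read_counts <- function(counts_path, metadata_path, delim = "\t", two_condition = TRUE) {
  raw <- readr::read_delim(counts_path, delim = delim, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 3) stop_format("Count table needs a gene-ID column plus at least 2 samples.")
  gene_ids <- as.character(raw[[1]])
  counts <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(counts)) stop_value("Count table contains non-numeric entries.")
  rownames(counts) <- gene_ids
  counts <- validate_counts(counts)
  metadata <- readr::read_delim(metadata_path, delim = delim, show_col_types = FALSE, progress = FALSE)
  metadata <- validate_metadata(metadata, counts, two_condition = two_condition)
  list(counts = counts, metadata = metadata)
}

#' Write a count matrix with metadata
#'
#' Inverse of [read_counts()]; used by the pipeline and the synthetic-data
#' CLI to materialize datasets as TSV.
#'
#' @param counts Validated count matrix.
#' @param metadata Matched metadata tibble.
#' @param counts_path,metadata_path Output paths.
#' @export
write_counts <- function(counts, metadata, counts_path, metadata_path) {
  tbl <- tibble::as_tibble(counts, rownames = "gene_id")
  readr::write_tsv(tbl, counts_path, progress = FALSE)
  readr::write_tsv(tibble::as_tibble(metadata), metadata_path, progress = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' Read a two-column cross-species homolog map
#'
#' Many-to-many pairs are allowed; duplicate pairs are removed. The map is
#' symmetric: lookups in either direction use the same pair set.
#'
#' @param path Path to a 2-column delimited file (species A gene, species B
#'   gene). A header row is detected and kept only if its fields are the
#'   literal names `gene_a`/`gene_b`.
#' @param delim Field delimiter.
#' @return A tibble of class `homolog_map` with columns `gene_a`, `gene_b`.
#' @export
read_homolog_map <- function(path, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, col_names = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (nrow(raw) == 0) {
    rlang::warn("Homolog map file is empty; returning an empty map.")
    return(new_homolog_map(tibble::tibble(gene_a = character(), gene_b = character())))
  }
  if (ncol(raw) != 2) stop_format(sprintf("Homolog map must have exactly 2 columns, found %d.", ncol(raw)))
  names(raw) <- c("gene_a", "gene_b")
  if (identical(tolower(unlist(raw[1, ])), c("gene_a", "gene_b"))) raw <- raw[-1, , drop = FALSE]
  if (anyNA(raw) || any(raw == "")) stop_format("Homolog map contains rows with a missing field.")
  new_homolog_map(raw)
}

new_homolog_map <- function(pairs) {
  pairs <- dplyr::distinct(tibble::as_tibble(pairs))
  structure(pairs, class = c("homolog_map", class(pairs)))
}

#' @export
print.homolog_map <- function(x, ...) {
  cat(sprintf("<homolog_map> %d pairs, %d species-A genes, %d species-B genes\n",
              nrow(x), dplyr::n_distinct(x$gene_a), dplyr::n_distinct(x$gene_b)))
  NextMethod()
}

#' Write a homolog map as 2-column TSV
#' @param map A `homolog_map` tibble.
#' @param path Output path.
#' @export
write_homolog_map <- function(map, path) {
  readr::write_tsv(tibble::as_tibble(map), path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a phenotype table and select traits
#'
#' Rows with a missing value for a requested trait are retained and flagged
#' (column `missing`), never dropped silently; exclusion happens per trait
#' at analysis time.
#'
#' @param path Path to a delimited table keyed by `sample_id` or by
#'   (`genotype`, `condition`, `replicate`).
#' @param trait Name(s) of trait column(s) to keep.
#' @param delim Field delimiter.
#' @return A tibble with the key columns, the requested traits and a logical
#'   `missing` column (TRUE where any requested trait is absent/non-finite).
#' @export
read_phenotypes <- function(path, trait, delim = "\t") {
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  select_traits(tbl, trait)
}

#' Select traits from an in-memory phenotype table
#'
#' @param tbl Data frame keyed by `sample_id` or (`genotype`, `condition`,
#'   `replicate`).
#' @param trait Trait column name(s).
#' @return See [read_phenotypes()].
#' @export
select_traits <- function(tbl, trait) {
  tbl <- tibble::as_tibble(tbl)
  keys <- intersect(c("sample_id", "genotype", "condition", "replicate"), names(tbl))
  if (length(keys) == 0) stop_format("Phenotype table needs sample_id or genotype/condition/replicate key columns.")
  available <- setdiff(names(tbl), keys)
  unknown <- setdiff(trait, names(tbl))
  if (length(unknown) > 0) {
    stop_lookup(sprintf("Unknown trait(s) %s; available traits: %s.",
                        paste(unknown, collapse = ", "), paste(available, collapse = ", ")))
  }
  if (anyDuplicated(tbl[keys])) stop_format("Phenotype table keys are not unique.")
  out <- tbl[, c(keys, trait), drop = FALSE]
  vals <- out[, trait, drop = FALSE]
  out$missing <- apply(vals, 1L, function(v) any(!is.finite(suppressWarnings(as.numeric(v)))))
  out
}

#' Read a regulator (transcription factor) list
#'
#' @param path Text file, one gene ID per line.
#' @return Character vector of unique, non-empty IDs.
#' @export
read_regulators <- function(path) {
  ids <- readr::read_lines(path, progress = FALSE)
  ids <- unique(ids[nzchar(trimws(ids))])
  trimws(ids)
}

#' Write a run manifest
#'
#' Records inputs, parameters and seeds for a run as YAML so any output can
#' be traced to the exact invocation that produced it.
#'
#' @param manifest Named list.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  manifest$evotrait_version <- as.character(utils::packageVersion("evotrait"))
  manifest$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
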