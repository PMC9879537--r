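#' Construct an expression map
#'
#' An expression map is a gene x sample matrix of raw RNA-seq read counts
#' (a transcriptome atlas): `K` genes by `m` samples, where each sample
#' carries a biological sample label (organ/stage/condition) and a replicate
#' index. Counts are kept raw: the classifier consumes non-normalized read
#' counts, and normalization only happens inside the distance baseline.
#'
#' @param counts Matrix of non-negative integer read counts with gene IDs as
#'   row names and sample IDs as column names.
#' @param species_id Species identifier string.
#' @param sample_info Optional tibble with columns `sample_id` and
#'   `sample_label` (and optionally `replicate`). When absent, labels are
#'   parsed from sample IDs of the form `"<label>.<replicate>"`; IDs without
#'   a numeric suffix become single-replicate labels.
#' @return An `expression_map` object: a list with elements `species_id`,
#'   `counts` (the matrix) and `samples` (a tibble of sample metadata).
#' @examples
#' counts <- matrix(0:5, nrow = 2, dimnames = list(c("g1", "g2"),
#'                  c("root.1", "root.2", "leaf.1")))
#' expression_map(counts, "demo")
#' @export
expression_map <- function(counts, species_id, sample_info = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_format("counts must carry gene IDs as rownames and sample IDs as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    abort_format(paste0("duplicate gene ID: ",
                        rownames(counts)[duplicated(rownames(counts))][1]))
  }
  if (anyDuplicated(colnames(counts))) {
    abort_format("duplicate sample IDs in counts matrix")
  }
  if (anyNA(counts)) abort_format("counts contain missing values (ragged input?)")
  if (!is.numeric(counts)) abort_format("counts must be numeric")
  bad <- which(counts < 0 | counts != round(counts))
  if (length(bad)) {
    g <- rownames(counts)[(bad[1] - 1L) %% nrow(counts) + 1L]
    abort_format(paste0("negative or non-integer count for gene ", g))
  }
  storage.mode(counts) <- "double"

  samples <- build_sample_info(colnames(counts), sample_info)
  structure(
    list(species_id = as.character(species_id), counts = counts, samples = samples),
    class = "expression_map"
  )
}

build_sample_info <- function(sample_ids, sample_info) {
  if (is.null(sample_info)) {
    m <- regmatches(sample_ids, regexec("^(.*)\\.([0-9]+)$", sample_ids))
    label <- vapply(seq_along(m), function(i) {
      if (length(m[[i]]) == 3L) m[[i]][2] else sample_ids[i]
    }, character(1))
    replicate <- vapply(seq_along(m), function(i) {
      if (length(m[[i]]) == 3L) as.integer(m[[i]][3]) else 1L
    }, integer(1))
    tibble::tibble(sample_id = sample_ids, sample_label = label,
                   replicate = replicate)
  } else {
    sample_info <- tibble::as_tibble(sample_info)
    if (!all(c("sample_id", "sample_label") %in% names(sample_info))) {
      abort_config("sample_info needs columns sample_id and sample_label")
    }
    missing <- setdiff(sample_ids, sample_info$sample_id)
    if (length(missing)) {
      abort_config(paste0("sample_info lacks entries for: ",
                          paste(missing, collapse = ", ")))
    }
    info <- sample_info[match(sample_ids, sample_info$sample_id), ]
    if (!"replicate" %in% names(info)) {
      info <- dplyr::mutate(
        dplyr::group_by(info, .data$sample_label),
        replicate = dplyr::row_number())
      info <- dplyr::ungroup(info)
      info <- info[match(sample_ids, info$sample_id), ]
    }
    dplyr::select(info, "sample_id", "sample_label", "replicate")
  }
}

#' @export
print.expression_map <- function(x, ...) {
  cat("<expression_map> species:", x$species_id,
      "|", nrow(x$counts), "genes x", ncol(x$counts), "samples",
      "(", dplyr::n_distinct(x$samples$sample_label), "sample labels )\n")
  invisible(x)
}

#' @export
dim.expression_map <- function(x) dim(x$counts)

#' Read an expression map from TSV
#'
#' Expects a header row of sample IDs and one row per gene: the gene ID in
#' the first column followed by integer read counts. Ragged rows, duplicate
#' gene IDs and negative or non-integer counts are rejected.
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_map
#' @return An [expression_map()] object.
#' @export
read_expression_map <- function(path, species_id, sample_info = NULL) {
  df <- suppressWarnings(readr::read_tsv(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE))
  if (nrow(df) == 0 || ncol(df) < 2) {
    abort_format(paste0("empty or column-less expression map: ", path))
  }
  genes <- df[[1]]
  counts <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  counts <- matrix(counts, nrow = nrow(df),
                   dimnames = list(genes, names(df)[-1]))
  if (anyNA(counts)) {
    bad <- genes[rowSums(is.na(counts)) > 0][1]
    abort_format(paste0("ragged or non-numeric row for gene ", bad, " in ", path))
  }
  expression_map(counts, species_id, sample_info)
}

#' Write an expression map to TSV
#'
#' Inverse of [read_expression_map()]: the written file round-trips to an
#' identical map (same counts, same gene and sample order).
#'
#' @param map An [expression_map()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_map <- function(map, path) {
  df <- tibble::as_tibble(map$counts, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Tidy an expression map to long form
#'
#' @param map An [expression_map()].
#' @return A tibble with columns `gene_id`, `sample_id`, `sample_label`,
#'   `replicate`, `count`.
#' @export
map_to_tibble <- function(map) {
  long <- tibble::as_tibble(map$counts, rownames = "gene_id")
  long <- tidyr::pivot_longer(long, -"gene_id", names_to = "sample_id",
                              values_to = "count")
  dplyr::left_join(long, map$samples, by = "sample_id")
}

# columns of `map` holding each replicate of a sample label
label_columns <- function(map, label) {
  which(map$samples$sample_label == label)
}

abort_format <- function(msg) rlang::abort(msg, class = "crossexpress_format_error")
abort_config <- function(msg) rlang::abort(msg, class = "crossexpress_config_error")
abort_lookup <- function(msg) rlang::abort(msg, class = "crossexpress_lookup_error")
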