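#' Construct a set of interspecific gene pairs
#'
#' A pair set is a tibble of (gene_a, gene_b) rows, ordered by species role:
#' `gene_a` always belongs to species A, `gene_b` to species B. Duplicate
#' pairs are collapsed with a warning. The `label` records how the set is
#' used: `"positive"` (orthopairs), `"negative"` (random pairs) or
#' `"query"` (pairs to be scored).
#'
#' @param gene_a,gene_b Character vectors of equal length.
#' @param label One of `"positive"`, `"negative"`, `"query"`.
#' @return A `pair_set` tibble with columns `gene_a`, `gene_b` and a
#'   `label` attribute.
#' @export
pair_set <- function(gene_a = character(), gene_b = character(),
                     label = c("query", "positive", "negative")) {
  label <- match.arg(label)
  stopifnot(length(gene_a) == length(gene_b))
  df <- tibble::tibble(gene_a = as.character(gene_a),
                       gene_b = as.character(gene_b))
  dup <- duplicated(df)
  if (any(dup)) {
    rlang::warn(paste0("collapsed ", sum(dup), " duplicate pair(s)"))
    df <- df[!dup, ]
  }
  new_pair_set(df, label)
}

new_pair_set <- function(df, label) {
  structure(tibble::as_tibble(df), label = label,
            class = c("pair_set", class(tibble::tibble())))
}

#' @export
print.pair_set <- function(x, ...) {
  cat("<pair_set>", nrow(x), "pairs, label:", pair_label(x), "\n")
  NextMethod()
}

#' Label of a pair set
#' @param pairs A [pair_set()].
#' @return The label string.
#' @export
pair_label <- function(pairs) attr(pairs, "label") %||% "query"

pair_key <- function(df) paste(df$gene_a, df$gene_b, sep = "\r")

#' Read 1-to-1 orthopairs from a two-column TSV
#'
#' The file is headerless: species-A gene ID, tab, species-B gene ID. Such
#' orthopair lists serve as the positive training set for the Expression
#' Score classifier, on the assumption that 1-to-1 orthologs tend to retain
#' similar expression profiles.
#'
#' @param path Path to the TSV file.
#' @return A [pair_set()] with label `"positive"`; duplicates collapsed
#'   with a warning, an empty file yields an empty (flagged) set.
#' @export
read_orthopairs <- function(path) {
  df <- suppressWarnings(readr::read_tsv(
    path, col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE))
  if (nrow(df) == 0) {
    rlang::warn(paste0("empty orthopair file: ", path))
    return(pair_set(label = "positive"))
  }
  if (ncol(df) != 2) {
    abort_format(paste0("orthopair file must have exactly 2 columns, found ",
                        ncol(df), ": ", path))
  }
  pair_set(df[[1]], df[[2]], label = "positive")
}

#' Write a pair set to a headerless two-column TSV
#' @param pairs A [pair_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthopairs <- function(pairs, path) {
  readr::write_tsv(pairs[, c("gene_a", "gene_b")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read orthogroups
#'
#' Accepts two dialects, auto-detected from the header:
#' * OrthoFinder `Orthogroups.tsv`: a group-ID column plus one column per
#'   species whose cells are `", "`-separated gene lists (possibly empty);
#' * long format: columns `group_id`, `species`, `gene`.
#'
#' Groups with an empty gene list for either requested species are dropped:
#' only interspecific groups (at least one gene on each side) take part in
#' ES scoring and fractionation.
#'
#' @param path Path to the TSV file.
#' @param species_a,species_b Column (or `species` value, for the long
#'   dialect) naming each species.
#' @return A tibble with columns `group_id`, `genes_a` (list), `genes_b`
#'   (list), `n_a`, `n_b`.
#' @export
read_orthogroups <- function(path, species_a, species_b) {
  df <- suppressWarnings(readr::read_tsv(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE))
  if (all(c("group_id", "species", "gene") %in% names(df))) {
    return(groups_from_long(df, species_a, species_b))
  }
  missing <- setdiff(c(species_a, species_b), names(df))
  if (length(missing)) {
    abort_config(paste0("species column(s) absent from ", path, ": ",
                        paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    group_id = df[[1]],
    genes_a = split_gene_list(df[[species_a]]),
    genes_b = split_gene_list(df[[species_b]])
  )
  finalize_groups(out)
}

split_gene_list <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, ",[ ]*"), function(g) unique(g[nzchar(g)]))
}

groups_from_long <- function(df, species_a, species_b) {
  if (!any(df$species %in% c(species_a, species_b))) {
    abort_config(paste0("no rows for species ", species_a, "/", species_b))
  }
  ids <- unique(df$group_id)
  ga <- split(df$gene[df$species == species_a], df$group_id[df$species == species_a])
  gb <- split(df$gene[df$species == species_b], df$group_id[df$species == species_b])
  out <- tibble::tibble(
    group_id = ids,
    genes_a = lapply(ids, function(i) unique(ga[[i]]) %||% character()),
    genes_b = lapply(ids, function(i) unique(gb[[i]]) %||% character())
  )
  finalize_groups(out)
}

finalize_groups <- function(out) {
  out$n_a <- lengths(out$genes_a)
  out$n_b <- lengths(out$genes_b)
  out[out$n_a >= 1L & out$n_b >= 1L, ]
}

#' Write orthogroups in the OrthoFinder wide dialect
#' @param groups An orthogroup tibble from [read_orthogroups()].
#' @param path Output path.
#' @param species_a,species_b Column names to write.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(groups, path, species_a = "species_a",
                              species_b = "species_b") {
  df <- tibble::tibble(
    Orthogroup = groups$group_id,
    a = vapply(groups$genes_a, paste, character(1), collapse = ", "),
    b = vapply(groups$genes_b, paste, character(1), collapse = ", ")
  )
  names(df)[2:3] <- c(species_a, species_b)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' All interspecific pairs within orthogroups
#'
#' Expands every orthogroup into its complete set of cross-species gene
#' pairs (the candidate edges of the bipartite graph that fractionation
#' later thresholds).
#'
#' @param groups Orthogroup tibble from [read_orthogroups()].
#' @return A `query`-labelled [pair_set()] with an extra `group_id` column.
#' @export
orthogroup_pairs <- function(groups) {
  if (nrow(groups) == 0) {
    out <- tibble::tibble(gene_a = character(), gene_b = character(),
                          group_id = character())
    return(new_pair_set(out, "query"))
  }
  rows <- purrr::pmap(
    list(groups$group_id, groups$genes_a, groups$genes_b),
    function(id, ga, gb) {
      grid <- expand.grid(gene_a = ga, gene_b = gb,
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      grid$group_id <- id
      grid
    })
  out <- dplyr::bind_rows(rows)
  dup <- duplicated(out[, c("gene_a", "gene_b")])
  new_pair_set(out[!dup, ], "query")
}

#' Orthopairs implied by 1-to-1 orthogroups
#' @param groups Orthogroup tibble.
#' @return A positive-labelled [pair_set()] of the 1x1 groups' pairs.
#' @export
orthopairs_from_groups <- function(groups) {
  one <- groups[groups$n_a == 1L & groups$n_b == 1L, ]
  pair_set(unlist(one$genes_a) %||% character(),
           unlist(one$genes_b) %||% character(), label = "positive")
}

#' Concatenated feature vector for one gene pair
#'
#' The classifier's input for a pair is the concatenation of the two genes'
#' raw read-count profiles: first the species-A gene's row of map A in map-A
#' sample order, then the species-B gene's row of map B. No normalization is
#' applied.
#'
#' @param gene_a,gene_b Gene IDs.
#' @param map_a,map_b [expression_map()] objects for species A and B.
#' @return A numeric vector of length `m_A + m_B`.
#' @export
build_feature_vector <- function(gene_a, gene_b, map_a, map_b) {
  drop(feature_matrix(pair_set(gene_a, gene_b), map_a, map_b))
}

#' Feature matrix for a pair set
#'
#' Row-binds [build_feature_vector()] over all pairs; vectorized.
#'
#' @param pairs A [pair_set()] (or tibble with `gene_a`, `gene_b`).
#' @inheritParams build_feature_vector
#' @return A numeric matrix, one row per pair, `m_A + m_B` columns named
#'   `A:<sample>` / `B:<sample>`.
#' @export
feature_matrix <- function(pairs, map_a, map_b) {
  ia <- match(pairs$gene_a, rownames(map_a$counts))
  ib <- match(pairs$gene_b, rownames(map_b$counts))
  if (anyNA(ia)) {
    abort_lookup(paste0("gene ", pairs$gene_a[which(is.na(ia))[1]],
                        " absent from species ", map_a$species_id, " map"))
  }
  if (anyNA(ib)) {
    abort_lookup(paste0("gene ", pairs$gene_b[which(is.na(ib))[1]],
                        " absent from species ", map_b$species_id, " map"))
  }
  X <- cbind(map_a$counts[ia, , drop = FALSE],
             map_b$counts[ib, , drop = FALSE])
  dimnames(X) <- list(NULL, c(paste0("A:", colnames(map_a$counts)),
                              paste0("B:", colnames(map_b$counts))))
  X
}

`%||%` <- function(x, y) if (is.null(x)) y else x
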