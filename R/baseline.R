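#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed as in the DESeq median method:
#' each gene with a strictly positive geometric mean across samples
#' contributes the ratio of its count in a sample to that geometric mean,
#' and the sample's factor is the median of these ratios. Genes with any
#' zero count (zero geometric mean) are excluded from the median.
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @return A positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_geo <- rowMeans(log(counts))
  eligible <- is.finite(log_geo)
  if (!any(eligible)) {
    rlang::abort("no gene has non-zero counts in every sample",
                 class = "crossexpress_normalization_error")
  }
  apply(counts[eligible, , drop = FALSE], 2, function(col) {
    stats::median(col / exp(log_geo[eligible]))
  })
}

#' Normalize an expression map for distance calculation
#'
#' Counts are divided by their sample's size factor, incremented by 1,
#' then each gene row is divided by its median over the samples entering
#' the comparison. The increment makes the per-gene medians at least 1,
#' so the division is always defined.
#'
#' @param map An [expression_map()].
#' @param factors Per-sample size factors (default computed from the full
#'   map with [size_factors()]).
#' @param samples Sample IDs entering the comparison (default all); the
#'   per-gene median divisor is taken over these columns only.
#' @return The normalized gene x sample matrix restricted to `samples`.
#' @export
normalize_for_distance <- function(map, factors = size_factors(map$counts),
                                   samples = NULL) {
  counts <- map$counts
  if (is.null(samples)) samples <- colnames(counts)
  missing <- setdiff(samples, colnames(counts))
  if (length(missing)) {
    abort_lookup(paste0("samples absent from map: ",
                        paste(missing, collapse = ", ")))
  }
  stopifnot(all(factors > 0), length(factors) == ncol(counts))
  norm <- sweep(counts, 2, factors, "/") + 1
  norm <- norm[, samples, drop = FALSE]
  med <- apply(norm, 1, stats::median)
  norm / med
}

#' Construct a sample matching between two species' atlases
#'
#' Cross-species Euclidean-style distances need to know which samples to
#' compare. Samples with a clear counterpart are matched directly
#' (label-to-label); samples without a one-to-one counterpart (different
#' organs, stages or morphologies) are pooled into group matches, within
#' which the minimal residual is used.
#'
#' @param type Character vector, each `"direct"` or `"group"`.
#' @param a_labels,b_labels Lists (or comma-separated strings) of sample
#'   labels per match entry; a direct entry has exactly one label on each
#'   side.
#' @return A `sample_matching` tibble with list-columns `a_labels`,
#'   `b_labels`.
#' @export
sample_matching <- function(type, a_labels, b_labels) {
  as_list <- function(x) {
    if (is.character(x)) x <- strsplit(x, ",[ ]*")
    lapply(x, as.character)
  }
  out <- tibble::tibble(type = as.character(type),
                        a_labels = as_list(a_labels),
                        b_labels = as_list(b_labels))
  if (!all(out$type %in% c("direct", "group"))) {
    abort_config("matching type must be 'direct' or 'group'")
  }
  if (any(lengths(out$a_labels) == 0 | lengths(out$b_labels) == 0)) {
    abort_config("matching entries must have at least one label per side")
  }
  bad_direct <- out$type == "direct" &
    (lengths(out$a_labels) != 1 | lengths(out$b_labels) != 1)
  if (any(bad_direct)) {
    abort_config("direct matches must have exactly one label per side")
  }
  for (side in c("a_labels", "b_labels")) {
    labs <- unlist(out[[side]])
    if (anyDuplicated(labs)) {
      abort_config(paste0("sample label appears in more than one match: ",
                          labs[duplicated(labs)][1]))
    }
  }
  structure(out, class = c("sample_matching", class(tibble::tibble())))
}

#' Read a sample matching from TSV
#'
#' Columns: `type` (`direct`/`group`), `a_labels`, `b_labels`
#' (comma-separated sample labels).
#'
#' @param path Path to the TSV.
#' @return A [sample_matching()] tibble.
#' @export
read_sample_matching <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  if (!all(c("type", "a_labels", "b_labels") %in% names(df))) {
    abort_format("matching file needs columns type, a_labels, b_labels")
  }
  sample_matching(df$type, df$a_labels, df$b_labels)
}

#' Pseudo-Euclidean expression distance between gene pairs
#'
#' For each resampling repeat, one biological replicate is drawn at random
#' per sample label in each species. Directly matched samples contribute
#' the squared residual of the two genes' normalized values; a group match
#' contributes the square of the minimal absolute residual over all its
#' label pairs. The distance is the square root of the summed
#' contributions. Repeating over random replicate draws (default 100)
#' yields a distribution per pair, summarized by mean and standard
#' deviation.
#'
#' @param pairs A [pair_set()] (or tibble with `gene_a`, `gene_b`).
#' @param map_a,map_b [expression_map()] objects.
#' @param matching A [sample_matching()].
#' @param repeats Number of replicate-resampling repeats.
#' @param seed Integer seed.
#' @return The pairs tibble with `mean_distance` and `sd_distance`
#'   columns; the per-repeat distance matrix is kept in
#'   `attr(, "distances")`.
#' @export
pseudo_euclidean <- function(pairs, map_a, map_b, matching, repeats = 100,
                             seed = NULL) {
  pairs <- tibble::as_tibble(pairs)
  labels_a <- unlist(matching$a_labels)
  labels_b <- unlist(matching$b_labels)
  check_labels(map_a, labels_a, "A")
  check_labels(map_b, labels_b, "B")

  used_a <- map_a$samples$sample_id[map_a$samples$sample_label %in% labels_a]
  used_b <- map_b$samples$sample_id[map_b$samples$sample_label %in% labels_b]
  norm_a <- normalize_for_distance(map_a, samples = used_a)
  norm_b <- normalize_for_distance(map_b, samples = used_b)
  cols_a <- split(colnames(norm_a),
                  map_a$samples$sample_label[match(colnames(norm_a),
                                                   map_a$samples$sample_id)])
  cols_b <- split(colnames(norm_b),
                  map_b$samples$sample_label[match(colnames(norm_b),
                                                   map_b$samples$sample_id)])

  ga <- match(pairs$gene_a, rownames(norm_a))
  gb <- match(pairs$gene_b, rownames(norm_b))
  if (anyNA(ga) || anyNA(gb)) {
    abort_lookup("pair gene absent from its expression map")
  }

  n <- nrow(pairs)
  D <- matrix(NA_real_, n, repeats)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      pick <- function(cols) vapply(cols, function(cc) {
        cc[sample.int(length(cc), 1)]
      }, character(1))
      va <- norm_a[, pick(cols_a), drop = FALSE]
      colnames(va) <- names(cols_a)
      vb <- norm_b[, pick(cols_b), drop = FALSE]
      colnames(vb) <- names(cols_b)
      d2 <- numeric(n)
      for (m in seq_len(nrow(matching))) {
        la <- matching$a_labels[[m]]
        lb <- matching$b_labels[[m]]
        if (matching$type[m] == "direct") {
          d2 <- d2 + (va[cbind(ga, match(la, colnames(va)))] -
                        vb[cbind(gb, match(lb, colnames(vb)))])^2
        } else {
          best <- rep(Inf, n)
          for (xa in la) for (xb in lb) {
            best <- pmin(best, abs(va[cbind(ga, match(xa, colnames(va)))] -
                                     vb[cbind(gb, match(xb, colnames(vb)))]))
          }
          d2 <- d2 + best^2
        }
      }
      D[, r] <- sqrt(d2)
    }
  })
  out <- dplyr::mutate(pairs,
                       mean_distance = rowMeans(D),
                       sd_distance = apply(D, 1, stats::sd))
  attr(out, "distances") <- D
  out
}

check_labels <- function(map, labels, side) {
  missing <- setdiff(labels, map$samples$sample_label)
  if (length(missing)) {
    rlang::abort(paste0("matching labels absent from species-", side,
                        " map: ", paste(missing, collapse = ", ")),
                 class = "crossexpress_matching_error")
  }
}

#' Baseline classifier scores from pseudo-Euclidean distances
#'
#' The distance baseline scores a pair by its negated mean distance, so
#' that larger scores mean more similar expression profiles and the
#' scores are comparable to classifier output in ROC analyses.
#'
#' @param distances Output of [pseudo_euclidean()].
#' @return The input tibble with a `score` column (`-mean_distance`).
#' @export
baseline_scores <- function(distances) {
  dplyr::mutate(tibble::as_tibble(distances), score = -.data$mean_distance)
}
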