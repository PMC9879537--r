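#' Sample a negative training set of random interspecific pairs
#'
#' Draws `n` distinct gene pairs uniformly without replacement from the
#' cross product of the two species' gene lists, excluding the positive
#' (orthopair) set. The default `n` equals the positive-set size, giving
#' the balanced 1:1 class ratio the classifier is trained with.
#'
#' @param genes_a,genes_b Character vectors of candidate gene IDs.
#' @param positives A positive [pair_set()] to exclude.
#' @param n Number of pairs to draw (default `nrow(positives)`).
#' @param seed Integer seed; identical inputs and seed give identical sets.
#' @return A negative-labelled [pair_set()], disjoint from `positives`.
#' @export
sample_negative_pairs <- function(genes_a, genes_b, positives,
                                  n = nrow(positives), seed = NULL) {
  genes_a <- unique(as.character(genes_a))
  genes_b <- unique(as.character(genes_b))
  na <- length(genes_a); nb <- length(genes_b)
  ia <- match(positives$gene_a, genes_a)
  ib <- match(positives$gene_b, genes_b)
  inside <- !is.na(ia) & !is.na(ib)
  pos_idx <- (ia[inside] - 1) * nb + ib[inside]  # 1-based linear index
  pool <- na * nb - length(unique(pos_idx))
  if (n > pool) {
    rlang::abort(paste0("cannot draw ", n, " negative pairs: only ", pool,
                        " non-positive pairs available"),
                 class = "crossexpress_sampling_error")
  }
  idx <- with_seed(seed, draw_excluding(na * nb, pos_idx, n))
  gene_a <- genes_a[(idx - 1) %/% nb + 1]
  gene_b <- genes_b[(idx - 1) %% nb + 1]
  pair_set(gene_a, gene_b, label = "negative")
}

# uniform without-replacement draw from 1:total minus `excluded`
draw_excluding <- function(total, excluded, n) {
  if (total <= 2e7) {
    keep <- rep(TRUE, total)
    keep[excluded] <- FALSE
    cand <- which(keep)
    return(cand[sample.int(length(cand), n)])
  }
  # large cross products: rejection sampling; symmetric over the pool,
  # so the resulting n-subset is still uniform
  chosen <- integer(0)
  excl <- as.numeric(excluded)
  while (length(chosen) < n) {
    draw <- ceiling(stats::runif(2 * (n - length(chosen))) * total)
    draw <- draw[!(draw %in% excl)]
    chosen <- unique(c(chosen, draw))
  }
  chosen[seq_len(n)]
}

#' Stratified k-fold partition of the training pairs
#'
#' Splits the positive and negative training sets into `k` folds for the
#' out-of-fold re-classification procedure. Stratified by label: each fold
#' receives `floor(n/k)` or `ceiling(n/k)` pairs from each class, so every
#' training subset keeps the balanced class ratio.
#'
#' @param positives,negatives [pair_set()] objects.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the random assignment.
#' @return A tibble with columns `gene_a`, `gene_b`, `label`, `fold`
#'   (fold index in `1:k`).
#' @export
make_fold_partition <- function(positives, negatives, k = 10, seed = NULL) {
  if (k < 2) rlang::abort("k must be at least 2",
                          class = "crossexpress_partition_error")
  if (nrow(positives) < k || nrow(negatives) < k) {
    rlang::abort(paste0("each class needs at least k = ", k,
                        " pairs (have ", nrow(positives), " positive, ",
                        nrow(negatives), " negative)"),
                 class = "crossexpress_partition_error")
  }
  assign_folds <- function(n) sample(rep(seq_len(k), length.out = n))
  with_seed(seed, {
    dplyr::bind_rows(
      tibble::tibble(gene_a = positives$gene_a, gene_b = positives$gene_b,
                     label = "positive", fold = assign_folds(nrow(positives))),
      tibble::tibble(gene_a = negatives$gene_a, gene_b = negatives$gene_b,
                     label = "negative", fold = assign_folds(nrow(negatives)))
    )
  })
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}
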