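#' Booster parameters for the Expression Score classifier
#'
#' Defaults follow the published configuration of the gradient-boosted
#' pair classifier: no row or column subsampling, default regularization
#' (`alpha = 0`, `lambda = 1`, `gamma = 0`), balanced class weight
#' (`scale_pos_weight = 1`, the training sets are 1:1 by construction) and
#' depth-unlimited trees (`max_depth = 0`). The number of boosting rounds
#' is selected automatically by early stopping on a stratified holdout
#' slice of the training data.
#'
#' @param subsample Row subsample fraction per tree, in (0, 1].
#' @param colsample_bytree,colsample_bylevel Column subsample fractions.
#' @param alpha,lambda L1/L2 regularization (>= 0).
#' @param gamma Minimum split loss (>= 0).
#' @param max_depth Maximum tree depth; 0 means unlimited growth.
#' @param scale_pos_weight Positive-class weight.
#' @param eta Learning rate.
#' @param max_bin Histogram bins used to discretize count features.
#' @param max_rounds Cap on boosting rounds.
#' @param early_stopping_rounds Patience (rounds without validation-AUC
#'   improvement) before stopping.
#' @param validation_fraction Fraction of the training set held out
#'   (stratified) for early stopping.
#' @param nthread Threads for xgboost; 1 keeps runs deterministic.
#' @return A `booster_params` list.
#' @export
booster_params <- function(subsample = 1, colsample_bytree = 1,
                           colsample_bylevel = 1, alpha = 0, lambda = 1,
                           gamma = 0, max_depth = 0, scale_pos_weight = 1,
                           eta = 0.3, max_bin = 32, max_rounds = 500,
                           early_stopping_rounds = 25,
                           validation_fraction = 0.2, nthread = 1) {
  p <- list(subsample = subsample, colsample_bytree = colsample_bytree,
            colsample_bylevel = colsample_bylevel, alpha = alpha,
            lambda = lambda, gamma = gamma, max_depth = max_depth,
            scale_pos_weight = scale_pos_weight, eta = eta,
            max_bin = max_bin, max_rounds = max_rounds,
            early_stopping_rounds = early_stopping_rounds,
            validation_fraction = validation_fraction, nthread = nthread)
  frac <- c(p$subsample, p$colsample_bytree, p$colsample_bylevel)
  if (any(frac <= 0 | frac > 1)) {
    abort_config("subsample/colsample fractions must lie in (0, 1]")
  }
  if (any(c(p$alpha, p$lambda, p$gamma) < 0)) {
    abort_config("alpha, lambda and gamma must be non-negative")
  }
  if (p$validation_fraction <= 0 || p$validation_fraction >= 1) {
    abort_config("validation_fraction must lie in (0, 1)")
  }
  structure(p, class = "booster_params")
}

xgb_param_list <- function(params) {
  list(objective = "binary:logistic", eval_metric = "auc",
       eta = params$eta, max_depth = params$max_depth,
       subsample = params$subsample,
       colsample_bytree = params$colsample_bytree,
       colsample_bylevel = params$colsample_bylevel,
       alpha = params$alpha, lambda = params$lambda, gamma = params$gamma,
       scale_pos_weight = params$scale_pos_weight,
       tree_method = "hist", max_bin = params$max_bin,
       grow_policy = if (params$max_depth == 0) "lossguide" else "depthwise",
       nthread = params$nthread)
}

# fit a booster on a numeric feature matrix with early stopping on a
# stratified holdout; returns the xgb.Booster
fit_booster <- function(X, y, params, seed = NULL) {
  if (length(unique(y)) < 2) {
    rlang::abort("training labels contain a single class",
                 class = "crossexpress_training_error")
  }
  with_seed(seed, {
    holdout <- stratified_holdout(y, params$validation_fraction)
    dtrain <- xgboost::xgb.DMatrix(X[!holdout, , drop = FALSE],
                                   label = y[!holdout],
                                   nthread = params$nthread)
    dvalid <- xgboost::xgb.DMatrix(X[holdout, , drop = FALSE],
                                   label = y[holdout],
                                   nthread = params$nthread)
    xgboost::xgb.train(
      params = xgb_param_list(params), data = dtrain,
      nrounds = params$max_rounds, evals = list(valid = dvalid),
      early_stopping_rounds = params$early_stopping_rounds, verbose = 0)
  })
}

stratified_holdout <- function(y, fraction) {
  flag <- logical(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_out <- max(1L, round(fraction * length(idx)))
    flag[sample(idx, n_out)] <- TRUE
  }
  flag
}

booster_predict <- function(booster, X, nthread = 1) {
  # xgboost stores best_iteration 0-based; iterationrange is 1-based
  # inclusive, so the optimal model is rounds 1 .. best + 1
  best <- tryCatch(as.integer(xgboost::xgb.attr(booster, "best_iteration")),
                   error = function(e) NA_integer_)
  d <- xgboost::xgb.DMatrix(X, nthread = nthread)
  if (!is.na(best) && best >= 0) {
    stats::predict(booster, d, iterationrange = c(1, best + 1))
  } else {
    stats::predict(booster, d)
  }
}

#' Train the gene-pair classifier
#'
#' Fits a gradient-boosted decision-tree binary classifier on concatenated
#' raw read-count feature vectors. The boosting-round count is chosen by
#' early stopping on a stratified holdout slice.
#'
#' @param features Numeric feature matrix (rows = pairs), or a list of
#'   equal-length numeric vectors.
#' @param labels Binary vector (1/TRUE = positive class), one per row.
#' @param params A [booster_params()] list.
#' @param seed Integer seed (holdout split and any subsampling).
#' @return A `pair_classifier` object; `predict()` returns probabilities
#'   in \[0, 1\].
#' @export
train_pair_classifier <- function(features, labels,
                                  params = booster_params(), seed = NULL) {
  if (is.list(features) && !is.data.frame(features)) {
    if (length(features) == 0) {
      rlang::abort("no training examples supplied",
                   class = "crossexpress_training_error")
    }
    len <- lengths(features)
    if (length(unique(len)) != 1) {
      rlang::abort("feature vectors have inconsistent lengths",
                   class = "crossexpress_shape_error")
    }
    features <- do.call(rbind, features)
  }
  if (NROW(features) == 0) {
    rlang::abort("no training examples supplied",
                 class = "crossexpress_training_error")
  }
  y <- as.integer(as.logical(labels))
  if (length(y) != nrow(features)) {
    rlang::abort("labels length does not match feature rows",
                 class = "crossexpress_shape_error")
  }
  booster <- fit_booster(features, y, params, seed)
  structure(list(booster = booster, params = params, seed = seed,
                 n_train = nrow(features),
                 n_features = ncol(features)),
            class = "pair_classifier")
}

#' @export
predict.pair_classifier <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata)) {
    newdata <- do.call(rbind, newdata)
  }
  booster_predict(object$booster, newdata, object$params$nthread)
}

#' @export
print.pair_classifier <- function(x, ...) {
  cat("<pair_classifier> trained on", x$n_train, "pairs,",
      x$n_features, "features\n")
  invisible(x)
}

#' Score gene pairs with a trained classifier
#'
#' @param model A `pair_classifier`.
#' @param pairs A [pair_set()] (or tibble with `gene_a`, `gene_b`).
#' @param map_a,map_b [expression_map()] objects.
#' @return The input pairs as a tibble with a `score` column in \[0, 1\].
#' @export
score_pairs <- function(model, pairs, map_a, map_b) {
  out <- tibble::as_tibble(pairs)
  if (nrow(out) == 0) return(dplyr::mutate(out, score = numeric(0)))
  X <- feature_matrix(pairs, map_a, map_b)
  dplyr::mutate(out, score = predict(model, X))
}

# out-of-fold scores given a precomputed feature matrix; folds is an
# integer vector over rows
oof_scores_matrix <- function(X, y, folds, params, seed = NULL) {
  score <- rep(NA_real_, nrow(X))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    booster <- fit_booster(X[!hold, , drop = FALSE], y[!hold], params,
                           seed = if (is.null(seed)) NULL else seed + f)
    score[hold] <- booster_predict(booster, X[hold, , drop = FALSE],
                                   params$nthread)
  }
  score
}

#' Out-of-fold re-classification of the training pairs
#'
#' Scoring a training pair with a model that saw it would be biased, so
#' each fold of the positive/negative training sets is scored by the model
#' trained on the other folds: every training pair receives exactly one
#' score, from a model whose training data excluded it.
#'
#' @param positives,negatives [pair_set()] objects.
#' @param partition Fold assignment from [make_fold_partition()].
#' @param map_a,map_b [expression_map()] objects.
#' @param params A [booster_params()] list.
#' @param seed Integer seed.
#' @return `partition` with an out-of-fold `score` column.
#' @export
reclassify_training <- function(positives, negatives, partition,
                                map_a, map_b, params = booster_params(),
                                seed = NULL) {
  X <- feature_matrix(partition, map_a, map_b)
  y <- as.integer(partition$label == "positive")
  dplyr::mutate(tibble::as_tibble(partition),
                score = oof_scores_matrix(X, y, partition$fold, params, seed))
}

#' Compute Expression Scores for orthogroup gene pairs
#'
#' Runs the full iterated pipeline. Each iteration draws a fresh random
#' negative set and fold partition (seed = `base_seed + i`), scores the
#' training pairs out-of-fold, then trains a model on the complete
#' positive + negative sets and scores all remaining interspecific pairs
#' within the orthogroups. The final Expression Score (ES) of a pair is
#' the median of its per-iteration scores, which damps the influence of
#' coexpressed random pairs that occasionally enter a negative set.
#'
#' @param map_a,map_b [expression_map()] objects.
#' @param positives Positive [pair_set()] (orthopairs).
#' @param orthogroups Orthogroup tibble from [read_orthogroups()]; the
#'   pairs scored by the full model are its interspecific pairs minus the
#'   positives. May be `NULL` if `query_pairs` is given (or if only
#'   out-of-fold scores are wanted).
#' @param params A [booster_params()] list.
#' @param n_iterations Number of independent training/scoring iterations.
#' @param k Folds for the re-classification procedure.
#' @param base_seed Integer; iteration `i` uses seed `base_seed + i`.
#' @param query_pairs Optional explicit [pair_set()] to score with the
#'   full model instead of orthogroup pairs.
#' @param progress Print per-iteration progress.
#' @return An `es_table`: a tibble with columns `gene_a`, `gene_b`,
#'   `group_id` (for orthogroup pairs), `es`, `n_iterations`,
#'   `provenance` (`"out_of_fold"` for training positives, `"full_model"`
#'   otherwise). Per-iteration scores are kept in `attr(, "iterations")`
#'   and the per-iteration out-of-fold training scores (positives and
#'   negatives) in `attr(, "oof")`.
#' @export
compute_expression_scores <- function(map_a, map_b, positives,
                                      orthogroups = NULL,
                                      params = booster_params(),
                                      n_iterations = 100, k = 10,
                                      base_seed = 1, query_pairs = NULL,
                                      progress = FALSE) {
  if (nrow(positives) == 0) {
    rlang::abort("positive set is empty", class = "crossexpress_training_error")
  }
  if (is.null(query_pairs)) {
    query_pairs <- if (!is.null(orthogroups)) {
      all_pairs <- orthogroup_pairs(orthogroups)
      all_pairs[!(pair_key(all_pairs) %in% pair_key(positives)), ]
    } else {
      tibble::tibble(gene_a = character(), gene_b = character())
    }
  }
  query_pairs <- tibble::as_tibble(query_pairs)

  X_pos <- feature_matrix(positives, map_a, map_b)
  X_query <- if (nrow(query_pairs)) feature_matrix(query_pairs, map_a, map_b)
  genes_a <- rownames(map_a$counts)
  genes_b <- rownames(map_b$counts)

  n_pos <- nrow(positives); n_query <- nrow(query_pairs)
  pos_scores <- matrix(NA_real_, n_pos, n_iterations)
  query_scores <- matrix(NA_real_, n_query, n_iterations)
  oof_list <- vector("list", n_iterations)

  for (i in seq_len(n_iterations)) {
    seed_i <- base_seed + i
    it <- tryCatch({
      negatives <- sample_negative_pairs(genes_a, genes_b, positives,
                                         n = n_pos, seed = seed_i)
      partition <- make_fold_partition(positives, negatives, k = k,
                                       seed = seed_i)
      X_neg <- feature_matrix(negatives, map_a, map_b)
      # partition rows are positives then negatives, in input order
      X <- rbind(X_pos, X_neg)
      y <- as.integer(partition$label == "positive")
      oof <- oof_scores_matrix(X, y, partition$fold, params, seed = seed_i * 1000L)
      full <- if (n_query) fit_booster(X, y, params, seed = seed_i * 1000L)
      list(oof = dplyr::mutate(partition, score = oof, iteration = i),
           qs = if (n_query) booster_predict(full, X_query, params$nthread))
    }, error = function(e) {
      rlang::abort(paste0("iteration ", i, " failed: ", conditionMessage(e)),
                   parent = e)
    })
    pos_scores[, i] <- it$oof$score[it$oof$label == "positive"]
    if (n_query) query_scores[, i] <- it$qs
    oof_list[[i]] <- it$oof
    if (progress) message("iteration ", i, "/", n_iterations, " done")
  }

  out <- dplyr::bind_rows(
    tibble::tibble(gene_a = positives$gene_a, gene_b = positives$gene_b,
                   group_id = positives[["group_id"]] %||%
                     rep(NA_character_, n_pos),
                   es = row_medians(pos_scores),
                   provenance = "out_of_fold"),
    tibble::tibble(gene_a = query_pairs$gene_a, gene_b = query_pairs$gene_b,
                   group_id = query_pairs[["group_id"]] %||%
                     rep(NA_character_, n_query),
                   es = if (n_query) row_medians(query_scores) else numeric(0),
                   provenance = rep("full_model", n_query))
  )
  out$n_iterations <- n_iterations
  structure(out,
            iterations = rbind(pos_scores, query_scores),
            oof = dplyr::bind_rows(oof_list),
            params = params, base_seed = base_seed, k = k,
            class = c("es_table", class(tibble::tibble())))
}

row_medians <- function(m) apply(m, 1, stats::median)

#' Per-iteration out-of-fold AUC of an ES run
#'
#' @param es An `es_table` from [compute_expression_scores()].
#' @return A tibble with columns `iteration`, `auc`: the ROC AUC of the
#'   out-of-fold scores against the training labels, per iteration.
#' @export
es_iteration_auc <- function(es) {
  oof <- attr(es, "oof")
  if (is.null(oof)) rlang::abort("es_table carries no out-of-fold scores")
  oof |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(auc = roc_auc(.data$score,
                                   .data$label == "positive")$auc)
}

#' Aggregate out-of-fold AUC of an ES run
#'
#' The run-level classifier quality: the ROC AUC of final out-of-fold
#' Expression Scores against the training labels. With
#' `method = "final"` (the pipeline's aggregation) each training pair's
#' score is the median of its out-of-fold scores over the iterations in
#' which it served as a training pair - every iteration for the
#' positives, the iterations it was drawn in for the redrawn negatives.
#' `method = "pooled"` instead pools the raw per-iteration scores.
#'
#' @param es An `es_table`.
#' @param method `"final"` (median-aggregated ES, default) or
#'   `"pooled"`.
#' @return A single AUC value.
#' @export
es_oof_auc <- function(es, method = c("final", "pooled")) {
  method <- match.arg(method)
  oof <- attr(es, "oof")
  if (method == "pooled") {
    return(roc_auc(oof$score, oof$label == "positive")$auc)
  }
  final <- oof |>
    dplyr::group_by(.data$gene_a, .data$gene_b, .data$label) |>
    dplyr::summarise(es = stats::median(.data$score), .groups = "drop")
  roc_auc(final$es, final$label == "positive")$auc
}

#' Write an ES table to TSV
#' @param es An `es_table`.
#' @param path Output path.
#' @param iterations Also write the per-iteration wide table next to
#'   `path` (suffix `.iterations.tsv`).
#' @return `path`, invisibly.
#' @export
write_es_table <- function(es, path, iterations = FALSE) {
  readr::write_tsv(tibble::as_tibble(es), path, progress = FALSE)
  if (iterations) {
    m <- attr(es, "iterations")
    colnames(m) <- paste0("iter", seq_len(ncol(m)))
    wide <- dplyr::bind_cols(tibble::as_tibble(es)[, c("gene_a", "gene_b")],
                             tibble::as_tibble(m))
    readr::write_tsv(wide, sub("(\\.tsv)?$", ".iterations.tsv", path),
                     progress = FALSE)
  }
  invisible(path)
}

#' Per-iteration scores of an ES table in long form
#' @param x An `es_table`.
#' @param ... Ignored.
#' @return A tibble with one row per pair and iteration.
#' @exportS3Method generics::tidy
tidy.es_table <- function(x, ...) {
  m <- attr(x, "iterations")
  df <- tibble::as_tibble(x)[, c("gene_a", "gene_b", "provenance")]
  out <- tidyr::expand_grid(df, iteration = seq_len(ncol(m)))
  out$score <- as.vector(t(m))
  out
}

#' One-row summary of an ES run
#' @param x An `es_table`.
#' @param ... Ignored.
#' @return A one-row tibble with pair counts, iteration count and the
#'   pooled out-of-fold AUC.
#' @exportS3Method generics::glance
glance.es_table <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_training_positives = sum(x$provenance == "out_of_fold"),
    n_query = sum(x$provenance == "full_model"),
    n_iterations = x$n_iterations[1] %||% NA_integer_,
    k = attr(x, "k") %||% NA_integer_,
    oof_auc = if (!is.null(attr(x, "oof"))) es_oof_auc(x) else NA_real_
  )
}
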