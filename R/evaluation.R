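#' ROC curve and AUC
#'
#' AUC is computed as the Mann-Whitney statistic: the probability that a
#' random positive outscores a random negative, ties counted one half.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels Binary labels (1/TRUE = positive).
#' @return A list with `auc` and `curve`, a tibble of (`threshold`,
#'   `fpr`, `tpr`) points at every distinct score, descending.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  check_two_classes(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  curve <- tibble::tibble(
    threshold = s[keep],
    tpr = cumsum(l)[keep] / n1,
    fpr = cumsum(!l)[keep] / n0
  )
  curve <- dplyr::bind_rows(
    tibble::tibble(threshold = Inf, tpr = 0, fpr = 0), curve)
  list(auc = auc, curve = curve)
}

check_two_classes <- function(labels) {
  if (anyNA(labels) || length(unique(labels)) < 2) {
    rlang::abort("labels must contain both classes",
                 class = "crossexpress_evaluation_error")
  }
}

#' Precision-recall curve and average precision
#'
#' Precision and recall at every distinct score threshold (predicted
#' positive when score >= threshold), descending. Average precision is
#' the recall-weighted sum of precisions.
#'
#' @inheritParams roc_auc
#' @return A list with `average_precision` and `curve`, a tibble of
#'   (`threshold`, `recall`, `precision`).
#' @export
precision_recall <- function(scores, labels) {
  labels <- as.logical(labels)
  check_two_classes(labels)
  n1 <- sum(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(l)[keep]; fp <- cumsum(!l)[keep]
  curve <- tibble::tibble(
    threshold = s[keep],
    recall = tp / n1,
    precision = tp / (tp + fp)
  )
  ap <- sum(diff(c(0, curve$recall)) * curve$precision)
  list(average_precision = ap, curve = curve)
}

#' Sensitivity and specificity at a score threshold
#'
#' A pair is predicted positive when its score strictly exceeds the
#' threshold (a score exactly at the threshold is treated as negative).
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP).
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble: `sensitivity`, `specificity`, `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
sensitivity_specificity <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  check_two_classes(labels)
  pred <- scores > threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Expression breadth of a profile
#'
#' The fraction of samples in which a gene is appreciably expressed:
#' samples whose count reaches `min_fraction_of_max` times the profile
#' maximum. Genes expressed across many organs ("broad") are easier to
#' classify from expression than narrowly expressed ones.
#'
#' @param profile Non-negative count vector.
#' @param min_fraction_of_max Fraction of the maximum defining
#'   "expressed" (default 0.1).
#' @return Breadth in \[0, 1\]; `NA` (with a warning) for an all-zero
#'   profile, which is unclassifiable.
#' @export
expression_breadth <- function(profile, min_fraction_of_max = 0.1) {
  stopifnot(all(profile >= 0))
  if (all(profile == 0)) {
    rlang::warn("all-zero profile: breadth undefined")
    return(NA_real_)
  }
  mean(profile >= min_fraction_of_max * max(profile))
}

#' Expression breadth for every gene of a map
#'
#' @param map An [expression_map()].
#' @param min_fraction_of_max See [expression_breadth()].
#' @param cutoff Breadth cutoff separating `"narrow"` from `"broad"`
#'   genes; default the median breadth.
#' @return A tibble with columns `gene_id`, `breadth`, `pattern`.
#' @export
map_breadth <- function(map, min_fraction_of_max = 0.1, cutoff = NULL) {
  mx <- apply(map$counts, 1, max)
  breadth <- unname(rowMeans(
    map$counts >= pmax(min_fraction_of_max * mx, 1e-300)))
  breadth[mx == 0] <- NA_real_
  if (is.null(cutoff)) cutoff <- stats::median(breadth, na.rm = TRUE)
  tibble::tibble(
    gene_id = rownames(map$counts),
    breadth = breadth,
    pattern = dplyr::case_when(
      is.na(breadth) ~ NA_character_,
      breadth > cutoff ~ "broad",
      TRUE ~ "narrow"
    )
  )
}

#' Downsample an expression map by sample clustering
#'
#' Samples are clustered hierarchically (average linkage) on the distance
#' 1 - Pearson correlation of their count profiles; the tree is cut at
#' `cut_height` and one uniformly random sample is retained per cluster.
#' Raising the cut height merges more samples and so removes more of the
#' atlas; re-running the ES pipeline on the reduced map probes the
#' method's stability to sampling.
#'
#' @param map An [expression_map()].
#' @param cut_height Tree cut height in (0, 2).
#' @param seed Integer seed for the per-cluster random pick.
#' @return A reduced [expression_map()] (gene order preserved).
#' @export
downsample_by_clustering <- function(map, cut_height, seed = NULL) {
  stopifnot(cut_height > 0, cut_height < 2)
  if (ncol(map$counts) < 2) {
    rlang::abort("need at least 2 samples to downsample")
  }
  suppressWarnings(cc <- stats::cor(map$counts))
  if (anyNA(cc)) {
    rlang::warn("constant sample column(s): correlation distance set to 1")
    cc[is.na(cc)] <- 0
  }
  d <- stats::as.dist(1 - cc)
  tree <- stats::hclust(d, method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  keep <- with_seed(seed, {
    vapply(split(seq_along(cl), cl), function(idx) {
      idx[sample.int(length(idx), 1)]
    }, integer(1))
  })
  keep <- sort(unname(keep))
  expression_map(map$counts[, keep, drop = FALSE], map$species_id,
                 sample_info = map$samples[keep, ])
}

#' Global protein alignment identity (Needleman-Wunsch)
#'
#' Optimal global pairwise alignment under BLOSUM62 with affine gap
#' penalties, scored with `gap_open` for the first residue of a gap and
#' `gap_extend` for each further residue. Identity is the number of
#' identical aligned positions divided by the alignment length (gapped
#' columns count in the denominator).
#'
#' @param seq_a,seq_b Protein sequences (character strings).
#' @param matrix Substitution matrix name (`"BLOSUM62"`) or a numeric
#'   matrix.
#' @param gap_open Score for opening a gap (default -11).
#' @param gap_extend Score for each gap extension (default -1).
#' @return A one-row tibble: `aligned_length`, `identical`, `identity`,
#'   `score`.
#' @export
nw_identity <- function(seq_a, seq_b, matrix = "BLOSUM62",
                        gap_open = -11, gap_extend = -1) {
  sub_mat <- if (is.character(matrix)) {
    get(utils::data(list = matrix, package = "Biostrings",
                    envir = environment()))
  } else matrix
  for (s in c(seq_a, seq_b)) {
    if (!nzchar(s)) {
      rlang::abort("empty sequence", class = "crossexpress_input_error")
    }
    residues <- strsplit(s, "")[[1]]
    bad <- setdiff(residues, rownames(sub_mat))
    if (length(bad)) {
      rlang::abort(paste0("invalid residue(s): ",
                          paste(unique(bad), collapse = ", ")),
                   class = "crossexpress_input_error")
    }
  }
  # our convention: a gap of length L scores gap_open + (L-1)*gap_extend;
  # Biostrings charges gapOpening + L*gapExtension
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = sub_mat,
    gapOpening = -(gap_open - gap_extend), gapExtension = -gap_extend,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ident <- sum(pa == pb)
  tibble::tibble(
    aligned_length = length(pa),
    identical = ident,
    identity = ident / length(pa),
    score = Biostrings::score(aln)
  )
}

#' Alignment identities for gene pairs from two protein FASTA files
#'
#' @param pairs A [pair_set()] (or tibble with `gene_a`, `gene_b`).
#' @param fasta_a,fasta_b Paths to the two species' protein FASTA files.
#' @inheritParams nw_identity
#' @return The pairs tibble with `identity`, `aligned_length` and `score`
#'   columns.
#' @export
pair_identities <- function(pairs, fasta_a, fasta_b, matrix = "BLOSUM62",
                            gap_open = -11, gap_extend = -1) {
  aa_a <- Biostrings::readAAStringSet(fasta_a)
  aa_b <- Biostrings::readAAStringSet(fasta_b)
  names(aa_a) <- sub("\\s.*$", "", names(aa_a))
  names(aa_b) <- sub("\\s.*$", "", names(aa_b))
  pairs <- tibble::as_tibble(pairs)
  missing_a <- setdiff(pairs$gene_a, names(aa_a))
  missing_b <- setdiff(pairs$gene_b, names(aa_b))
  if (length(missing_a) || length(missing_b)) {
    abort_lookup(paste0("sequences missing from FASTA: ",
                        paste(c(missing_a, missing_b), collapse = ", ")))
  }
  res <- purrr::map2(pairs$gene_a, pairs$gene_b, function(a, b) {
    nw_identity(as.character(aa_a[[a]]), as.character(aa_b[[b]]),
                matrix = matrix, gap_open = gap_open,
                gap_extend = gap_extend)
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(res))
}
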