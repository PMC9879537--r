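test_that("booster parameter validation enforces ranges", {
  expect_error(booster_params(subsample = 0), class = "crossexpress_config_error")
  expect_error(booster_params(colsample_bytree = 1.2),
               class = "crossexpress_config_error")
  expect_error(booster_params(alpha = -1), class = "crossexpress_config_error")
  expect_error(booster_params(validation_fraction = 1),
               class = "crossexpress_config_error")
  p <- booster_params()
  expect_equal(p$subsample, 1)
  expect_equal(p$lambda, 1)
  expect_equal(p$scale_pos_weight, 1)
  expect_equal(p$max_depth, 0)
})

test_that("a linearly separable toy set is ranked perfectly in training", {
  set.seed(2)
  n <- 50
  shared <- matrix(rpois(n * 5, 50), n, 5)
  pos <- cbind(shared, shared + matrix(rpois(n * 5, 2), n, 5))
  neg <- cbind(matrix(rpois(n * 5, 50), n, 5),
               matrix(rpois(n * 5, 500), n, 5))
  X <- rbind(pos, neg)
  y <- rep(c(1, 0), each = n)
  model <- train_pair_classifier(X, y, seed = 1)
  scores <- predict(model, X)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_equal(roc_auc(scores, y)$auc, 1.0)
})

test_that("degenerate training inputs raise typed errors", {
  expect_error(train_pair_classifier(list(), c()),
               class = "crossexpress_training_error")
  expect_error(train_pair_classifier(list(c(1, 2), c(1, 2, 3)), c(1, 0)),
               class = "crossexpress_shape_error")
  X <- matrix(rpois(40, 10), 10, 4)
  expect_error(train_pair_classifier(X, rep(1, 10)),
               class = "crossexpress_training_error")
})

test_that("scoring is empty-safe and deterministic once trained", {
  sim <- small_sim()
  neg <- sample_negative_pairs(rownames(sim$map_a$counts),
                               rownames(sim$map_b$counts),
                               sim$orthopairs, seed = 1)
  X <- rbind(feature_matrix(sim$orthopairs, sim$map_a, sim$map_b),
             feature_matrix(neg, sim$map_a, sim$map_b))
  y <- rep(c(1, 0), c(nrow(sim$orthopairs), nrow(neg)))
  model <- train_pair_classifier(X, y, seed = 3)

  empty <- score_pairs(model, pair_set(), sim$map_a, sim$map_b)
  expect_equal(nrow(empty), 0L)
  expect_true("score" %in% names(empty))

  s1 <- score_pairs(model, sim$orthopairs[1:10, ], sim$map_a, sim$map_b)
  s2 <- score_pairs(model, sim$orthopairs[1:10, ], sim$map_a, sim$map_b)
  expect_identical(s1$score, s2$score)
  expect_true(all(s1$score >= 0 & s1$score <= 1))
})

test_that("re-classification scores every training pair without leakage", {
  sim <- small_sim()
  pos <- sim$orthopairs
  neg <- sample_negative_pairs(rownames(sim$map_a$counts),
                               rownames(sim$map_b$counts), pos, seed = 2)
  part <- make_fold_partition(pos, neg, k = 4, seed = 2)
  oof <- reclassify_training(pos, neg, part, sim$map_a, sim$map_b, seed = 2)
  expect_equal(nrow(oof), nrow(pos) + nrow(neg))
  expect_false(anyNA(oof$score))
  expect_true(all(oof$score >= 0 & oof$score <= 1))
  # audit: the scored set of each fold is disjoint from its training set
  for (f in unique(part$fold)) {
    train_keys <- paste(part$gene_a, part$gene_b)[part$fold != f]
    scored_keys <- paste(oof$gene_a, oof$gene_b)[oof$fold == f]
    expect_length(intersect(train_keys, scored_keys), 0)
  }
})

test_that("a planted diverged orthopair scores below 0.5 out of fold", {
  sim <- small_sim(seed = 9)
  # positive-labelled pair built from two unrelated background genes:
  # structurally an "orthopair", expression profiles independent
  meta <- sim$gene_meta
  in_groups <- unlist(c(sim$orthogroups$genes_a, sim$orthogroups$genes_b))
  bg_a <- meta$gene[meta$species == "A" & !(meta$gene %in% in_groups)]
  bg_b <- meta$gene[meta$species == "B" & !(meta$gene %in% in_groups)]
  arch <- setNames(meta$archetype, meta$gene)
  pick_b <- bg_b[arch[bg_b] != arch[bg_a[1]]][1]
  pos <- pair_set(c(sim$orthopairs$gene_a, bg_a[1]),
                  c(sim$orthopairs$gene_b, pick_b), label = "positive")
  es <- compute_expression_scores(sim$map_a, sim$map_b, pos,
                                  orthogroups = NULL, n_iterations = 3,
                                  k = 5, base_seed = 17)
  planted <- tibble::as_tibble(es)
  planted <- planted[planted$gene_a == bg_a[1] & planted$gene_b == pick_b, ]
  expect_equal(planted$provenance, "out_of_fold")
  expect_lt(planted$es, 0.5)
})

test_that("final ES is the median of per-iteration scores (sort-and-middle oracle)", {
  sim <- small_sim(seed = 5, n = 150, labels_a = 8, labels_b = 6)
  es <- compute_expression_scores(sim$map_a, sim$map_b, sim$orthopairs,
                                  sim$orthogroups, n_iterations = 3,
                                  k = 5, base_seed = 4)
  m <- attr(es, "iterations")
  expect_equal(ncol(m), 3L)
  mid <- apply(m, 1, function(v) sort(v)[(length(v) + 1) / 2])
  expect_equal(es$es, unname(mid))
  expect_true(all(es$es >= apply(m, 1, min) & es$es <= apply(m, 1, max)))
  # provenance: training positives out-of-fold, orthogroup pairs full-model
  pos_keys <- paste(sim$orthopairs$gene_a, sim$orthopairs$gene_b)
  expect_true(all(es$provenance[paste(es$gene_a, es$gene_b) %in% pos_keys]
                  == "out_of_fold"))
  expect_true(all(es$provenance[!(paste(es$gene_a, es$gene_b) %in% pos_keys)]
                  == "full_model"))
})

test_that("single-iteration runs return that iteration's scores exactly", {
  sim <- small_sim(seed = 6, n = 150, labels_a = 8, labels_b = 6)
  es <- compute_expression_scores(sim$map_a, sim$map_b, sim$orthopairs,
                                  orthogroups = NULL, n_iterations = 1,
                                  k = 5, base_seed = 2)
  m <- attr(es, "iterations")
  expect_equal(es$es, unname(m[, 1]))
  expect_equal(unique(es$n_iterations), 1)
})

test_that("the even-count median is the mean of the central values", {
  # direct check of the aggregation rule used for stored iteration scores
  expect_equal(crossexpress:::row_medians(matrix(c(0.1, 0.9, 0.9, 0.2), 1)),
               0.55)
  expect_equal(crossexpress:::row_medians(matrix(c(0.1, 0.9, 0.9), 1)), 0.9)
})

test_that("full runs are reproducible under a fixed base seed", {
  sim <- small_sim(seed = 8, n = 150, labels_a = 8, labels_b = 6)
  run <- function() {
    compute_expression_scores(sim$map_a, sim$map_b, sim$orthopairs,
                              sim$orthogroups, n_iterations = 2,
                              k = 5, base_seed = 31)
  }
  es1 <- run(); es2 <- run()
  expect_identical(tibble::as_tibble(es1), tibble::as_tibble(es2))
  expect_identical(attr(es1, "iterations"), attr(es2, "iterations"))
})

test_that("tidy and glance summarize an ES run", {
  sim <- small_sim(seed = 10, n = 150, labels_a = 8, labels_b = 6)
  es <- compute_expression_scores(sim$map_a, sim$map_b, sim$orthopairs,
                                  orthogroups = NULL, n_iterations = 2,
                                  k = 5, base_seed = 1)
  td <- tidy(es)
  expect_equal(nrow(td), nrow(es) * 2)
  expect_true(all(c("gene_a", "gene_b", "iteration", "score") %in% names(td)))
  gl <- glance(es)
  expect_equal(gl$n_pairs, nrow(es))
  expect_true(gl$oof_auc > 0 && gl$oof_auc < 1)
})
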