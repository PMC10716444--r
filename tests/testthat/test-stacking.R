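test_that("base specifications carry the tuned hyperparameters verbatim", {
  specs <- default_base_specs()
  expect_named(specs, c("LR", "SVM", "KNN", "RF", "MLP"))
  expect_equal(specs$SVM$params[c("C", "kernel", "degree", "tol")],
               list(C = 1.6134, kernel = "rbf", degree = 0.2651,
                    tol = 0.078))
  expect_equal(specs$LR$params[c("random_state", "max_iter")],
               list(random_state = 30, max_iter = 1100))
  expect_equal(specs$KNN$params, list(n_neighbors = 20, leaf_size = 17))
  expect_equal(specs$RF$params[c("max_depth", "min_samples_split",
                                 "min_samples_leaf", "random_state")],
               list(max_depth = 10, min_samples_split = 10,
                    min_samples_leaf = 1, random_state = 30))
  expect_equal(specs$MLP$params[c("activation", "alpha", "batch_size",
                                  "hidden_layer_sizes", "learning_rate_init",
                                  "max_iter", "momentum", "beta_1", "beta_2",
                                  "epsilon")],
               list(activation = "relu", alpha = 1e-05, batch_size = 37,
                    hidden_layer_sizes = 11, learning_rate_init = 0.021,
                    max_iter = 8532, momentum = 0.58, beta_1 = 0.9,
                    beta_2 = 0.999, epsilon = 1e-08))
  expect_equal(base_spec("KNN", n_neighbors = 5)$params$n_neighbors, 5)
})

test_that("out-of-fold meta-features are built without leakage", {
  d <- gaussian_features(n_pos = 24, n_neg = 24, p = 4, shift = 1.5, seed = 1)
  specs <- lapply(c("LR", "RF"), base_spec)
  model <- fit_stacking(d$features, d$labels, specs = specs,
                        oof_folds = 3L, seed = 11)
  expect_equal(ncol(model$oof_meta), 2L)
  expect_false(anyNA(model$oof_meta))

  # recompute each fold's meta block with base models trained only on the
  # complementary folds (same seeds); equality proves the OOF protocol
  for (f in 1:3) {
    hold <- which(model$fold == f)
    rest <- which(model$fold != f)
    for (s in seq_along(specs)) {
      bf <- stackac4c:::fit_base_classifier(
        specs[[s]], d$features[rest, , drop = FALSE], d$labels[rest],
        seed = 11 * 1000L + f * 10L + s)
      expect_equal(unname(model$oof_meta[hold, s]),
                   unname(stackac4c:::predict_base(
                     bf, d$features[hold, , drop = FALSE])),
                   tolerance = 1e-12)
    }
  }
})

test_that("meta input dimension equals the number of base specs", {
  d <- gaussian_features(n_pos = 20, n_neg = 20, p = 3, shift = 2, seed = 2)
  for (kinds in list("RF", c("LR", "KNN"), c("LR", "KNN", "RF"))) {
    model <- fit_stacking(d$features, d$labels, specs = kinds,
                          oof_folds = 2L, seed = 3)
    expect_equal(ncol(model$oof_meta), length(kinds))
    expect_length(model$base_fits, length(kinds))
  }
})

test_that("all five base classifiers stack and separate strong synthetic signal", {
  ds <- simulate_dataset(sim_config(n_pos = 60, n_neg = 60, length = 101,
                                    c_enrichment = 0.5, seed = 5))
  enc <- encode_sequences(ds, encoder_config(lambda = 10L))
  model <- fit_stacking(enc$features, enc$labels, oof_folds = 3L, seed = 4)
  expect_equal(ncol(model$oof_meta), 5L)
  p <- predict_proba(model, enc$features)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(compute_metrics(enc$labels, p)$roc_auc, 0.95)
})

test_that("stacking predictions are deterministic and duplicate rows score identically", {
  d <- gaussian_features(n_pos = 25, n_neg = 25, p = 4, shift = 1, seed = 6)
  m1 <- fit_stacking(d$features, d$labels, specs = c("LR", "RF", "KNN"),
                     oof_folds = 3L, seed = 21)
  m2 <- fit_stacking(d$features, d$labels, specs = c("LR", "RF", "KNN"),
                     oof_folds = 3L, seed = 21)
  x <- d$features[c(1, 5, 1), ]
  expect_identical(predict_proba(m1, x), predict_proba(m2, x))
  p <- predict_proba(m1, x)
  expect_identical(p[1], p[3])
})

test_that("single-base stacking tracks the base classifier's ranking", {
  d <- gaussian_features(n_pos = 60, n_neg = 60, p = 5, shift = 1, seed = 7)
  model <- fit_stacking(d$features, d$labels, specs = "RF",
                        oof_folds = 3L, seed = 9)
  test <- gaussian_features(n_pos = 40, n_neg = 40, p = 5, shift = 1,
                            seed = 8)
  stack_scores <- predict_proba(model, test$features)
  base_scores <- stackac4c:::predict_base(model$base_fits$RF, test$features)
  expect_gt(cor(stack_scores, base_scores, method = "spearman"), 0.99)
})

test_that("schema mismatches are rejected with the offending names", {
  d <- gaussian_features(n_pos = 15, n_neg = 15, p = 3, shift = 2, seed = 3)
  model <- fit_stacking(d$features, d$labels, specs = "LR", oof_folds = 2L,
                        seed = 1)
  bad <- d$features
  colnames(bad) <- c("f1", "f2", "other")
  err <- tryCatch(predict_proba(model, bad), error = conditionMessage)
  expect_match(err, "f3")
  expect_match(err, "other")
  # column order must not matter once the schema matches
  reordered <- d$features[, c(3, 1, 2)]
  expect_equal(predict_proba(model, reordered),
               predict_proba(model, d$features))
})

test_that("degenerate stacking inputs error early", {
  d <- gaussian_features(n_pos = 10, n_neg = 10, p = 3, shift = 1, seed = 4)
  expect_error(fit_stacking(d$features, rep(1L, 20), specs = "LR"),
               "single class")
  expect_error(fit_stacking(d$features, d$labels, specs = "LR",
                            oof_folds = 11L), "fewer samples")
})

test_that("the six evaluated base-classifier combinations are enumerated", {
  combos <- enumerate_combinations()
  expect_length(combos, 6L)
  sizes <- vapply(combos, function(cb) length(cb$kinds), integer(1))
  expect_equal(sizes, c(rep(4L, 5), 5L))
  omitted <- vapply(combos[1:5], function(cb)
    setdiff(c("LR", "SVM", "KNN", "RF", "MLP"), cb$kinds), character(1))
  expect_setequal(omitted, c("LR", "SVM", "KNN", "RF", "MLP"))
  expect_identical(combos[[6]]$label, "All")
})

test_that("repeated training cycles average to the column means of per-cycle metrics", {
  train <- gaussian_features(n_pos = 20, n_neg = 20, p = 4, shift = 1.5,
                             seed = 12)
  test <- gaussian_features(n_pos = 16, n_neg = 16, p = 4, shift = 1.5,
                            seed = 13)
  one <- repeated_fit_average(train$features, train$labels,
                              test$features, test$labels,
                              specs = c("LR", "KNN"), cycles = 1L, seed = 2,
                              oof_folds = 2L, cv_folds = 2L)
  expect_equal(unname(one$avg), unname(unlist(one$per_cycle[1, -1])),
               tolerance = 1e-12)

  two <- repeated_fit_average(train$features, train$labels,
                              test$features, test$labels,
                              specs = c("LR", "KNN"), cycles = 2L, seed = 2,
                              oof_folds = 2L, cv_folds = 2L)
  expect_equal(unname(two$avg),
               unname(colMeans(two$per_cycle[, -1])), tolerance = 1e-12)
  expect_true(all(is.finite(two$sd)))
})
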