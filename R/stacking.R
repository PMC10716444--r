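BASE_KINDS <- c("LR", "SVM", "KNN", "RF", "MLP")

#' Base classifier specification
#'
#' The five base learners and their fixed tuned hyperparameters. Values are
#' stored verbatim in the spec; fitting translates them onto the backing R
#' implementations (glmnet ridge logistic, e1071 RBF-SVM with Platt
#' probabilities, class::knn, ranger probability forest, nnet single-hidden-
#' layer perceptron). Fields with no counterpart in the backing optimizer
#' (the SVM's `degree`, inert under an RBF kernel; the MLP's Adam-specific
#' `batch_size`/`momentum`/`beta_1`/`beta_2`/`epsilon`/`learning_rate_init`
#' under nnet's BFGS) are recorded but have no effect.
#'
#' @param kind One of `"LR"`, `"SVM"`, `"KNN"`, `"RF"`, `"MLP"`.
#' @param ... Hyperparameter overrides merged over the tuned defaults.
#' @return A `base_spec` list with `kind` and `params`.
#' @export
base_spec <- function(kind, ...) {
  kind <- match.arg(kind, BASE_KINDS)
  defaults <- switch(kind,
    LR = list(random_state = 30, max_iter = 1100, C = 1.0),
    SVM = list(C = 1.6134, kernel = "rbf", degree = 0.2651, tol = 0.078),
    KNN = list(n_neighbors = 20, leaf_size = 17),
    RF = list(max_depth = 10, min_samples_split = 10, min_samples_leaf = 1,
              random_state = 30, n_estimators = 100),
    MLP = list(activation = "relu", alpha = 1e-05, batch_size = 37,
               beta_1 = 0.9, beta_2 = 0.999, epsilon = 1e-08,
               hidden_layer_sizes = 11, learning_rate_init = 0.021,
               max_iter = 8532, momentum = 0.58))
  overrides <- list(...)
  params <- utils::modifyList(defaults, overrides)
  structure(list(kind = kind, params = params), class = "base_spec")
}

#' The five tuned base classifier specifications
#' @return Named list of `base_spec` objects (LR, SVM, KNN, RF, MLP).
#' @export
default_base_specs <- function() {
  specs <- lapply(BASE_KINDS, base_spec)
  names(specs) <- BASE_KINDS
  specs
}

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  expr
}

# L2 (ridge) logistic regression at inverse regularization strength C,
# parameterized like the tuned models. glmnet converges reliably only along
# a decreasing lambda path, so fit a short path ending at the target
# penalty 1/(n*C) and predict at that value.
ridge_logistic <- function(x, y, C = 1.0) {
  s <- 1 / (nrow(x) * C)
  # glmnet warns on classes below 8 observations; routine for small CV
  # folds of the meta matrix, so not surfaced to callers
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                   lambda = s * c(1000, 100, 10, 5, 2, 1)),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, s = s), class = "ridge_logistic")
}

predict_ridge <- function(rl, x) {
  as.numeric(stats::predict(rl$fit, x, type = "response", s = rl$s))
}

fit_base_classifier <- function(spec, features, labels, seed) {
  stopifnot(inherits(spec, "base_spec"))
  labels <- as.integer(labels)
  p <- spec$params
  yf <- factor(labels, levels = c(0L, 1L))
  fit <- switch(spec$kind,
    LR = ridge_logistic(features, yf, C = p$C),
    SVM = {
      scale_cols <- apply(features, 2L, stats::var) > 0
      with_seed(seed,
        e1071::svm(x = features, y = yf, type = "C-classification",
                   kernel = "radial", cost = p$C, tolerance = p$tol,
                   probability = TRUE, scale = scale_cols))
    },
    KNN = list(train = features, cl = yf,
               k = min(p$n_neighbors, nrow(features))),
    RF = ranger::ranger(x = features, y = yf, probability = TRUE,
                        num.trees = p$n_estimators, max.depth = p$max_depth,
                        min.node.size = p$min_samples_split,
                        min.bucket = p$min_samples_leaf,
                        seed = seed, num.threads = 1L),
    MLP = with_seed(seed,
      nnet::nnet(x = features, y = labels, size = p$hidden_layer_sizes,
                 decay = p$alpha, maxit = min(p$max_iter, 200L),
                 entropy = TRUE, trace = FALSE, MaxNWts = 100000L,
                 reltol = 1e-6))
  )
  structure(list(kind = spec$kind, fit = fit, seed = seed),
            class = "base_fit")
}

predict_base <- function(bf, features) {
  out <- switch(bf$kind,
    LR = predict_ridge(bf$fit, features),
    SVM = {
      pr <- stats::predict(bf$fit, features, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    KNN = with_seed(bf$seed, {
      pred <- class::knn(bf$fit$train, features, bf$fit$cl, k = bf$fit$k,
                         prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    }),
    RF = stats::predict(bf$fit, data = features,
                        num.threads = 1L)$predictions[, "1"],
    MLP = as.numeric(stats::predict(bf$fit, features))
  )
  pmin(pmax(as.numeric(out), 0), 1)
}

resolve_specs <- function(specs) {
  if (is.null(specs)) return(default_base_specs())
  if (inherits(specs, "base_spec")) specs <- list(specs)
  specs <- lapply(specs, function(s) {
    if (inherits(s, "base_spec")) s
    else if (is.character(s)) base_spec(s)
    else stop("specs must be base_spec objects or kind names")
  })
  names(specs) <- vapply(specs, `[[`, character(1), "kind")
  if (anyDuplicated(names(specs))) stop("duplicate base classifier kinds")
  specs
}

# glmnet needs >= 2 predictor columns; stacking a single base classifier
# gives a 1-column meta matrix, so pad with an all-zero column whose
# coefficient is necessarily 0.
pad_meta <- function(m) {
  if (ncol(m) >= 2L) return(m)
  cbind(m, .pad = 0)
}

#' Fit the two-layer stacking ensemble
#'
#' Layer 1 holds the base classifiers; layer 2 is an L2-regularized logistic
#' meta-learner. Meta-features are built out-of-fold to prevent leakage: the
#' training rows are split into `oof_folds` stratified folds, and each row's
#' meta-feature — one positive-class probability per base classifier — comes
#' from base models trained only on the complementary folds. The
#' meta-learner is then fit on the full out-of-fold matrix, and the base
#' classifiers are refit on all training rows for deployment.
#'
#' @param features Numeric training matrix with column names.
#' @param labels Binary 0/1 vector, both classes present.
#' @param specs Base classifiers: `base_spec` list or kind names; default
#'   all five.
#' @param oof_folds Folds used for meta-feature generation (default 5).
#' @param seed Integer seed driving fold assignment and every base fit.
#' @param meta_c Inverse regularization strength of the meta-learner's L2
#'   penalty (default 1; translated to a ridge penalty `1/(n * meta_c)`).
#' @return A `stacking_model`.
#' @export
fit_stacking <- function(features, labels, specs = NULL, oof_folds = 5L,
                         seed = 1L, meta_c = 1.0) {
  specs <- resolve_specs(specs)
  labels <- as.integer(labels)
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (is.null(colnames(features))) stop("feature matrix must have column names")
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  if (min(table(labels)) < oof_folds)
    stop("fewer samples in a class than out-of-fold folds")

  fold <- stratified_folds(labels, oof_folds, seed)
  meta_X <- matrix(NA_real_, nrow(features), length(specs),
                   dimnames = list(NULL, names(specs)))
  for (f in seq_len(oof_folds)) {
    hold <- which(fold == f)
    rest <- which(fold != f)
    for (s in seq_along(specs)) {
      bf <- fit_base_classifier(specs[[s]],
                                features[rest, , drop = FALSE], labels[rest],
                                seed = seed * 1000L + f * 10L + s)
      meta_X[hold, s] <- predict_base(bf, features[hold, , drop = FALSE])
    }
  }
  stopifnot(!anyNA(meta_X))
  yf <- factor(labels, levels = c(0L, 1L))
  meta_fit <- ridge_logistic(pad_meta(meta_X), yf, C = meta_c)
  base_fits <- lapply(seq_along(specs), function(s)
    fit_base_classifier(specs[[s]], features, labels,
                        seed = seed * 1000L + s))
  names(base_fits) <- names(specs)

  model <- structure(list(specs = specs, base_fits = base_fits,
                          meta_fit = meta_fit, meta_c = meta_c,
                          oof_folds = as.integer(oof_folds),
                          fold = fold, oof_meta = meta_X,
                          schema = colnames(features),
                          seed = as.integer(seed)),
                     class = "stacking_model")
  attr(model, "train_fingerprint") <- row_fingerprints(features)
  model
}

#' Positive-class probabilities from a model
#' @param model A fitted model.
#' @param features Feature matrix whose columns match the training schema.
#' @param ... Passed to methods.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, features, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.stacking_model <- function(model, features, ...) {
  stopifnot(is.matrix(features))
  if (is.null(colnames(features))) stop("feature matrix must have column names")
  missing <- setdiff(model$schema, colnames(features))
  extra <- setdiff(colnames(features), model$schema)
  if (length(missing) || length(extra))
    stop("feature schema mismatch; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  features <- features[, model$schema, drop = FALSE]
  meta_X <- vapply(model$base_fits, predict_base, numeric(nrow(features)),
                   features = features)
  if (nrow(features) == 1L) meta_X <- matrix(meta_X, nrow = 1L,
                                             dimnames = list(NULL, names(model$base_fits)))
  predict_ridge(model$meta_fit, pad_meta(meta_X))
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(sprintf("stacking_model: %s -> L2 logistic meta-learner (oof folds %d, seed %d)\n",
              paste(names(x$specs), collapse = "+"), x$oof_folds, x$seed))
  invisible(x)
}

#' Enumerate the evaluated base-classifier combinations
#'
#' From a pool of five base classifiers, the six evaluated ensembles: the
#' five leave-one-out quadruples and the full set (labelled `"All"`).
#'
#' @param pool Character vector of exactly five kinds (default the standard
#'   LR/SVM/KNN/RF/MLP pool).
#' @return List of `list(label =, kinds =)`, length 6.
#' @export
enumerate_combinations <- function(pool = BASE_KINDS) {
  stopifnot(length(pool) == 5L, !anyDuplicated(pool))
  quads <- lapply(seq_along(pool), function(i) {
    kinds <- pool[-i]
    list(label = paste(kinds, collapse = "+"), kinds = kinds)
  })
  c(quads, list(list(label = "All", kinds = pool)))
}

#' Repeated training cycles with simple averaging
#'
#' Trains the stacking ensemble over several independent cycles, each with
#' its own fold partition and fit seeds (and, optionally, its own
#' cluster-centroid undersampling draw), then averages the per-cycle metrics
#' — the protocol behind reporting a mean of repeated runs. Per cycle it
#' records validation metrics (pooled stratified cross-validation on the
#' training data) and independent-test metrics from a model fit on the full
#' cycle training data.
#'
#' @param train_features,train_labels Training data.
#' @param test_features,test_labels Independent test data.
#' @param specs Base classifiers (default all five).
#' @param cycles Number of training cycles (default 10).
#' @param seed Master seed; cycle c uses `seed + 1000 * c`.
#' @param oof_folds Meta-feature folds (default 5).
#' @param cv_folds Validation cross-validation folds (default 10).
#' @param threshold Classification threshold.
#' @param resample If `TRUE`, re-draw cluster-centroid undersampling of the
#'   training data each cycle.
#' @param resample_target Majority target passed to the undersampler.
#' @return List: `per_cycle` (data frame of per-cycle metrics), `avg` and
#'   `sd` (named numeric summaries over cycles).
#' @export
repeated_fit_average <- function(train_features, train_labels,
                                 test_features, test_labels,
                                 specs = NULL, cycles = 10L, seed = 1L,
                                 oof_folds = 5L, cv_folds = 10L,
                                 threshold = 0.5, resample = FALSE,
                                 resample_target = NULL) {
  stopifnot(cycles >= 1L)
  specs <- resolve_specs(specs)
  rows <- vector("list", cycles)
  for (cyc in seq_len(cycles)) {
    cycle_seed <- seed + 1000L * cyc
    feats <- train_features; labs <- as.integer(train_labels)
    if (resample) {
      rs <- cluster_centroids_undersample(feats, labs,
                                          target = resample_target,
                                          seed = cycle_seed)
      feats <- rs$features; labs <- rs$labels
    }
    factory <- function(x, y, seed)
      fit_stacking(x, y, specs = specs, oof_folds = oof_folds, seed = seed)
    cv <- kfold_cv(feats, labs, factory, folds = cv_folds,
                   seed = cycle_seed, threshold = threshold)
    model <- fit_stacking(feats, labs, specs = specs, oof_folds = oof_folds,
                          seed = cycle_seed)
    test <- independent_test(model, test_features, as.integer(test_labels),
                             threshold = threshold)
    v <- cv$pooled
    rows[[cyc]] <- data.frame(
      cycle = cyc,
      val_sn = v$sn, val_sp = v$sp, val_acc = v$acc, val_mcc = v$mcc,
      val_roc = v$roc_auc, val_prc = v$pr_auc,
      test_sn = test$sn, test_sp = test$sp, test_acc = test$acc,
      test_mcc = test$mcc, test_roc = test$roc_auc, test_prc = test$pr_auc)
  }
  per_cycle <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_cycle), "cycle")
  list(per_cycle = per_cycle,
       avg = colMeans(per_cycle[metric_cols]),
       sd = vapply(per_cycle[metric_cols], stats::sd, numeric(1)))
}
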