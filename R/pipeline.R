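#' Assemble a validated pipeline run configuration
#'
#' Ties the stages together: encode, optionally undersample the training
#' split, fit the stacking ensemble over repeated cycles, and evaluate with
#' stratified cross-validation plus an independent test. Inputs are either a
#' positives/negatives FASTA pair (with an optional second pair for the
#' independent test) or an in-memory simulation request.
#'
#' @param train_pos,train_neg Training FASTA paths (positives, negatives).
#' @param test_pos,test_neg Optional independent-test FASTA paths.
#' @param simulate Optional [sim_config()]; used instead of FASTA input
#'   (an 80/20 stratified split provides the independent test).
#' @param encoder An [encoder_config()].
#' @param resample Undersample the training split (default `TRUE` when the
#'   training class ratio exceeds 1.5, else `FALSE`).
#' @param resample_test Also undersample the test split (default `FALSE`;
#'   resampling a test set biases evaluation and is off unless explicitly
#'   requested).
#' @param combo Base-classifier combination label: `"All"` or a `+`-joined
#'   subset such as `"LR+SVM+RF"`.
#' @param oof_folds,cv_folds,cycles,threshold,seed Protocol knobs
#'   (defaults 5, 10, 10, 0.5, 1).
#' @param out_dir Output directory for the manifest and artifacts, or `NULL`
#'   for no files.
#' @return A `run_config` list.
#' @export
run_config <- function(train_pos = NULL, train_neg = NULL,
                       test_pos = NULL, test_neg = NULL, simulate = NULL,
                       encoder = encoder_config(), resample = NULL,
                       resample_test = FALSE, combo = "All",
                       oof_folds = 5L, cv_folds = 10L, cycles = 10L,
                       threshold = 0.5, seed = 1L, out_dir = NULL) {
  if (is.null(simulate)) {
    if (is.null(train_pos) || is.null(train_neg))
      stop("either `simulate` or a training FASTA pair is required")
    for (p in c(train_pos, train_neg, test_pos, test_neg))
      if (!file.exists(p)) stop("input file not found: ", p)
  } else {
    stopifnot(inherits(simulate, "sim_config"))
  }
  structure(list(train_pos = train_pos, train_neg = train_neg,
                 test_pos = test_pos, test_neg = test_neg,
                 simulate = simulate, encoder = encoder,
                 resample = resample, resample_test = resample_test,
                 combo = combo, oof_folds = as.integer(oof_folds),
                 cv_folds = as.integer(cv_folds),
                 cycles = as.integer(cycles), threshold = threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

combo_kinds <- function(label) {
  if (identical(label, "All")) return(BASE_KINDS)
  kinds <- strsplit(label, "+", fixed = TRUE)[[1]]
  bad <- setdiff(kinds, BASE_KINDS)
  if (length(bad)) stop("unknown base classifier(s): ", paste(bad, collapse = ", "))
  kinds
}

stratified_holdout <- function(labels, frac_test, seed) {
  fold <- stratified_folds(labels, round(1 / frac_test), seed)
  which(fold == 1L)
}

#' Run the full prediction pipeline
#'
#' Executes encode -> (optional) cluster-centroid undersampling -> repeated
#' stacking fits -> cross-validation and independent-test reports, and
#' writes a manifest (seeds, configuration, package version, metric
#' summaries) sufficient to reproduce the run.
#'
#' @param config A [run_config()].
#' @return List with `manifest`, `repeated` (per-cycle and averaged
#'   metrics), `train` and `test` dataset summaries; artifacts are written
#'   under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  datasets <- stage("input", {
    if (!is.null(config$simulate)) {
      full <- simulate_dataset(config$simulate)
      test_idx <- stratified_holdout(full$label, 0.2,
                                     seed = config$seed + 17L)
      list(train = full[-test_idx, ], test = full[test_idx, ])
    } else {
      train <- read_fasta_pair(config$train_pos, config$train_neg)
      test <- if (!is.null(config$test_pos))
        read_fasta_pair(config$test_pos, config$test_neg) else NULL
      if (is.null(test)) {
        test_idx <- stratified_holdout(train$label, 0.2,
                                       seed = config$seed + 17L)
        test <- train[test_idx, ]; train <- train[-test_idx, ]
      }
      list(train = train, test = test)
    }
  })

  enc_train <- stage("encode", encode_sequences(datasets$train, config$encoder))
  enc_test <- stage("encode", encode_sequences(datasets$test, config$encoder))

  ratio <- max(table(enc_train$labels)) / min(table(enc_train$labels))
  resample <- if (is.null(config$resample)) ratio > 1.5 else config$resample

  test_features <- enc_test$features
  test_labels <- enc_test$labels
  if (config$resample_test) {
    rs <- stage("undersample",
                cluster_centroids_undersample(test_features, test_labels,
                                              seed = config$seed + 29L))
    test_features <- rs$features; test_labels <- rs$labels
  }

  specs <- resolve_specs(combo_kinds(config$combo))
  repeated <- stage("train", repeated_fit_average(
    enc_train$features, enc_train$labels, test_features, test_labels,
    specs = specs, cycles = config$cycles, seed = config$seed,
    oof_folds = config$oof_folds, cv_folds = config$cv_folds,
    threshold = config$threshold, resample = resample))

  manifest <- list(
    package_version = as.character(utils::packageVersion("stackac4c")),
    seed = config$seed,
    combo = config$combo,
    resample_train = resample,
    resample_test = config$resample_test,
    oof_folds = config$oof_folds, cv_folds = config$cv_folds,
    cycles = config$cycles, threshold = config$threshold,
    encoder = list(pseknc_k = config$encoder$pseknc_k,
                   lambda = config$encoder$lambda, w = config$encoder$w,
                   kmer_spec = config$encoder$kmer_spec),
    n_train = nrow(enc_train$features), n_test = nrow(test_features),
    feature_dim = ncol(enc_train$features),
    avg_metrics = as.list(repeated$avg),
    sd_metrics = as.list(repeated$sd))

  if (!is.null(config$out_dir)) {
    stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.table(repeated$per_cycle,
                         file.path(config$out_dir, "per_cycle_metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  list(manifest = manifest, repeated = repeated,
       train = datasets$train, test = datasets$test)
}
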