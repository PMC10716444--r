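#' Normalize a raw nucleotide string to the RNA alphabet
#'
#' Uppercases the input and maps thymine (`T`/`t`) to uracil (`U`), so that
#' sequences distributed as DNA or RNA, in either case, are handled
#' identically. Any character outside `A/C/G/T/U` (either case) is rejected
#' rather than imputed: ac4C benchmark windows contain no ambiguity codes,
#' and silently guessing a base would corrupt the composition features.
#'
#' @param raw Non-empty character scalar.
#' @return Character scalar over `{A,C,G,U}`. Idempotent.
#' @examples
#' normalize_alphabet("acgt")  # "ACGU"
#' @export
normalize_alphabet <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (nchar(raw) == 0L) stop("sequence is empty")
  out <- chartr("acgtuT", "ACGUUU", raw)
  chars <- strsplit(out, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% RNA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid nucleotide character(s): %s",
      paste(sprintf("'%s' at position %d", chars[bad], bad), collapse = ", ")
    ))
  }
  out
}

#' Construct a labeled sequence dataset
#'
#' A dataset is an ordered collection of fixed-interpretation nucleotide
#' windows: a data frame with columns `id`, `residues` (normalized to
#' `{A,C,G,U}`) and `label` (0/1 or `NA` throughout), plus a free-text
#' `provenance` attribute recording where the windows came from.
#'
#' @param id Character vector of unique identifiers.
#' @param residues Character vector of sequences (normalized on construction).
#' @param label Optional 0/1 vector, one per sequence, or `NULL` (unlabeled).
#' @param provenance Free-text source tag.
#' @return An object of class `ac4c_dataset` (a data frame).
#' @export
new_dataset <- function(id, residues, label = NULL, provenance = "") {
  stopifnot(is.character(id), is.character(residues),
            length(id) == length(residues))
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  residues <- vapply(seq_along(residues), function(i) {
    tryCatch(normalize_alphabet(residues[[i]]),
             error = function(e) stop(sprintf("record '%s': %s", id[[i]],
                                              conditionMessage(e)), call. = FALSE))
  }, character(1))
  if (is.null(label)) {
    label <- rep(NA_integer_, length(id))
  } else {
    label <- as.integer(label)
    stopifnot(length(label) == length(id))
    if (anyNA(label)) stop("labels, when supplied, must be present for all sequences")
    if (!all(label %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  }
  out <- data.frame(id = id, residues = residues, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("ac4c_dataset", "data.frame")
  out
}

#' Read labeled nucleotide windows from a FASTA file
#'
#' Parses FASTA via Biostrings, normalizes each record with
#' [normalize_alphabet()] (T is mapped to U), and optionally attaches one
#' binary label to every record — the usual distribution format for ac4C
#' benchmarks is one positives file and one negatives file.
#'
#' @param path FASTA file path.
#' @param label Optional scalar 0/1 applied to all records, or `NULL`.
#' @param provenance Source tag; defaults to the file path.
#' @return An `ac4c_dataset`.
#' @export
read_fasta <- function(path, label = NULL, provenance = path) {
  stopifnot(file.exists(path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  if (!is.null(label)) {
    stopifnot(length(label) == 1L)
    label <- rep(as.integer(label), length(set))
  }
  new_dataset(ids, as.character(set), label, provenance = provenance)
}

#' Read a positives/negatives FASTA pair as one labeled dataset
#'
#' @param pos_path FASTA of positive (ac4C) windows, labeled 1.
#' @param neg_path FASTA of negative windows, labeled 0.
#' @return An `ac4c_dataset` with positives first, in file order.
#' @export
read_fasta_pair <- function(pos_path, neg_path) {
  pos <- read_fasta(pos_path, label = 1L)
  neg <- read_fasta(neg_path, label = 0L)
  bind_datasets(pos, neg,
                provenance = paste0(pos_path, " + ", neg_path))
}

bind_datasets <- function(..., provenance = "") {
  parts <- list(...)
  out <- do.call(rbind, lapply(parts, as.data.frame))
  new_dataset(out$id, out$residues,
              if (all(is.na(out$label))) NULL else out$label,
              provenance = provenance)
}

#' Write a dataset to FASTA
#'
#' @param dataset An `ac4c_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "ac4c_dataset"))
  set <- Biostrings::RNAStringSet(dataset$residues)
  names(set) <- dataset$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write an encoded feature table as delimited text
#'
#' One row per sequence: id, label (if present) and the feature values,
#' written at 6 significant digits so the table round-trips at the printed
#' precision through [read_feature_table()].
#'
#' @param dataset An `ac4c_dataset` (or `NULL`; then `features` rownames
#'   supply ids and no label column is written).
#' @param features Numeric matrix, one row per sequence, named columns.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(dataset, features, path, sep = "\t") {
  stopifnot(is.matrix(features))
  if (is.null(colnames(features))) stop("feature matrix must have column names")
  if (!is.null(dataset)) {
    stopifnot(inherits(dataset, "ac4c_dataset"),
              nrow(features) == nrow(dataset))
    ids <- dataset$id
    labels <- dataset$label
  } else {
    ids <- rownames(features)
    labels <- rep(NA_integer_, nrow(features))
  }
  has_label <- nrow(features) == 0L || !anyNA(labels)
  df <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (has_label) df$label <- labels
  num <- as.data.frame(signif(features, 6))
  names(num) <- colnames(features)
  df <- if (nrow(features) > 0L) cbind(df, num) else {
    empty <- as.data.frame(matrix(numeric(0), nrow = 0,
                                  ncol = ncol(features)))
    names(empty) <- colnames(features)
    cbind(df[0, , drop = FALSE], empty)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Input path.
#' @param sep Field separator.
#' @return List with `ids`, `labels` (or `NULL`) and `features` matrix.
#' @export
read_feature_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  has_label <- "label" %in% names(df)
  feat_cols <- setdiff(names(df), c("id", "label"))
  features <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(features) <- df$id
  list(ids = as.character(df$id),
       labels = if (has_label) as.integer(df$label) else NULL,
       features = features)
}

#' @export
print.ac4c_dataset <- function(x, ...) {
  lab <- x$label
  cat(sprintf("ac4c_dataset: %d sequences (%s)\n", nrow(x),
              if (all(is.na(lab))) "unlabeled"
              else sprintf("%d positive / %d negative", sum(lab == 1L),
                           sum(lab == 0L))))
  if (nrow(x) > 0L)
    cat(sprintf("  window length: %s\n",
                paste(unique(nchar(x$residues)), collapse = ", ")))
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("  provenance:", prov, "\n")
  invisible(x)
}
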