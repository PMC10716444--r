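#' Construct a dinucleotide physicochemical table
#'
#' The pseudo K-tuple encoder's sequence-order correlations are computed from
#' per-dinucleotide physicochemical indices. A table holds one row per index
#' and one column per RNA dinucleotide (16, lexicographic over A<C<G<U).
#' Before use each index is standardized to mean 0 / SD 1 across the 16
#' dinucleotides, the established convention for pseudo-composition encoders:
#' it puts indices with different units on a common scale so no single index
#' dominates the squared-difference correlation.
#'
#' @param values 6 x 16 (or generally m x 16) numeric matrix; rownames are
#'   index names, colnames the 16 dinucleotides.
#' @param standardized Logical flag; set by [standardize_physchem()].
#' @return A `physchem_table` (numeric matrix with a `standardized` attribute).
#' @export
physchem_table <- function(values, standardized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(colnames(values)) || !setequal(colnames(values), DINUCLEOTIDES))
    stop("physchem table must have the 16 RNA dinucleotides as columns")
  if (anyNA(values)) stop("physchem table has missing cells")
  values <- values[, DINUCLEOTIDES, drop = FALSE]
  attr(values, "standardized") <- isTRUE(standardized)
  class(values) <- c("physchem_table", class(values))
  values
}

#' Standardize each physicochemical index to mean 0 / SD 1
#'
#' @param tab A `physchem_table`.
#' @return The standardized table (idempotent).
#' @export
standardize_physchem <- function(tab) {
  stopifnot(inherits(tab, "physchem_table"))
  if (isTRUE(attr(tab, "standardized"))) return(tab)
  vals <- unclass(tab)
  attr(vals, "standardized") <- NULL
  vals <- t(apply(vals, 1, function(r) (r - mean(r)) / stats::sd(r)))
  colnames(vals) <- colnames(tab)
  physchem_table(vals, standardized = TRUE)
}

#' Load a physicochemical table from TSV
#'
#' Expected layout: header row of the 16 dinucleotides, first column `index`
#' naming each property, one row per property.
#'
#' @param path TSV path; defaults to the packaged RNA helical-parameter set
#'   (rise, roll, shift, slide, tilt, twist).
#' @param standardize Standardize after loading (default `TRUE`).
#' @return A `physchem_table`.
#' @export
read_physchem <- function(path = NULL, standardize = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "rna_dinucleotide_physchem.tsv",
                        package = "stackac4c", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  colnames(mat) <- chartr("T", "U", toupper(colnames(mat)))
  tab <- physchem_table(mat)
  if (standardize) standardize_physchem(tab) else tab
}

#' Packaged default physicochemical table (standardized)
#'
#' Six RNA dinucleotide helical parameters — rise, roll, shift (translate),
#' slide, tilt, twist — as published for RNA base-pair steps and used across
#' the pseudo K-tuple composition literature, standardized over the 16
#' dinucleotides.
#'
#' @return A standardized `physchem_table`.
#' @export
physchem_default <- function() {
  read_physchem(NULL, standardize = TRUE)
}
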