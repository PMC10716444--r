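#' Configuration for the synthetic ac4C benchmark generator
#'
#' The generator emulates the structure of the public ac4C benchmarks:
#' fixed-length A/C/G/U windows, a positive class carrying a codon-phased
#' cytidine enrichment, and a configurable class ratio from balanced up to
#' roughly 1:10. Negatives are i.i.d. draws from the background composition;
#' positives add `c_enrichment` of extra probability mass on C at every
#' codon-position-1 site (positions 1, 4, 7, ...), with the other three
#' bases scaled down proportionally. The signal is a continuous positional
#' composition bias — one knob — rather than a literal inserted motif,
#' matching the observation that acetylated transcripts are enriched for
#' cytidine-containing codons rather than a sharp consensus.
#'
#' @param n_pos,n_neg Class sizes.
#' @param length Window length (default 201).
#' @param c_enrichment Extra C probability at codon-position-1 of positives,
#'   in `[0, 1 - background C]` (default 0.3).
#' @param background Length-4 composition over A,C,G,U summing to 1
#'   (default uniform).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pos, n_neg, length = 201L, c_enrichment = 0.3,
                       background = rep(0.25, 4), seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length >= 3L, c_enrichment >= 0)
  if (base::length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be a length-4 probability vector over A,C,G,U")
  if (background[2] + c_enrichment > 1)
    stop("c_enrichment pushes the C probability above 1")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length = as.integer(length), c_enrichment = c_enrichment,
                 background = as.numeric(background),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a labeled ac4C-style benchmark dataset
#'
#' @param config A [sim_config()].
#' @return An `ac4c_dataset` (positives first), deterministic given the seed.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bg <- config$background
  boosted <- bg
  boosted[2] <- bg[2] + config$c_enrichment
  boosted[-2] <- bg[-2] * (1 - boosted[2]) / (1 - bg[2])
  L <- config$length
  codon1 <- seq(1L, L, by = 3L)

  with_seed(config$seed, {
    draw <- function(n, pos_signal) {
      vapply(seq_len(n), function(i) {
        probs <- matrix(bg, nrow = 4L, ncol = L)
        if (pos_signal) probs[, codon1] <- boosted
        paste(apply(probs, 2L, function(p)
          sample(RNA_ALPHABET, 1L, prob = p)), collapse = "")
      }, character(1))
    }
    pos <- draw(config$n_pos, TRUE)
    neg <- draw(config$n_neg, FALSE)
    new_dataset(
      id = c(sprintf("pos_%d", seq_len(config$n_pos)),
             sprintf("neg_%d", seq_len(config$n_neg))),
      residues = c(pos, neg),
      label = c(rep(1L, config$n_pos), rep(0L, config$n_neg)),
      provenance = sprintf("simulated (seed %d, enrichment %g)",
                           config$seed, config$c_enrichment))
  })
}

#' Write a simulated dataset as positives/negatives FASTA plus a label table
#'
#' @param dataset An `ac4c_dataset` with labels.
#' @param out_prefix Path prefix; writes `<prefix>_pos.fasta`,
#'   `<prefix>_neg.fasta` and `<prefix>_labels.tsv`.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_simulated_dataset <- function(dataset, out_prefix) {
  stopifnot(inherits(dataset, "ac4c_dataset"), !anyNA(dataset$label))
  pos_path <- paste0(out_prefix, "_pos.fasta")
  neg_path <- paste0(out_prefix, "_neg.fasta")
  lab_path <- paste0(out_prefix, "_labels.tsv")
  write_fasta(dataset[dataset$label == 1L, ], pos_path)
  write_fasta(dataset[dataset$label == 0L, ], neg_path)
  utils::write.table(data.frame(id = dataset$id, label = dataset$label),
                     lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pos = pos_path, neg = neg_path, labels = lab_path))
}
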