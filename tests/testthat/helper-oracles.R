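# Independent oracles and small fixture builders used across the suite.
# Each oracle is a direct, loop-level transcription of the defining formula,
# sharing no code with the implementation it checks.

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Brute-force overlapping k-mer frequency by sliding a window.
kmer_freq_oracle <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  words <- vapply(seq_len(L - k + 1), function(i)
    paste(chars[i:(i + k - 1)], collapse = ""), character(1))
  all_kmers <- sort(apply(
    do.call(expand.grid, rep(list(c("A", "C", "G", "U")), k)),
    1, paste, collapse = ""))
  counts <- vapply(all_kmers, function(w) sum(words == w), numeric(1))
  counts / (L - k + 1)
}

# Nested-loop pseudo K-tuple composition: k-tuple frequencies plus lambda
# tier correlations from the mean squared standardized-index difference of
# dinucleotide pairs, all over a shared denominator.
pseknc_oracle <- function(seq, k, lambda, w, physchem_raw) {
  P <- t(apply(unclass(physchem_raw), 1,
               function(r) (r - mean(r)) / sd(r)))
  colnames(P) <- colnames(physchem_raw)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  dinuc_at <- function(i) paste0(chars[i], chars[i + 1])
  theta_pair <- function(d1, d2) mean((P[, d1] - P[, d2])^2)
  theta <- vapply(seq_len(lambda), function(j) {
    mean(vapply(seq_len(L - j - 1), function(i)
      theta_pair(dinuc_at(i), dinuc_at(i + j)), numeric(1)))
  }, numeric(1))
  f <- kmer_freq_oracle(seq, k)
  unname(c(f, w * theta) / (sum(f) + w * sum(theta)))
}

# Mann-Whitney pair-counting AUC: fraction of (positive, negative) score
# pairs correctly ordered, ties counted one half.
mw_auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Labeled feature fixture: two Gaussian classes with controllable
# separation, as a stand-in for encoded windows in model-level tests.
gaussian_features <- function(n_pos, n_neg, p = 6, shift = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_pos * p, mean = shift), n_pos, p),
               matrix(rnorm(n_neg * p, mean = 0), n_neg, p))
    colnames(x) <- sprintf("f%d", seq_len(p))
    list(features = x, labels = c(rep(1L, n_pos), rep(0L, n_neg)))
  })
}

tmp_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}
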