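EIIP_VALUES <- c(A = 0.1260, C = 0.1340, G = 0.806, U = 0.1335)

new_feature_vector <- function(values, names, encoder) {
  stopifnot(length(values) == length(names))
  v <- as.numeric(values)
  names(v) <- names
  attr(v, "encoder") <- encoder
  v
}

check_residues <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!grepl("^[ACGU]+$", seq))
    stop("sequence must be normalized to {A,C,G,U}; see normalize_alphabet()")
  seq
}

#' All k-mers over A/C/G/U in lexicographic order
#' @param k Word size.
#' @return Character vector of length `4^k`.
#' @keywords internal
kmer_names <- function(k) {
  memoize(paste0("kmer_names_", k), function() {
    g <- do.call(expand.grid,
                 c(rep(list(RNA_ALPHABET), k), stringsAsFactors = FALSE))
    apply(g[, k:1, drop = FALSE], 1, paste0, collapse = "")
  })
}

count_kmers <- function(seq, k) {
  cnt <- Biostrings::oligonucleotideFrequency(Biostrings::RNAString(seq),
                                              width = k)
  as.numeric(cnt)  # Biostrings order is lexicographic over A<C<G<U
}

#' k-mer composition of a nucleotide window
#'
#' Overlapping k-mer counts normalized by the number of length-k windows,
#' `L - k + 1`, so the 4^k entries always sum to 1 regardless of sequence
#' length. Feature order is lexicographic (A < C < G < U).
#'
#' @param seq Normalized sequence string.
#' @param k Word size (>= 1).
#' @return Named numeric vector of length `4^k`, encoder tag `"kmer"`.
#' @examples
#' encode_kmer("ACGUACGU", 2)[c("AC", "CG", "GU", "UA")]
#' @export
encode_kmer <- function(seq, k) {
  check_residues(seq)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  L <- nchar(seq)
  if (L < k) stop(sprintf("sequence length %d is shorter than k = %d", L, k))
  new_feature_vector(count_kmers(seq, k) / (L - k + 1), kmer_names(k), "kmer")
}

reverse_complement_kmers <- function(kmers) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(kmers)))
}

#' Strand-collapsed k-mer classes
#'
#' Groups the 4^k k-mers into reverse-complement equivalence classes, each
#' named by its lexicographically smaller member. For odd k there are no
#' self-complementary words, giving exactly `4^k / 2` classes.
#' @keywords internal
rc_classes <- function(k) {
  memoize(paste0("rc_classes_", k), function() {
    km <- kmer_names(k)
    canon <- pmin(km, reverse_complement_kmers(km))
    split(km, factor(canon, levels = sort(unique(canon))))
  })
}

#' Default composite k-mer specification (48 dimensions)
#'
#' The predictor's k-mer block is a 48-dimensional composite: the 16
#' dinucleotide frequencies plus the 32 reverse-complement-collapsed
#' trinucleotide classes. This composition is a documented reconstruction —
#' it is the package's canonical choice of a dimension-consistent k-mer
#' block, and any other specification can be supplied instead.
#'
#' @return List of components, each `list(k =, collapse =)` with collapse
#'   `"none"` or `"rc"`.
#' @export
default_kmer_spec <- function() {
  list(list(k = 2L, collapse = "none"),
       list(k = 3L, collapse = "rc"))
}

#' Composite k-mer encoding
#'
#' Concatenates one or more k-mer blocks, each individually normalized to
#' sum 1. With the default specification the result has exactly 48
#' dimensions.
#'
#' @param seq Normalized sequence string.
#' @param spec List of components as in [default_kmer_spec()].
#' @return Named numeric vector, encoder tag `"kmer"`.
#' @export
encode_kmer_composite <- function(seq, spec = default_kmer_spec()) {
  if (length(spec) == 0L) stop("kmer spec must contain at least one component")
  parts <- lapply(spec, function(comp) {
    stopifnot(is.list(comp), !is.null(comp$k))
    collapse <- if (is.null(comp$collapse)) "none" else comp$collapse
    base <- encode_kmer(seq, comp$k)
    if (collapse == "none") {
      names(base) <- sprintf("k%d_%s", comp$k, names(base))
      base
    } else if (collapse == "rc") {
      cls <- rc_classes(comp$k)
      vals <- vapply(cls, function(members) sum(base[members]), numeric(1))
      new_feature_vector(vals, sprintf("k%drc_%s", comp$k, names(cls)), "kmer")
    } else {
      stop("unknown collapse mode: ", collapse)
    }
  })
  new_feature_vector(unlist(lapply(parts, as.numeric)),
                     unlist(lapply(parts, names)), "kmer")
}

#' Electron-ion interaction pseudopotential (EIIP) trinucleotide encoding
#'
#' Each of the 64 trinucleotides xyz contributes one feature: its normalized
#' overlapping frequency weighted by the summed EIIP of its three bases,
#' `EIIP_x + EIIP_y + EIIP_z`, with per-base values A = 0.1260, C = 0.1340,
#' G = 0.806 and U = 0.1335 (the published thymine value, carried over to
#' uracil for mRNA). Trinucleotides absent from the window score exactly 0.
#'
#' @param seq Normalized sequence string, length >= 3.
#' @return Named numeric 64-vector, encoder tag `"pseeiip"`.
#' @export
encode_pseeiip <- function(seq) {
  check_residues(seq)
  L <- nchar(seq)
  if (L < 3L) stop("sequence shorter than 3 nucleotides")
  freq <- count_kmers(seq, 3L) / (L - 2L)
  tri <- kmer_names(3L)
  eiip3 <- memoize("eiip_trinucleotide", function()
    vapply(strsplit(tri, "", fixed = TRUE),
           function(x) sum(EIIP_VALUES[x]), numeric(1)))
  new_feature_vector(eiip3 * freq, tri, "pseeiip")
}

# 16x16 matrix of mean squared standardized-index differences between
# dinucleotide pairs; the kernel of the sequence-order correlation.
# Cached on the table (attr "dinuc_dist") since it is reused per sequence.
dinuc_distance_matrix <- function(physchem) {
  cached <- attr(physchem, "dinuc_dist")
  if (!is.null(cached)) return(cached)
  P <- unclass(standardize_physchem(physchem))
  D <- matrix(0, 16, 16, dimnames = list(DINUCLEOTIDES, DINUCLEOTIDES))
  for (a in seq_len(16)) for (b in seq_len(16))
    D[a, b] <- mean((P[, a] - P[, b])^2)
  D
}

#' Pseudo K-tuple nucleotide composition (PseKNC)
#'
#' Augments the 4^k k-tuple frequencies with `lambda` sequence-order
#' correlation factors. The j-th factor is the average, over all positions i,
#' of the squared physicochemical difference between the dinucleotides
#' starting at i and at i + j, where the per-pair difference is the mean over
#' the six standardized dinucleotide indices. Frequencies and weighted
#' correlations share one denominator, so the full (4^k + lambda)-vector
#' sums to 1:
#' entries 1..4^k are `f_u / (1 + w * sum(theta))` and the remaining lambda
#' entries are `w * theta_j / (1 + w * sum(theta))`.
#'
#' @param seq Normalized sequence string; must satisfy `lambda < L - 1`.
#' @param k Tuple size (default 3).
#' @param lambda Number of correlation tiers (default 20).
#' @param w Weight factor balancing composition against correlations
#'   (default 0.1).
#' @param physchem A `physchem_table`; standardized internally if needed.
#' @return Named numeric vector of length `4^k + lambda`, tag `"pseknc"`.
#' @export
encode_pseknc <- function(seq, k = 3L, lambda = 20L, w = 0.1,
                          physchem = physchem_default()) {
  check_residues(seq)
  k <- as.integer(k); lambda <- as.integer(lambda)
  stopifnot(k >= 1L, lambda >= 0L, w >= 0)
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k")
  if (lambda >= L - 1L)
    stop(sprintf(paste0("lambda = %d too large for sequence length %d: the ",
                        "correlation tiers require lambda < L - 1"),
                 lambda, L))
  f <- count_kmers(seq, k) / (L - k + 1L)
  theta <- numeric(lambda)
  if (lambda > 0L) {
    D <- dinuc_distance_matrix(physchem)
    idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], RNA_ALPHABET)
    code <- (idx[-L] - 1L) * 4L + idx[-1L]  # dinucleotide at each position
    for (j in seq_len(lambda)) {
      i <- seq_len(L - j - 1L)
      theta[j] <- mean(D[cbind(code[i], code[i + j])])
    }
  }
  denom <- sum(f) + w * sum(theta)
  new_feature_vector(c(f, w * theta) / denom,
                     c(kmer_names(k),
                       if (lambda > 0L) sprintf("theta%d", seq_len(lambda))),
                     "pseknc")
}

#' Fuse per-encoder feature vectors into one hybrid vector
#'
#' Concatenates encoder outputs in the fixed canonical order in which they
#' are supplied (the package default is k-mer composite, PseKNC, PseEIIP),
#' prefixing each name with its encoder tag so part boundaries remain
#' recoverable. The default three encoders on any valid window give the
#' 196-dimensional hybrid vector (48 + 84 + 64).
#'
#' @param parts Non-empty list of feature vectors from the encoders.
#' @return Named numeric vector, encoder tag `"fused"`.
#' @export
fuse_features <- function(parts) {
  if (!is.list(parts) || length(parts) == 0L)
    stop("parts must be a non-empty list of feature vectors")
  pieces <- lapply(parts, function(p) {
    tag <- attr(p, "encoder")
    if (is.null(tag)) tag <- "feat"
    v <- as.numeric(p)
    names(v) <- paste0(tag, ".", names(p))
    v
  })
  out <- unlist(pieces, use.names = TRUE)
  if (anyDuplicated(names(out)))
    stop("fused feature names are not unique; check encoder tags")
  new_feature_vector(as.numeric(out), names(out), "fused")
}

#' Encoder configuration
#'
#' @param kmer_spec Composite k-mer specification ([default_kmer_spec()]).
#' @param pseknc_k PseKNC tuple size (default 3).
#' @param lambda PseKNC correlation tiers (default 20).
#' @param w PseKNC weight factor (default 0.1).
#' @param physchem A `physchem_table` or `NULL` for the packaged default.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(kmer_spec = default_kmer_spec(), pseknc_k = 3L,
                           lambda = 20L, w = 0.1, physchem = NULL) {
  stopifnot(lambda >= 0, w >= 0, pseknc_k >= 1)
  if (is.null(physchem)) physchem <- physchem_default()
  physchem <- standardize_physchem(physchem)
  attr(physchem, "dinuc_dist") <- dinuc_distance_matrix(physchem)
  structure(list(kmer_spec = kmer_spec, pseknc_k = as.integer(pseknc_k),
                 lambda = as.integer(lambda), w = w, physchem = physchem),
            class = "encoder_config")
}

#' Encode one window with the fused default feature set
#'
#' @param seq Normalized sequence string.
#' @param config An [encoder_config()].
#' @return Fused named numeric vector (196-D under defaults).
#' @export
encode_sequence <- function(seq, config = encoder_config()) {
  fuse_features(list(
    encode_kmer_composite(seq, config$kmer_spec),
    encode_pseknc(seq, k = config$pseknc_k, lambda = config$lambda,
                  w = config$w, physchem = config$physchem),
    encode_pseeiip(seq)
  ))
}

#' Encode a dataset into a feature matrix
#'
#' @param dataset An `ac4c_dataset`.
#' @param config An [encoder_config()].
#' @return List with `features` (n x p matrix, rownames = ids) and `labels`
#'   (integer vector or `NULL` if the dataset is unlabeled).
#' @export
encode_sequences <- function(dataset, config = encoder_config()) {
  stopifnot(inherits(dataset, "ac4c_dataset"))
  if (nrow(dataset) == 0L) stop("empty dataset")
  rows <- lapply(dataset$residues, encode_sequence, config = config)
  features <- do.call(rbind, lapply(rows, as.numeric))
  colnames(features) <- names(rows[[1]])
  rownames(features) <- dataset$id
  labels <- if (all(is.na(dataset$label))) NULL else dataset$label
  list(features = features, labels = labels)
}
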