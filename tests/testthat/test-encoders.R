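test_that("k-mer composition matches closed-form and brute-force counts", {
  expect_equal(unname(as.numeric(encode_kmer("ACGU", 1))), rep(0.25, 4))
  v <- encode_kmer("AAAA", 2)
  expect_equal(unname(v[["AA"]]), 1)
  expect_equal(sum(v), 1)
  expect_equal(sum(v != 0), 1L)

  v <- encode_kmer("ACGUACGU", 2)
  expect_equal(unname(v[c("AC", "CG", "GU", "UA")]),
               c(2, 2, 2, 1) / 7, ignore_attr = TRUE)

  withr::with_seed(11, {
    for (rep in 1:5) {
      s <- random_seq(sample(10:40, 1))
      for (k in 1:3)
        expect_equal(unname(as.numeric(encode_kmer(s, k))),
                     unname(kmer_freq_oracle(s, k)), tolerance = 1e-14)
    }
  })
  expect_error(encode_kmer("ACG", 4), "shorter than k")
})

test_that("k-mer vectors sum to one for every sequence and k", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      s <- random_seq(sample(5:60, 1))
      for (k in 1:3)
        expect_equal(sum(encode_kmer(s, k)), 1, tolerance = 1e-12)
    }
  })
})

test_that("composite k-mer block has 48 dimensions and per-component normalization", {
  withr::with_seed(3, s <- random_seq(201))
  v <- encode_kmer_composite(s)
  expect_length(v, 48L)
  expect_equal(sum(v), 2, tolerance = 1e-12)  # two components, each sums to 1
  expect_equal(sum(v[startsWith(names(v), "k2_")]), 1, tolerance = 1e-12)
  expect_equal(sum(v[startsWith(names(v), "k3rc_")]), 1, tolerance = 1e-12)

  single <- encode_kmer_composite(s, list(list(k = 1L, collapse = "none")))
  expect_equal(unname(as.numeric(single)),
               unname(as.numeric(encode_kmer(s, 1))))
  expect_error(encode_kmer_composite(s, list()), "at least one component")
})

test_that("strand-collapsed trinucleotide classes pair each word with its reverse complement", {
  cls <- stackac4c:::rc_classes(3)
  expect_length(cls, 32L)
  expect_true(all(lengths(cls) == 2L))
  # every class holds a word and its reverse complement
  rc <- function(x) chartr("ACGU", "UGCA",
                           vapply(strsplit(x, ""), function(ch)
                             paste(rev(ch), collapse = ""), character(1)))
  for (members in cls) expect_identical(sort(rc(members)), sort(members))
})

test_that("EIIP encoding is the frequency vector weighted by summed base potentials", {
  v <- encode_pseeiip("AAAAA")
  expect_length(v, 64L)
  expect_equal(unname(v[["AAA"]]), 3 * 0.1260 * 1, tolerance = 1e-12)
  expect_true(all(v[names(v) != "AAA"] == 0))

  withr::with_seed(8, s <- random_seq(50))
  freq <- kmer_freq_oracle(s, 3)
  eiip <- c(A = 0.1260, C = 0.1340, G = 0.806, U = 0.1335)
  weights <- vapply(strsplit(names(freq), ""), function(x) sum(eiip[x]),
                    numeric(1))
  expect_equal(unname(as.numeric(encode_pseeiip(s))),
               unname(freq * weights), tolerance = 1e-12)
  expect_error(encode_pseeiip("AC"), "shorter than 3")
})

test_that("physicochemical table standardizes to mean 0 / SD 1 and is idempotent", {
  tab <- read_physchem(standardize = FALSE)
  expect_false(attr(tab, "standardized"))
  std <- standardize_physchem(tab)
  expect_true(attr(std, "standardized"))
  expect_equal(dim(std), c(6L, 16L))
  expect_equal(unname(rowMeans(std)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(std, 1, sd)), rep(1, 6), tolerance = 1e-9)
  expect_identical(unclass(standardize_physchem(std)), unclass(std))
})

test_that("PseKNC has dimension 4^k + lambda, sums to one, and respects limiting cases", {
  withr::with_seed(21, s <- random_seq(201))
  v <- encode_pseknc(s)
  expect_length(v, 84L)
  expect_equal(sum(v), 1, tolerance = 1e-12)

  # w = 0: composition part reduces to plain frequencies, tiers vanish
  v0 <- encode_pseknc(s, w = 0)
  expect_equal(unname(as.numeric(v0[1:64])), unname(kmer_freq_oracle(s, 3)),
               tolerance = 1e-12)
  expect_true(all(v0[65:84] == 0))

  # identical physicochemical values for all dinucleotides -> all theta 0
  flat <- physchem_table(matrix(rep(c(1, 2, 3, 4, 5, 6), each = 16), 6, 16,
                                byrow = TRUE,
                                dimnames = list(letters[1:6],
                                                stackac4c:::DINUCLEOTIDES)),
                         standardized = TRUE)
  vf <- encode_pseknc(s, physchem = flat)
  expect_true(all(vf[65:84] == 0))
  expect_equal(unname(as.numeric(vf[1:64])), unname(kmer_freq_oracle(s, 3)),
               tolerance = 1e-12)

  expect_error(encode_pseknc("ACGUACGU", lambda = 7), "lambda")
})

test_that("PseKNC matches the nested-loop oracle", {
  raw <- read_physchem(standardize = FALSE)
  # single-tier correlation on a short word, against the direct sum
  v <- encode_pseknc("ACGUACGU", k = 3, lambda = 1, w = 0.1, physchem = raw)
  oracle <- pseknc_oracle("ACGUACGU", k = 3, lambda = 1, w = 0.1,
                          physchem_raw = raw)
  expect_equal(unname(as.numeric(v)), oracle, tolerance = 1e-12)

  withr::with_seed(77, {
    for (rep in 1:20) {
      s <- random_seq(30)
      v <- encode_pseknc(s, k = 3, lambda = 5, w = 0.1, physchem = raw)
      expect_equal(unname(as.numeric(v)),
                   pseknc_oracle(s, 3, 5, 0.1, raw), tolerance = 1e-10)
    }
  })
})

test_that("feature fusion reaches 196 dimensions with recoverable part boundaries", {
  withr::with_seed(4, s <- random_seq(201))
  fused <- encode_sequence(s)
  expect_length(fused, 196L)
  expect_false(anyDuplicated(names(fused)) > 0)
  tags <- sub("\\..*$", "", names(fused))
  expect_equal(unname(table(tags)[c("kmer", "pseknc", "pseeiip")]),
               c(48L, 84L, 64L), ignore_attr = TRUE)

  single <- fuse_features(list(encode_pseeiip(s)))
  expect_equal(unname(as.numeric(single)),
               unname(as.numeric(encode_pseeiip(s))))
  expect_error(fuse_features(list()), "non-empty")
})

test_that("encoders are deterministic and order-independent across a dataset", {
  withr::with_seed(9, seqs <- replicate(4, random_seq(60)))
  ds <- new_dataset(sprintf("s%d", 1:4), seqs)
  cfg <- encoder_config(lambda = 10L)
  enc <- encode_sequences(ds, cfg)
  rev_ds <- ds[4:1, ]
  enc_rev <- encode_sequences(rev_ds, cfg)
  expect_identical(enc$features, enc$features)
  expect_equal(enc$features[rev_ds$id, ], enc_rev$features)
  expect_equal(encode_sequence(seqs[1], cfg), encode_sequence(seqs[1], cfg))
})
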