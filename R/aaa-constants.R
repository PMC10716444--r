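# Shared package constants (file named to load first).

RNA_ALPHABET <- c("A", "C", "G", "U")

# Lexicographic over A<C<G<U: AA, AC, AG, AU, CA, ...
DINUCLEOTIDES <- as.vector(t(outer(RNA_ALPHABET, RNA_ALPHABET,
                                   function(a, b) paste0(a, b))))

# Memo store for small static lookups (k-mer name lists, strand-collapse
# classes, EIIP trinucleotide weights) recomputed otherwise per sequence.
.memo <- new.env(parent = emptyenv())

memoize <- function(key, value_fn) {
  if (!exists(key, envir = .memo, inherits = FALSE))
    assign(key, value_fn(), envir = .memo)
  get(key, envir = .memo, inherits = FALSE)
}
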