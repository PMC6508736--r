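# Small in-code fixtures shared across test files.

make_counts <- function(n_genes = 50, n_samples = 4, mu = 200, size = 5,
                        seed = 42) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, size = size, mu = mu),
              n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              paste0("S", seq_len(n_samples))))
  count_matrix(m)
}

# A tiny hand-specified human-style reference (non-Sertoli types) kept in
# raw per-cell units (rescale = FALSE) so expected values stay readable.
make_tiny_ref <- function() {
  expr <- rbind(GA = c(Leydig = 10, spermatogonia = 5, round_spermatids = 1),
                GB = c(Leydig = 0, spermatogonia = 0, round_spermatids = 20),
                GC = c(Leydig = 2, spermatogonia = 2, round_spermatids = 2))
  cell_type_reference(expr, "human", rescale = FALSE)
}

tiny_comp <- function() {
  cell_composition(c(Sertoli = 0.2, Leydig = 0.2, spermatogonia = 0.3,
                     round_spermatids = 0.3))
}

expect_nested <- function(smaller, larger) {
  expect_length(setdiff(smaller, larger), 0)
}
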