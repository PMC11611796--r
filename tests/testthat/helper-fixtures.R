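# Small in-code fixtures shared across the test files.

tiny_benchmark <- function(id = "TB-1",
                           nx = 4L, ny = nx, na = 4L, nb = na,
                           prefix = "") {
  mk <- function(slot, n) paste0(prefix, slot, letters[seq_len(n)])
  bias_benchmark(
    id, "tiny synthetic benchmark",
    target_x = term_set("tx", mk("x", nx)),
    target_y = term_set("ty", mk("y", ny)),
    attribute_a = term_set("ta", mk("a", na)),
    attribute_b = term_set("tb", mk("b", nb)))
}

tiny_store <- function(terms, dim = 4L, seed = 1L, label = "tiny") {
  m <- withr::with_seed(seed, matrix(stats::rnorm(length(terms) * dim),
                                     nrow = length(terms)))
  rownames(m) <- terms
  embedding_store(m, source_label = label)
}

store_for <- function(benchmark, beta = 1, noise = 1, seed = 1L,
                      dim = 50L, n_filler = 0L) {
  generate_synthetic_embeddings(
    synthetic_config(dimension = dim, bias_strength = beta,
                     noise_scale = noise, seed = seed),
    benchmark, n_filler = n_filler)
}

# Independent cosine / association / partition oracles, deliberately written
# with scalar arithmetic so the tests do not reuse the package's code paths.
oracle_cos <- function(u, v) sum(u * v) / sqrt(sum(u^2)) / sqrt(sum(v^2))

oracle_assoc <- function(w, A, B) {
  mean(vapply(seq_len(nrow(A)), function(i) oracle_cos(w, A[i, ]), 0)) -
    mean(vapply(seq_len(nrow(B)), function(i) oracle_cos(w, B[i, ]), 0))
}

oracle_exact_p <- function(X, Y, A, B) {
  W <- rbind(X, Y)
  s <- vapply(seq_len(nrow(W)), function(i) oracle_assoc(W[i, ], A, B), 0)
  n <- length(s)
  obs <- sum(s[seq_len(nrow(X))]) - sum(s[-seq_len(nrow(X))])
  subsets <- utils::combn(n, n / 2)
  stats_i <- apply(subsets, 2, function(idx) sum(s[idx]) - sum(s[-idx]))
  mean(stats_i > obs)
}
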