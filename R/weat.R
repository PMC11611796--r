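as_vec_matrix <- function(x, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric vector or matrix", what), call. = FALSE)
  }
  x
}

check_vector_sets <- function(sets) {
  dims <- vapply(sets, ncol, 1L)
  if (length(unique(dims)) != 1L) {
    stop(sprintf("vector dimension mismatch across sets: %s",
                 paste(dims, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(sets)) {
    m <- sets[[nm]]
    if (nrow(m) == 0L) stop(sprintf("%s is empty", nm), call. = FALSE)
    if (!all(is.finite(m))) stop(sprintf("%s contains non-finite values", nm), call. = FALSE)
    if (any(rowSums(m != 0) == 0L)) {
      stop(sprintf("%s contains a zero vector", nm), call. = FALSE)
    }
  }
  invisible(sets)
}

row_unit <- function(m) m / sqrt(rowSums(m^2))

# Cosine similarity between each row of W and each row of M.
cosine_matrix <- function(W, M) {
  tcrossprod(row_unit(W), row_unit(M))
}

# s(w, A, B) for each row w of W: mean cosine to A minus mean cosine to B.
association_profile <- function(W, A, B) {
  rowMeans(cosine_matrix(W, A)) - rowMeans(cosine_matrix(W, B))
}

#' Association of a word with two attribute sets
#'
#' The per-word association measure `s(w, A, B)`: the mean cosine
#' similarity of `w` to the attribute vectors in `A` minus the mean cosine
#' similarity to those in `B`. Values lie in `[-2, 2]`.
#'
#' @param w_vec Numeric vector (one word's embedding).
#' @param A_vecs,B_vecs Numeric matrices, one attribute vector per row.
#' @return The association value, a single real number.
#' @examples
#' weat_association(c(1, 0), matrix(c(1, 0), 1), matrix(c(0, 1), 1)) # 1
#' @export
weat_association <- function(w_vec, A_vecs, B_vecs) {
  W <- as_vec_matrix(w_vec, "w_vec")
  A <- as_vec_matrix(A_vecs, "A_vecs")
  B <- as_vec_matrix(B_vecs, "B_vecs")
  if (nrow(W) != 1L) stop("w_vec must be a single vector", call. = FALSE)
  check_vector_sets(list(w_vec = W, A_vecs = A, B_vecs = B))
  as.numeric(association_profile(W, A, B))
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

apply_sd <- function(x, convention) {
  switch(convention, population = pop_sd(x), sample = stats::sd(x),
         stop("unknown sd convention: ", convention, call. = FALSE))
}

effect_size_impl <- function(sX, sY, sd_convention) {
  num <- mean(sX) - mean(sY)
  den <- apply_sd(c(sX, sY), sd_convention)
  if (den == 0) {
    if (num == 0) return(0)
    stop("zero association spread with non-zero mean difference", call. = FALSE)
  }
  num / den
}

#' WEAT effect size
#'
#' The normalized separation of the two target sets' association
#' distributions: the difference in mean association between targets `X`
#' and `Y`, divided by the standard deviation of the associations over the
#' pooled targets `X` union `Y` (a Cohen's-d-style statistic). Under the
#' default population-SD denominator and equal target-set sizes, the
#' magnitude is bounded by 2. When every pooled association is identical
#' (so both numerator and denominator vanish) the effect size is defined
#' as 0.
#'
#' @param X_vecs,Y_vecs Target vectors, one row per term.
#' @param A_vecs,B_vecs Attribute vectors, one row per term.
#' @param sd_convention `"population"` (divide by n; the default) or
#'   `"sample"` (divide by n - 1) for the denominator.
#' @return The effect size d.
#' @export
weat_effect_size <- function(X_vecs, Y_vecs, A_vecs, B_vecs,
                             sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  X <- as_vec_matrix(X_vecs, "X_vecs"); Y <- as_vec_matrix(Y_vecs, "Y_vecs")
  A <- as_vec_matrix(A_vecs, "A_vecs"); B <- as_vec_matrix(B_vecs, "B_vecs")
  check_vector_sets(list(X_vecs = X, Y_vecs = Y, A_vecs = A, B_vecs = B))
  effect_size_impl(association_profile(X, A, B),
                   association_profile(Y, A, B), sd_convention)
}

#' WEAT test statistic
#'
#' The differential association of the two target sets with the
#' attributes: the sum of associations over `X` minus the sum over `Y`.
#' Its permutation distribution over equal-size partitions of the pooled
#' targets yields the WEAT p-value.
#'
#' @inheritParams weat_effect_size
#' @return The test statistic, a single real number.
#' @export
weat_statistic <- function(X_vecs, Y_vecs, A_vecs, B_vecs) {
  X <- as_vec_matrix(X_vecs, "X_vecs"); Y <- as_vec_matrix(Y_vecs, "Y_vecs")
  A <- as_vec_matrix(A_vecs, "A_vecs"); B <- as_vec_matrix(B_vecs, "B_vecs")
  check_vector_sets(list(X_vecs = X, Y_vecs = Y, A_vecs = A, B_vecs = B))
  sum(association_profile(X, A, B)) - sum(association_profile(Y, A, B))
}

#' WEAT permutation p-value
#'
#' One-sided p-value of the test statistic under the null hypothesis of no
#' differential association: the probability that a random equal-size
#' partition `(Xi, Yi)` of the pooled targets yields a strictly greater
#' statistic than observed. `mode = "exact"` enumerates all
#' `choose(n, n/2)` partitions of the `n` pooled targets; `"monte_carlo"`
#' draws `n_draws` uniform random partitions; `"auto"` (the default) picks
#' exact enumeration when the partition count is at most `max_exact`.
#' Ties with the observed statistic count as non-exceedances; when more
#' than 1% of partitions tie, a degenerate-tie warning is raised.
#'
#' @inheritParams weat_effect_size
#' @param mode `"auto"`, `"exact"` or `"monte_carlo"`.
#' @param max_exact Partition-count threshold for automatic exact
#'   enumeration (default 200000).
#' @param n_draws Number of Monte-Carlo partitions (default 10000).
#' @param seed Integer seed for Monte-Carlo mode.
#' @return A list with `p` (the p-value), `method` (`"exact"` or
#'   `"monte_carlo"`) and `n` (partitions enumerated or draws taken).
#' @export
weat_p_value <- function(X_vecs, Y_vecs, A_vecs, B_vecs,
                         mode = c("auto", "exact", "monte_carlo"),
                         max_exact = 200000L, n_draws = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  X <- as_vec_matrix(X_vecs, "X_vecs"); Y <- as_vec_matrix(Y_vecs, "Y_vecs")
  A <- as_vec_matrix(A_vecs, "A_vecs"); B <- as_vec_matrix(B_vecs, "B_vecs")
  check_vector_sets(list(X_vecs = X, Y_vecs = Y, A_vecs = A, B_vecs = B))
  nX <- nrow(X)
  s <- association_profile(rbind(X, Y), A, B)
  n <- length(s)
  if (n %% 2L != 0L) {
    stop("p-value requires an even pooled target count (equal-size partitions)",
         call. = FALSE)
  }
  if (nX != nrow(Y)) {
    warning("unequal target-set sizes; partitions still split the union into equal halves",
            call. = FALSE)
  }
  half <- n %/% 2L
  total <- sum(s)
  # same floating-point expression as the partition statistics below, so the
  # observed partition ties with itself exactly
  obs <- 2 * sum(s[seq_len(nX)]) - total
  n_part <- choose(n, half)
  if (mode == "auto") {
    mode <- if (n_part <= max_exact) "exact" else "monte_carlo"
  }
  if (mode == "exact") {
    if (n_part > max_exact) {
      stop(sprintf("exact enumeration of %.0f partitions exceeds max_exact = %d",
                   n_part, max_exact), call. = FALSE)
    }
    subsets <- utils::combn(n, half)
    stats_i <- 2 * colSums(matrix(s[subsets], nrow = half)) - total
    count <- ncol(subsets)
  } else {
    stats_i <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_draws),
             function(i) 2 * sum(s[sample.int(n, half)]) - total, numeric(1))
    })
    count <- n_draws
  }
  n_tie <- sum(abs(stats_i - obs) <= 1e-12)
  # in exact mode the observed partition is always enumerated and ties with
  # itself; that tie is not a pathology
  ties <- max(0L, n_tie - (mode == "exact")) / length(stats_i)
  if (ties > 0.01) {
    warning(sprintf("degenerate partition distribution: %.1f%% of partition statistics tie with the observed value",
                    100 * ties), call. = FALSE)
  }
  list(p = mean(stats_i > obs), method = mode, n = count)
}

#' Run one WEAT on a benchmark and an embedding store
#'
#' Resolves the benchmark's four term sets against the store under the
#' out-of-vocabulary policy, then computes the effect size, test statistic
#' and permutation p-value, recording term-resolution bookkeeping.
#'
#' @param benchmark A [bias_benchmark].
#' @param store An [embedding_store].
#' @param oov_policy Out-of-vocabulary policy for term resolution; the
#'   default `"error"` aborts on any miss, so a single benchmark score
#'   cannot silently change meaning.
#' @param p_mode `"auto"`, `"exact"`, `"monte_carlo"`, or `"none"` to skip
#'   the p-value (used by bulk scoring where only the effect size is
#'   needed).
#' @param sd_convention Denominator convention for the effect size.
#' @inheritParams weat_p_value
#' @return An object of class `weat_result`: benchmark id, `effect_size`,
#'   `test_statistic`, `p_value`, `p_method`, `n_partitions_or_draws`,
#'   per-set resolution reports, per-set term counts actually used, and a
#'   `balanced` flag (equal resolved target sizes).
#' @examples
#' bm <- weat_benchmarks()[["WEAT-9"]]
#' store <- generate_synthetic_embeddings(synthetic_config(seed = 7), bm)
#' run_weat(bm, store)
#' @export
run_weat <- function(benchmark, store, oov_policy = "error",
                     p_mode = c("auto", "exact", "monte_carlo", "none"),
                     max_exact = 200000L, n_draws = 10000L, seed = 1L,
                     sd_convention = c("population", "sample")) {
  stopifnot(inherits(benchmark, "bias_benchmark"), inherits(store, "embedding_store"))
  p_mode <- match.arg(p_mode)
  sd_convention <- match.arg(sd_convention)
  res <- lapply(c(target_x = "target_x", target_y = "target_y",
                  attribute_a = "attribute_a", attribute_b = "attribute_b"),
                function(slot) resolve_terms(store, benchmark[[slot]]$terms, oov_policy))
  X <- res$target_x$vectors; Y <- res$target_y$vectors
  A <- res$attribute_a$vectors; B <- res$attribute_b$vectors
  d <- weat_effect_size(X, Y, A, B, sd_convention = sd_convention)
  stat <- weat_statistic(X, Y, A, B)
  if (p_mode == "none") {
    pv <- list(p = NA_real_, method = "none", n = 0L)
  } else {
    pv <- weat_p_value(X, Y, A, B, mode = p_mode, max_exact = max_exact,
                       n_draws = n_draws, seed = seed)
  }
  structure(list(
    benchmark_id = benchmark$id,
    effect_size = d,
    test_statistic = stat,
    p_value = pv$p,
    p_method = pv$method,
    n_partitions_or_draws = pv$n,
    n_used = vapply(res, function(r) nrow(r$vectors), 1L),
    balanced = nrow(X) == nrow(Y),
    sd_convention = sd_convention,
    resolution = lapply(res, `[[`, "report")),
    class = "weat_result")
}

#' @export
print.weat_result <- function(x, ...) {
  cat(sprintf("<weat_result> %s\n", x$benchmark_id))
  cat(sprintf("  effect size d = %.4f, statistic = %.4f\n",
              x$effect_size, x$test_statistic))
  if (x$p_method != "none") {
    cat(sprintf("  p = %.4g (%s over %d partitions/draws)\n",
                x$p_value, x$p_method, x$n_partitions_or_draws))
  }
  if (!x$balanced) cat("  note: unequal resolved target-set sizes\n")
  invisible(x)
}
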