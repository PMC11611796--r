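#' Pool a benchmark's attribute sets
#'
#' Concatenates the two attribute term lists (A then B), dropping
#' duplicates while preserving order. The pooled list is the urn from
#' which the resampled attribute subsets are drawn: pooling discards the
#' predefined A/B grouping, which is exactly what makes the resampling
#' score free of the original segregation.
#'
#' @param benchmark A [bias_benchmark].
#' @return Character vector of pooled attribute terms.
#' @export
pool_attributes <- function(benchmark) {
  stopifnot(inherits(benchmark, "bias_benchmark"))
  unique(c(benchmark$attribute_a$terms, benchmark$attribute_b$terms))
}

#' Resample attribute-set pairs from a pooled term list
#'
#' Constructs `K` new tests. Each test draws `2 * m` distinct terms
#' uniformly without replacement from the pool; the first `m` become the
#' new attribute set A', the last `m` the new B'. Tests are independent
#' draws, so repeats across tests are possible (and unavoidable when the
#' pool is small). Reproducible under `seed`.
#'
#' @param pool Character vector of candidate terms (at least `2 * m`).
#' @param m Attribute-set size per side (default 2, the minimum that
#'   defines an effect size).
#' @param K Number of resampled tests (default 100).
#' @param seed Integer seed.
#' @return A list of `K` elements, each `list(a = <m terms>, b = <m terms>)`.
#' @export
resample_attribute_sets <- function(pool, m = 2L, K = 100L, seed = 1L) {
  pool <- as.character(pool)
  m <- as.integer(m); K <- as.integer(K)
  stopifnot(m >= 1L, K >= 1L)
  if (length(pool) < 2L * m) {
    stop(sprintf("attribute pool has %d terms; need at least 2*m = %d",
                 length(pool), 2L * m), call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(K), function(k) {
      draw <- sample(pool, size = 2L * m, replace = FALSE)
      list(a = draw[seq_len(m)], b = draw[m + seq_len(m)])
    })
  })
}

resolve_sdweat_inputs <- function(benchmark, store, m, oov_policy) {
  rx <- resolve_terms(store, benchmark$target_x$terms, oov_policy)
  ry <- resolve_terms(store, benchmark$target_y$terms, oov_policy)
  pool_terms <- pool_attributes(benchmark)
  rp <- resolve_terms(store, pool_terms, oov_policy)
  dropped <- length(rp$report$missing)
  if (dropped / length(pool_terms) > 0.2) {
    stop(sprintf("benchmark '%s': %d of %d pooled attribute terms unresolved (> 20%%)",
                 benchmark$id, dropped, length(pool_terms)), call. = FALSE)
  }
  if (nrow(rp$vectors) < 2L * m) {
    stop(sprintf("benchmark '%s': resolved attribute pool has %d terms; need 2*m = %d",
                 benchmark$id, nrow(rp$vectors), 2L * m), call. = FALSE)
  }
  list(X = rx$vectors, Y = ry$vectors, pool = rp$vectors,
       reports = list(target_x = rx$report, target_y = ry$report,
                      pool = rp$report))
}

resampled_effect_sizes <- function(X, Y, pool_vecs, tests, sd_convention) {
  # Associations decompose over single attribute terms: s(w, A', B') =
  # mean cosine to A' minus mean cosine to B', so precompute the target x
  # pool cosine matrix once and average columns per test.
  W <- rbind(X, Y)
  cosWP <- cosine_matrix(W, pool_vecs)
  colnames(cosWP) <- rownames(pool_vecs)
  nX <- nrow(X)
  vapply(tests, function(tst) {
    s <- rowMeans(cosWP[, tst$a, drop = FALSE]) -
      rowMeans(cosWP[, tst$b, drop = FALSE])
    effect_size_impl(s[seq_len(nX)], s[-seq_len(nX)], sd_convention)
  }, numeric(1))
}

#' SD-WEAT: resampling-based bias score
#'
#' Scores bias on one benchmark as the standard deviation of WEAT effect
#' sizes over `K` resampled tests. Each test keeps the benchmark's
#' original target sets but replaces the attribute sets with a fresh
#' random pair drawn from the pooled attribute list
#' ([pool_attributes()], [resample_attribute_sets()]). Under an unbiased
#' store the resampled effect sizes scatter symmetrically around zero and
#' their mean is expected to be close to zero; planted or learned bias
#' polarizes the pooled attribute terms, so random bipartitions of them
#' produce widely dispersed effect sizes and a large SD. Supplying a
#' negative-control calibration attaches a z-score and right-tailed
#' p-value (see [negative_control()] and [sdweat_significance()]).
#'
#' @param benchmark A [bias_benchmark].
#' @param store An [embedding_store].
#' @param m Resampled attribute-set size per side (default 2).
#' @param K Number of resampled tests (default 100).
#' @param seed Integer seed for the resampling.
#' @param calibration Optional `null_calibration` from
#'   [negative_control()].
#' @param oov_policy Out-of-vocabulary policy (default
#'   `"lowercase_fallback"`: resampling tolerates missing pool words, so
#'   misses are lowercased then dropped with a warning; more than 20%
#'   unresolved pooled terms is an error).
#' @param score_sd_convention SD convention for the score itself
#'   (default `"sample"`, n - 1: the score is a dispersion estimate over
#'   sampled replicate tests).
#' @param effect_sd_convention SD convention inside each effect size
#'   (default `"population"`).
#' @return An object of class `sdweat_result`: `sd_score`, the `K`
#'   `effect_sizes`, `mean_effect`, the resampled `tests`, `m`, `K`,
#'   `seed`, conventions, resolution reports, and — when calibrated —
#'   `z` and `p_right`.
#' @examples
#' bm <- weat_benchmarks()[["WEAT-9"]]
#' store <- generate_synthetic_embeddings(synthetic_config(seed = 7), bm)
#' sd_weat(bm, store, seed = 1)
#' @export
sd_weat <- function(benchmark, store, m = 2L, K = 100L, seed = 1L,
                    calibration = NULL,
                    oov_policy = "lowercase_fallback",
                    score_sd_convention = c("sample", "population"),
                    effect_sd_convention = c("population", "sample")) {
  stopifnot(inherits(benchmark, "bias_benchmark"), inherits(store, "embedding_store"))
  score_sd_convention <- match.arg(score_sd_convention)
  effect_sd_convention <- match.arg(effect_sd_convention)
  m <- as.integer(m); K <- as.integer(K)
  if (K < 2L) stop("sd_weat: K must be at least 2", call. = FALSE)
  inp <- resolve_sdweat_inputs(benchmark, store, m, oov_policy)
  tests <- resample_attribute_sets(rownames(inp$pool), m = m, K = K, seed = seed)
  d <- resampled_effect_sizes(inp$X, inp$Y, inp$pool, tests, effect_sd_convention)
  out <- structure(list(
    benchmark_id = benchmark$id,
    sd_score = apply_sd(d, score_sd_convention),
    effect_sizes = d,
    mean_effect = mean(d),
    tests = tests,
    m = m, K = K, seed = as.integer(seed),
    score_sd_convention = score_sd_convention,
    effect_sd_convention = effect_sd_convention,
    resolution = inp$reports,
    z = NA_real_, p_right = NA_real_),
    class = "sdweat_result")
  if (!is.null(calibration)) {
    sig <- sdweat_significance(out$sd_score, calibration)
    out$z <- sig$z
    out$p_right <- sig$p_right
  }
  out
}

#' @export
print.sdweat_result <- function(x, ...) {
  cat(sprintf("<sdweat_result> %s: sd_score = %.4f (m = %d, K = %d, seed = %d)\n",
              x$benchmark_id, x$sd_score, x$m, x$K, x$seed))
  cat(sprintf("  mean resampled effect = %.4f\n", x$mean_effect))
  if (!is.na(x$z)) {
    cat(sprintf("  calibrated z = %.3f, right-tailed p = %.4g\n", x$z, x$p_right))
  }
  invisible(x)
}

#' Negative control: random-vocabulary calibration of the SD-WEAT
#'
#' Builds the null reference distribution for the SD-WEAT score. Keeping
#' the benchmark's target sets, `n_tests` resampled tests are constructed
#' whose attribute sets are drawn from general vocabulary (`vocab`) rather
#' than the benchmark's pooled attributes. The resulting effect sizes are
#' split, in draw order, into `G = n_tests / group_size` groups; the SD of
#' each group gives the control distribution of SD scores, summarized by
#' its mean `mu` and SD `sigma`. Defaults mirror the reference design:
#' 10000 tests in 100 groups of 100.
#'
#' @param benchmark A [bias_benchmark] (only its targets are used).
#' @param store An [embedding_store].
#' @param vocab Character vector of general-vocabulary candidate terms.
#'   `NULL` draws `vocab_size` terms via [sample_vocabulary()].
#' @param m Attribute-set size per side (default 2).
#' @param n_tests Total control tests (default 10000); must be divisible
#'   by `group_size`.
#' @param group_size Tests per group (default 100).
#' @param seed Integer seed.
#' @param vocab_size Pool size when `vocab` is `NULL` (default 1000 or the
#'   filtered vocabulary size, whichever is smaller).
#' @param oov_policy Out-of-vocabulary policy for targets and vocab.
#' @param effect_sd_convention SD convention inside each effect size.
#' @return An object of class `null_calibration`: `group_sds` (length G),
#'   `mu`, `sigma`, `n_tests`, `group_size`, `vocab_source`,
#'   `target_spec`.
#' @export
negative_control <- function(benchmark, store, vocab = NULL, m = 2L,
                             n_tests = 10000L, group_size = 100L, seed = 1L,
                             vocab_size = NULL,
                             oov_policy = "lowercase_fallback",
                             effect_sd_convention = c("population", "sample")) {
  stopifnot(inherits(benchmark, "bias_benchmark"), inherits(store, "embedding_store"))
  effect_sd_convention <- match.arg(effect_sd_convention)
  m <- as.integer(m); n_tests <- as.integer(n_tests)
  group_size <- as.integer(group_size)
  if (n_tests %% group_size != 0L) {
    stop(sprintf("n_tests (%d) must be divisible by group_size (%d)",
                 n_tests, group_size), call. = FALSE)
  }
  G <- n_tests %/% group_size
  if (G < 2L) {
    stop("negative control needs at least 2 groups (sigma is undefined for G = 1)",
         call. = FALSE)
  }
  if (group_size < 2L) stop("group_size must be at least 2", call. = FALSE)
  rx <- resolve_terms(store, benchmark$target_x$terms, oov_policy)
  ry <- resolve_terms(store, benchmark$target_y$terms, oov_policy)
  if (is.null(vocab)) {
    filt <- function(t) grepl("^[A-Za-z]+$", t) & nchar(t) >= 2L
    pool_n <- sum(filt(utils::head(vocabulary(store), 50000L)))
    if (is.null(vocab_size)) vocab_size <- min(1000L, pool_n)
    vocab <- sample_vocabulary(store, vocab_size, seed = seed)
  }
  vocab <- setdiff(vocab, c(benchmark$target_x$terms, benchmark$target_y$terms))
  rv <- resolve_terms(store, vocab, "skip")
  if (nrow(rv$vectors) < 2L * m) {
    stop(sprintf("resolved control vocabulary has %d terms; need 2*m = %d",
                 nrow(rv$vectors), 2L * m), call. = FALSE)
  }
  tests <- resample_attribute_sets(rownames(rv$vectors), m = m, K = n_tests,
                                   seed = seed)
  d <- resampled_effect_sizes(rx$vectors, ry$vectors, rv$vectors, tests,
                              effect_sd_convention)
  group_sds <- apply(matrix(d, nrow = group_size, ncol = G), 2L, stats::sd)
  structure(list(
    group_sds = group_sds,
    mu = mean(group_sds),
    sigma = stats::sd(group_sds),
    n_tests = n_tests, group_size = group_size, m = m,
    seed = as.integer(seed),
    vocab_source = store$source_label,
    target_spec = benchmark$id,
    effect_sizes = d),
    class = "null_calibration")
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf(
    "<null_calibration> %s: %d tests in %d groups of %d\n  mu = %.4f, sigma = %.4f\n",
    x$target_spec, x$n_tests, length(x$group_sds), x$group_size, x$mu, x$sigma))
  invisible(x)
}

#' Significance of an SD-WEAT score against a negative control
#'
#' Standardizes the score against the control distribution of group-wise
#' SDs, `z = (sd_score - mu) / sigma`, and converts to a right-tailed
#' p-value via the standard-normal survival function. An empirical
#' alternative (`method = "empirical"`) uses the control group SDs'
#' exceedance fraction directly, for sensitivity analysis.
#'
#' @param sd_score An SD-WEAT score (or an `sdweat_result`).
#' @param calibration A `null_calibration` from [negative_control()].
#' @param method `"normal"` (default) or `"empirical"`.
#' @return A list with `z` and `p_right`.
#' @export
sdweat_significance <- function(sd_score, calibration,
                                method = c("normal", "empirical")) {
  method <- match.arg(method)
  if (inherits(sd_score, "sdweat_result")) sd_score <- sd_score$sd_score
  stopifnot(inherits(calibration, "null_calibration"), is.numeric(sd_score))
  if (!is.finite(calibration$sigma) || calibration$sigma <= 0) {
    stop("degenerate negative control: sigma must be positive", call. = FALSE)
  }
  z <- (sd_score - calibration$mu) / calibration$sigma
  p <- if (method == "normal") {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    mean(calibration$group_sds > sd_score)
  }
  list(z = z, p_right = p)
}

target_key <- function(b) {
  paste(paste(sort(b$target_x$terms), collapse = "\u1f"),
        paste(sort(b$target_y$terms), collapse = "\u1f"), sep = "\u1e")
}

#' Run the WEAT and SD-WEAT over a benchmark suite
#'
#' For each benchmark: the classic WEAT ([run_weat()]), a negative
#' control ([negative_control()]), and the calibrated SD-WEAT
#' ([sd_weat()]). Across benchmarks it reports the Pearson correlation
#' between the two methods' effect sizes (WEAT d vs SD-WEAT score) and
#' between their p-values — the agreement summaries used to compare the
#' two approaches. With fewer than two benchmarks the correlations are
#' reported absent (`NA`).
#'
#' @param benchmarks A list of [bias_benchmark]s.
#' @param store An [embedding_store].
#' @param m,K,seed SD-WEAT parameters (see [sd_weat()]).
#' @param control `TRUE` to calibrate each benchmark against a negative
#'   control.
#' @param share_controls When `TRUE`, benchmarks with identical target
#'   sets share one calibration (the control depends on the store and the
#'   targets only).
#' @param vocab,n_control_tests,group_size,vocab_size Control parameters
#'   (see [negative_control()]).
#' @param oov_policy Out-of-vocabulary policy for the SD-WEAT runs; the
#'   classic WEAT inside the suite uses the same policy.
#' @param weat_args Extra arguments passed to [run_weat()] (e.g.
#'   `p_mode`, `n_draws`).
#' @return An object of class `sdweat_suite`: a `results` data frame (one
#'   row per benchmark: WEAT d and p, SD-WEAT score, mean effect, z,
#'   right-tailed p), the per-benchmark `weat`, `sdweat` and `control`
#'   objects, and `correlations` (`effect`, `p`).
#' @export
run_sdweat_suite <- function(benchmarks, store, m = 2L, K = 100L, seed = 1L,
                             control = TRUE, share_controls = FALSE,
                             vocab = NULL, n_control_tests = 10000L,
                             group_size = 100L, vocab_size = NULL,
                             oov_policy = "lowercase_fallback",
                             weat_args = list()) {
  if (inherits(benchmarks, "bias_benchmark")) benchmarks <- list(benchmarks)
  stopifnot(length(benchmarks) >= 1L)
  ids <- vapply(benchmarks, `[[`, "", "id")
  controls <- list()
  cache <- new.env(parent = emptyenv())
  weat_res <- list(); sdweat_res <- list()
  for (i in seq_along(benchmarks)) {
    b <- benchmarks[[i]]
    weat_res[[b$id]] <- do.call(run_weat, c(
      list(benchmark = b, store = store, oov_policy = oov_policy,
           seed = seed), weat_args))
    cal <- NULL
    if (isTRUE(control)) {
      key <- if (share_controls) target_key(b) else b$id
      if (is.null(cache[[key]])) {
        cache[[key]] <- negative_control(
          b, store, vocab = vocab, m = m, n_tests = n_control_tests,
          group_size = group_size, seed = seed + i, vocab_size = vocab_size,
          oov_policy = oov_policy)
      }
      cal <- cache[[key]]
      controls[[b$id]] <- cal
    }
    sdweat_res[[b$id]] <- sd_weat(b, store, m = m, K = K, seed = seed + i,
                                  calibration = cal, oov_policy = oov_policy)
  }
  results <- data.frame(
    benchmark_id = ids,
    weat_effect = vapply(weat_res, `[[`, 0, "effect_size"),
    weat_p = vapply(weat_res, `[[`, 0, "p_value"),
    sd_score = vapply(sdweat_res, `[[`, 0, "sd_score"),
    mean_effect = vapply(sdweat_res, `[[`, 0, "mean_effect"),
    z = vapply(sdweat_res, `[[`, 0, "z"),
    p_right = vapply(sdweat_res, `[[`, 0, "p_right"),
    m = m, K = K,
    stringsAsFactors = FALSE, row.names = NULL)
  correlations <- list(effect = NA_real_, p = NA_real_)
  if (length(benchmarks) >= 2L) {
    correlations$effect <- stats::cor(results$weat_effect, results$sd_score)
    if (all(is.finite(results$weat_p)) && all(is.finite(results$p_right))) {
      correlations$p <- stats::cor(results$weat_p, results$p_right)
    }
  }
  structure(list(results = results, weat = weat_res, sdweat = sdweat_res,
                 controls = controls, correlations = correlations,
                 seed = as.integer(seed)),
            class = "sdweat_suite")
}

#' @export
print.sdweat_suite <- function(x, ...) {
  cat(sprintf("<sdweat_suite> %d benchmark(s)\n", nrow(x$results)))
  print(x$results, digits = 4)
  if (!is.na(x$correlations$effect)) {
    cat(sprintf("Pearson r (WEAT d vs SD-WEAT score): %.3f\n", x$correlations$effect))
  }
  if (!is.na(x$correlations$p)) {
    cat(sprintf("Pearson r (p-values): %.3f\n", x$correlations$p))
  }
  invisible(x)
}
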