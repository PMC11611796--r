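ex <- list(X = matrix(c(1, 0), 1), Y = matrix(c(0, 1), 1),
           A = matrix(c(1, 0), 1), B = matrix(c(0, 1), 1))

test_that("association matches hand-computed values", {
  expect_equal(weat_association(c(1, 0), ex$A, ex$B), 1)       # cos 1 - cos 0
  expect_equal(weat_association(c(1, 1), ex$A, ex$B), 0)       # equal cosines
  expect_equal(weat_association(c(3, 7), ex$A, ex$A), 0)       # A = B
  m <- rbind(c(1, 2), c(2, 1))
  expect_equal(weat_association(c(5, -1), m, m), 0)
  expect_error(weat_association(c(1, 0, 0), ex$A, ex$B), "dimension")
  expect_error(weat_association(c(0, 0), ex$A, ex$B), "zero vector")
})

test_that("effect size and statistic match the extremal hand case", {
  # s values are {1, -1}: mean difference 2, population SD 1 -> d = 2
  expect_equal(weat_effect_size(ex$X, ex$Y, ex$A, ex$B), 2)
  expect_equal(weat_statistic(ex$X, ex$Y, ex$A, ex$B), 2)
  # identical target sets give zero effect and statistic
  expect_equal(weat_effect_size(ex$X, ex$X, ex$A, ex$B), 0)
  expect_equal(weat_statistic(ex$X, ex$X, ex$A, ex$B), 0)
  # scaling every vector by 7 changes nothing
  expect_equal(weat_effect_size(7 * ex$X, 7 * ex$Y, 7 * ex$A, 7 * ex$B), 2)
  # duplicating both target sets doubles the statistic, not the effect size
  X2 <- rbind(ex$X, ex$X); Y2 <- rbind(ex$Y, ex$Y)
  expect_equal(weat_statistic(X2, Y2, ex$A, ex$B), 4)
  expect_equal(weat_effect_size(X2, Y2, ex$A, ex$B), 2)
})

test_that("exact p-value agrees with brute-force partition enumeration", {
  # maximally separated toy: no partition beats the observed statistic, and
  # the observed partition's inherent self-tie raises no warning
  X2 <- rbind(ex$X, ex$X); Y2 <- rbind(ex$Y, ex$Y)
  expect_no_warning(pv <- weat_p_value(X2, Y2, ex$A, ex$B, mode = "exact"))
  expect_equal(pv$p, 0)
  expect_equal(pv$method, "exact")
  expect_equal(pv$n, choose(4, 2))

  # random instances against the independent oracle
  for (s in 1:5) {
    sets <- withr::with_seed(s, list(
      X = matrix(stats::rnorm(3 * 5), 3), Y = matrix(stats::rnorm(3 * 5), 3),
      A = matrix(stats::rnorm(4 * 5), 4), B = matrix(stats::rnorm(4 * 5), 4)))
    pv <- weat_p_value(sets$X, sets$Y, sets$A, sets$B, mode = "exact")
    expect_equal(pv$p, oracle_exact_p(sets$X, sets$Y, sets$A, sets$B))
  }
})

test_that("all-identical targets yield a degenerate tie warning and p = 0", {
  X <- matrix(rep(c(1, 2), each = 2), 2, byrow = FALSE)
  X <- rbind(c(1, 2), c(1, 2)); Y <- rbind(c(1, 2), c(1, 2))
  expect_warning(pv <- weat_p_value(X, Y, ex$A, ex$B, mode = "exact"),
                 "degenerate")
  expect_equal(pv$p, 0)
})

test_that("monte-carlo p converges to the exact value", {
  sets <- withr::with_seed(7, list(
    X = matrix(stats::rnorm(3 * 6), 3), Y = matrix(stats::rnorm(3 * 6), 3),
    A = matrix(stats::rnorm(3 * 6), 3), B = matrix(stats::rnorm(3 * 6), 3)))
  p_ex <- weat_p_value(sets$X, sets$Y, sets$A, sets$B, mode = "exact")$p
  # on so small an instance Monte-Carlo redraws the observed subset itself,
  # which legitimately triggers the tie diagnostic
  p_mc <- suppressWarnings(
    weat_p_value(sets$X, sets$Y, sets$A, sets$B, mode = "monte_carlo",
                 n_draws = 5000, seed = 11)$p)
  expect_lt(abs(p_mc - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / 5000) + 1e-9)
})

test_that("auto mode switches on the partition-count threshold", {
  sets <- withr::with_seed(3, list(
    X = matrix(stats::rnorm(4 * 5), 4), Y = matrix(stats::rnorm(4 * 5), 4),
    A = matrix(stats::rnorm(3 * 5), 3), B = matrix(stats::rnorm(3 * 5), 3)))
  expect_equal(weat_p_value(sets$X, sets$Y, sets$A, sets$B)$method, "exact")
  pv <- suppressWarnings(weat_p_value(sets$X, sets$Y, sets$A, sets$B,
                                      max_exact = 10, n_draws = 200, seed = 1))
  expect_equal(pv$method, "monte_carlo")
  expect_equal(pv$n, 200)
})

test_that("odd pooled target counts are rejected; unequal sizes warn", {
  X <- matrix(stats::rnorm(3 * 4), 3); Y <- matrix(stats::rnorm(2 * 4), 2)
  expect_error(weat_p_value(X, Y, ex$A %x% t(c(1, 1)), ex$B %x% t(c(1, 1))),
               "even")
  Y4 <- matrix(stats::rnorm(1 * 4), 1)
  A <- matrix(stats::rnorm(2 * 4), 2); B <- matrix(stats::rnorm(2 * 4), 2)
  expect_warning(weat_p_value(X, Y4, A, B, mode = "exact"), "unequal")
})

test_that("antisymmetry holds exactly under A/B and X/Y swaps", {
  for (s in 1:25) {
    sets <- withr::with_seed(100 + s, {
      n <- sample(2:5, 1)
      list(X = matrix(stats::rnorm(n * 7), n), Y = matrix(stats::rnorm(n * 7), n),
           A = matrix(stats::rnorm(3 * 7), 3), B = matrix(stats::rnorm(3 * 7), 3),
           w = stats::rnorm(7))
    })
    expect_identical(weat_association(sets$w, sets$B, sets$A),
                     -weat_association(sets$w, sets$A, sets$B))
    expect_identical(weat_effect_size(sets$X, sets$Y, sets$B, sets$A),
                     -weat_effect_size(sets$X, sets$Y, sets$A, sets$B))
    expect_identical(weat_statistic(sets$X, sets$Y, sets$B, sets$A),
                     -weat_statistic(sets$X, sets$Y, sets$A, sets$B))
    expect_identical(weat_effect_size(sets$Y, sets$X, sets$A, sets$B),
                     -weat_effect_size(sets$X, sets$Y, sets$A, sets$B))
  }
})

test_that("effect size is bounded by 2 for equal target sizes", {
  for (s in 1:300) {
    sets <- withr::with_seed(500 + s, {
      n <- sample(2:5, 1)
      list(X = matrix(stats::rnorm(n * 5), n), Y = matrix(stats::rnorm(n * 5), n),
           A = matrix(stats::rnorm(2 * 5), 2), B = matrix(stats::rnorm(2 * 5), 2))
    })
    d <- weat_effect_size(sets$X, sets$Y, sets$A, sets$B)
    expect_lte(abs(d), 2 + 1e-9)
  }
})

test_that("associations lie in [-2, 2]", {
  for (s in 1:50) {
    sets <- withr::with_seed(900 + s, list(
      w = stats::rnorm(6), A = matrix(stats::rnorm(4 * 6), 4),
      B = matrix(stats::rnorm(4 * 6), 4)))
    a <- weat_association(sets$w, sets$A, sets$B)
    expect_lte(abs(a), 2)
  }
})

test_that("run_weat assembles results with resolution bookkeeping", {
  b <- tiny_benchmark()
  st <- store_for(b, beta = 2, seed = 8, dim = 16)
  r <- run_weat(b, st, p_mode = "exact")
  expect_s3_class(r, "weat_result")
  expect_equal(r$benchmark_id, b$id)
  expect_equal(r$p_method, "exact")
  expect_equal(r$n_partitions_or_draws, choose(8, 4))
  expect_true(r$balanced)
  expect_equal(unname(r$n_used), c(4L, 4L, 4L, 4L))
  expect_equal(r$resolution$target_x$resolved$kind, rep("exact", 4))
  expect_gt(r$effect_size, 0)  # planted positive bias
  # missing terms abort under the default error policy
  b2 <- tiny_benchmark()
  b2$target_x$terms[1] <- "never-seen"
  expect_error(run_weat(b2, st), "never|seen")
})
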