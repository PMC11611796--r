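test_that("attribute pooling preserves order and drops duplicates", {
  b <- bias_benchmark("p", "",
                      term_set("X", "x1"), term_set("Y", "y1"),
                      term_set("A", c("male", "man", "boy")),
                      term_set("B", c("female", "woman", "girl")))
  expect_identical(pool_attributes(b),
                   c("male", "man", "boy", "female", "woman", "girl"))
  expect_length(pool_attributes(tiny_benchmark(na = 8)), 16L)
})

test_that("resampled attribute sets are disjoint 2m-term draws", {
  pool <- paste0("t", 1:10)
  tests <- resample_attribute_sets(pool, m = 2, K = 100, seed = 5)
  expect_length(tests, 100L)
  for (t in tests) {
    expect_length(t$a, 2L)
    expect_length(t$b, 2L)
    expect_length(unique(c(t$a, t$b)), 4L)   # pairwise distinct terms
    expect_true(all(c(t$a, t$b) %in% pool))
  }
  expect_identical(tests, resample_attribute_sets(pool, m = 2, K = 100, seed = 5))
  expect_error(resample_attribute_sets(pool[1:3], m = 2), "pool has 3")
})

test_that("a 2m-term pool forces every test to use all terms", {
  tests <- resample_attribute_sets(letters[1:4], m = 2, K = 50, seed = 2)
  for (t in tests) expect_setequal(c(t$a, t$b), letters[1:4])
  # only the assignment into A'/B' varies
  keys <- vapply(tests, function(t) paste(sort(t$a), collapse = ","), "")
  expect_gt(length(unique(keys)), 1L)
})

test_that("resampling is uniform over its support", {
  # m=1 on a 4-term pool: 12 ordered (a, b) pairs, each with probability 1/12
  pool <- letters[1:4]
  tests <- resample_attribute_sets(pool, m = 1, K = 6000, seed = 9)
  keys <- vapply(tests, function(t) paste(t$a, t$b), "")
  counts <- table(keys)
  expect_length(counts, 12L)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("sd_weat computes the SD of resampled effect sizes", {
  b <- tiny_benchmark(na = 6)
  st <- store_for(b, beta = 1, seed = 21, dim = 20)
  r <- sd_weat(b, st, m = 2, K = 60, seed = 13)
  expect_s3_class(r, "sdweat_result")
  expect_length(r$effect_sizes, 60L)
  expect_equal(r$sd_score, stats::sd(r$effect_sizes))
  expect_equal(r$mean_effect, mean(r$effect_sizes))
  expect_gte(r$sd_score, 0)
  expect_lte(r$sd_score, 2)
  expect_identical(r, sd_weat(b, st, m = 2, K = 60, seed = 13))  # determinism
  r2 <- sd_weat(b, st, m = 2, K = 60, seed = 13,
                score_sd_convention = "population")
  expect_equal(r2$sd_score, sqrt(mean((r$effect_sizes - mean(r$effect_sizes))^2)))
})

test_that("identical attribute vectors collapse every effect size to zero", {
  b <- tiny_benchmark(na = 4)
  st <- store_for(b, beta = 0, seed = 2, dim = 8)
  v <- st$vectors
  shared <- v[b$attribute_a$terms[1], ]
  for (t in c(b$attribute_a$terms, b$attribute_b$terms)) v[t, ] <- shared
  st2 <- embedding_store(v, "degenerate")
  r <- sd_weat(b, st2, K = 30, seed = 4)
  expect_equal(r$effect_sizes, rep(0, 30))
  expect_equal(r$sd_score, 0)
})

test_that("relabeling resampled halves negates effects but keeps the score", {
  b <- tiny_benchmark(na = 6)
  st <- store_for(b, beta = 1, seed = 31, dim = 20)
  r <- sd_weat(b, st, m = 2, K = 40, seed = 17)
  swapped <- lapply(r$tests, function(t) list(a = t$b, b = t$a))
  inp <- sdweat:::resolve_sdweat_inputs(b, st, 2L, "lowercase_fallback")
  d_swapped <- sdweat:::resampled_effect_sizes(inp$X, inp$Y, inp$pool, swapped,
                                               "population")
  expect_equal(d_swapped, -r$effect_sizes, tolerance = 1e-12)
  expect_equal(stats::sd(d_swapped), r$sd_score, tolerance = 1e-12)
})

test_that("negative control groups effect sizes in draw order", {
  b <- tiny_benchmark()
  st <- store_for(b, beta = 0, seed = 12, dim = 16, n_filler = 60)
  cal <- negative_control(b, st, n_tests = 200, group_size = 20, seed = 6)
  expect_s3_class(cal, "null_calibration")
  expect_length(cal$group_sds, 10L)
  expect_equal(cal$mu, mean(cal$group_sds))
  expect_equal(cal$sigma, stats::sd(cal$group_sds))
  expect_equal(cal$group_sds[1], stats::sd(cal$effect_sizes[1:20]))
  expect_gt(cal$sigma, 0)
  # degenerate and invalid group structures are rejected
  expect_error(negative_control(b, st, n_tests = 100, group_size = 100),
               "at least 2 groups")
  expect_error(negative_control(b, st, n_tests = 150, group_size = 100),
               "divisible")
})

test_that("control mu is stable under doubled noise scale", {
  b <- tiny_benchmark()
  mus <- vapply(c(1, 2), function(ns) {
    st <- generate_synthetic_embeddings(
      synthetic_config(dimension = 16, bias_strength = 0, noise_scale = ns,
                       seed = 44), b, n_filler = 80)
    negative_control(b, st, n_tests = 400, group_size = 40, seed = 8)$mu
  }, 0)
  # cosine statistics are scale-free, so the null dispersion barely moves
  expect_lt(abs(mus[1] - mus[2]) / mus[1], 0.25)
})

test_that("significance is the right-tailed normal tail of the z-score", {
  cal <- structure(list(group_sds = c(0.8, 1.0, 1.2), mu = 1, sigma = 0.1),
                   class = "null_calibration")
  s <- sdweat_significance(1, cal)
  expect_equal(s$z, 0)
  expect_equal(s$p_right, 0.5)
  s <- sdweat_significance(1.1, cal)
  expect_equal(s$z, 1)
  expect_equal(s$p_right, stats::pnorm(1, lower.tail = FALSE))
  expect_equal(sdweat_significance(1.3, cal)$p_right,
               stats::pnorm(3, lower.tail = FALSE))
  emp <- sdweat_significance(1.1, cal, method = "empirical")
  expect_equal(emp$p_right, 1 / 3)
  cal$sigma <- 0
  expect_error(sdweat_significance(1, cal), "degenerate")
})

test_that("suite reports per-benchmark results and cross-method correlations", {
  bms <- lapply(1:4, function(i)
    tiny_benchmark(sprintf("TB-%d", i), na = 5, prefix = paste0("q", i)))
  # one shared store covering all four benchmarks (same term prefixes)
  st <- generate_synthetic_embeddings(synthetic_config(seed = 55, dimension = 20),
                                      bms, n_filler = 80)
  suite <- run_sdweat_suite(bms, st, K = 40, seed = 3,
                            n_control_tests = 200, group_size = 20,
                            weat_args = list(p_mode = "exact"))
  expect_equal(nrow(suite$results), 4L)
  expect_true(all(is.finite(suite$results$sd_score)))
  expect_true(all(is.finite(suite$results$z)))
  expect_true(all(suite$results$p_right >= 0 & suite$results$p_right <= 1))
  expect_true(is.finite(suite$correlations$effect))
  # a single benchmark leaves the correlation absent
  single <- run_sdweat_suite(bms[[1]], st, K = 20, seed = 3,
                             n_control_tests = 100, group_size = 10,
                             weat_args = list(p_mode = "none"))
  expect_true(is.na(single$correlations$effect))
})

test_that("controls can be shared across benchmarks with identical targets", {
  b1 <- tiny_benchmark("S-1", na = 5)
  b2 <- b1; b2$id <- "S-2"
  b2$attribute_a <- term_set("ta2", paste0("c", letters[1:5]))
  b2$attribute_b <- term_set("tb2", paste0("d", letters[1:5]))
  st <- generate_synthetic_embeddings(synthetic_config(seed = 60, dimension = 16),
                                      list(b1, b2), n_filler = 60)
  suite <- run_sdweat_suite(list(b1, b2), st, K = 20, seed = 2,
                            share_controls = TRUE,
                            n_control_tests = 100, group_size = 10,
                            weat_args = list(p_mode = "none"))
  expect_identical(suite$controls[["S-1"]]$group_sds,
                   suite$controls[["S-2"]]$group_sds)
})
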