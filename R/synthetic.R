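#' Configuration for the synthetic planted-bias generator
#'
#' The generator emulates the situation the bias statistics are built for:
#' unit-norm word vectors in which the benchmark's term groups load on a
#' single shared latent "bias direction" with controllable strength, plus
#' isotropic Gaussian noise. Each term's raw vector is
#' `pole(term) * bias_strength * u + noise`, subsequently normalized to
#' unit length, where `u` is a fixed unit axis and the noise components
#' are i.i.d. `N(0, noise_scale^2)`. Poles default to +1 for the first
#' target and attribute sets, -1 for the second ones, so positive
#' `bias_strength` plants a positive-effect-size bias; `bias_strength = 0`
#' makes all groups exchangeable (the null model).
#'
#' @param dimension Vector dimension (default 50).
#' @param bias_strength Non-negative loading on the shared bias axis
#'   (default 1, which yields mid-scale effect sizes under the default
#'   noise).
#' @param noise_scale Positive standard deviation of the isotropic noise
#'   components (default 1).
#' @param seed Integer seed; the generator is fully deterministic given
#'   the configuration.
#' @param poles Named numeric vector giving the pole of each benchmark
#'   slot among `target_x`, `target_y`, `attribute_a`, `attribute_b`
#'   (+1, -1 or 0 for neutral).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(dimension = 50L, bias_strength = 1,
                             noise_scale = 1, seed = 1L,
                             poles = c(target_x = 1, target_y = -1,
                                       attribute_a = 1, attribute_b = -1)) {
  stopifnot(dimension >= 2L, bias_strength >= 0, noise_scale > 0)
  slots <- c("target_x", "target_y", "attribute_a", "attribute_b")
  if (!all(slots %in% names(poles))) {
    stop("synthetic_config: poles must name all four benchmark slots", call. = FALSE)
  }
  structure(list(dimension = as.integer(dimension),
                 bias_strength = bias_strength,
                 noise_scale = noise_scale,
                 seed = as.integer(seed),
                 poles = poles[slots]),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> dim %d, bias_strength %.3g, noise_scale %.3g, seed %d\n",
    x$dimension, x$bias_strength, x$noise_scale, x$seed))
  invisible(x)
}

filler_names <- function(n) {
  if (n == 0L) return(character(0))
  # purely alphabetic names so they pass the negative-control vocab filter
  width <- max(3L, ceiling(log(n + 1, 26)))
  idx <- seq_len(n) - 1L
  chars <- matrix("", nrow = n, ncol = width)
  for (j in seq_len(width)) {
    chars[, width - j + 1L] <- letters[(idx %% 26L) + 1L]
    idx <- idx %/% 26L
  }
  paste0("filler", apply(chars, 1L, paste, collapse = ""))
}

unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("degenerate zero vector in synthetic generator", call. = FALSE)
  m / nrm
}

#' Generate a synthetic planted-bias embedding store
#'
#' Builds vectors for every term of one or more benchmarks according to a
#' [synthetic_config()], plus optional neutral "filler" terms that stand in
#' for general vocabulary (used by the negative control). When several
#' benchmarks are supplied, a term keeps the pole of its first assignment.
#' Identical configuration and benchmark input yield byte-identical stores.
#'
#' @param cfg A [synthetic_config()].
#' @param benchmarks A [bias_benchmark] or list of them.
#' @param n_filler Number of pure-noise filler terms to add (default 0).
#' @return An [embedding_store] of unit-norm vectors.
#' @export
generate_synthetic_embeddings <- function(cfg, benchmarks, n_filler = 0L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (inherits(benchmarks, "bias_benchmark")) benchmarks <- list(benchmarks)
  slots <- c("target_x", "target_y", "attribute_a", "attribute_b")
  terms <- character(0)
  poles <- numeric(0)
  for (b in benchmarks) {
    for (slot in slots) {
      for (t in b[[slot]]$terms) {
        if (!t %in% terms) {
          terms <- c(terms, t)
          poles <- c(poles, cfg$poles[[slot]])
        }
      }
    }
  }
  fillers <- filler_names(n_filler)
  terms <- c(terms, fillers)
  poles <- c(poles, rep(0, n_filler))
  d <- cfg$dimension
  u <- c(1, rep(0, d - 1L))  # fixed unit bias axis
  m <- withr::with_seed(cfg$seed, {
    noise <- matrix(stats::rnorm(length(terms) * d, sd = cfg$noise_scale),
                    nrow = length(terms), ncol = d)
    noise + outer(poles * cfg$bias_strength, u)
  })
  rownames(m) <- terms
  embedding_store(unit_rows(m),
                  source_label = sprintf("synthetic(beta=%g,noise=%g,seed=%d)",
                                         cfg$bias_strength, cfg$noise_scale, cfg$seed))
}

#' Generate replicate synthetic stores
#'
#' Produces `n_replicates` stores that share a configuration (hence the
#' same structural planted bias) but use seeds `base_seed + 1 ...
#' base_seed + n_replicates`, giving independent noise. This mirrors the
#' design of training several embedding models identically except for the
#' random seed, the input to the stability analysis.
#'
#' @param cfg A [synthetic_config()]; its own `seed` is overridden.
#' @param benchmarks A [bias_benchmark] or list of them.
#' @param n_replicates Number of replicate stores (>= 2).
#' @param base_seed Integer base seed.
#' @param n_filler Filler terms per store.
#' @return A list of [embedding_store]s.
#' @export
generate_replicate_stores <- function(cfg, benchmarks, n_replicates = 9L,
                                      base_seed = 0L, n_filler = 0L) {
  stopifnot(n_replicates >= 2L)
  lapply(seq_len(n_replicates), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(base_seed + i)
    generate_synthetic_embeddings(cfg_i, benchmarks, n_filler = n_filler)
  })
}
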