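#' Score replicate embedding stores on a benchmark suite
#'
#' Evaluates every replicate store of one embedding method on every
#' benchmark with either the classic WEAT effect size or the SD-WEAT
#' score, producing the replicate-by-benchmark score panel that the
#' stability analysis summarizes. For the SD-WEAT, each replicate by
#' default gets its own resampling seed (`base_seed + replicate`), so the
#' panel's spread reflects model variability plus resampling noise;
#' `freeze_resampling = TRUE` reuses one seed across replicates to
#' isolate model variability.
#'
#' @param stores List of at least two [embedding_store]s (replicates of
#'   one method).
#' @param benchmarks List of [bias_benchmark]s.
#' @param metric `"weat"` (effect size) or `"sdweat"` (SD score).
#' @param method_label Label for the embedding method.
#' @param m,K SD-WEAT parameters.
#' @param base_seed Base seed for per-replicate resampling seeds.
#' @param freeze_resampling Use the same resampling seed for every
#'   replicate (SD-WEAT only).
#' @param oov_policy Out-of-vocabulary policy.
#' @return An object of class `score_panel`: a long data frame
#'   (`benchmark_id`, `replicate`, `score`, `seed`) with attributes
#'   `method_label` and `metric`. A store failing resolution on a
#'   benchmark leaves that cell `NA`; more than 20% missing cells is an
#'   error.
#' @export
score_replicates <- function(stores, benchmarks,
                             metric = c("weat", "sdweat"),
                             method_label = "method",
                             m = 2L, K = 100L, base_seed = 1L,
                             freeze_resampling = FALSE,
                             oov_policy = "lowercase_fallback") {
  metric <- match.arg(metric)
  if (inherits(benchmarks, "bias_benchmark")) benchmarks <- list(benchmarks)
  stopifnot(length(stores) >= 2L, length(benchmarks) >= 1L)
  rows <- list()
  for (r in seq_along(stores)) {
    sd_seed <- if (freeze_resampling) as.integer(base_seed) else as.integer(base_seed + r)
    for (b in benchmarks) {
      score <- tryCatch({
        if (metric == "weat") {
          run_weat(b, stores[[r]], oov_policy = oov_policy,
                   p_mode = "none")$effect_size
        } else {
          sd_weat(b, stores[[r]], m = m, K = K, seed = sd_seed,
                  oov_policy = oov_policy)$sd_score
        }
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        benchmark_id = b$id, replicate = r, score = score, seed = sd_seed,
        stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows)
  if (mean(is.na(panel$score)) > 0.2) {
    stop(sprintf("score_replicates: %.0f%% of panel cells failed resolution",
                 100 * mean(is.na(panel$score))), call. = FALSE)
  }
  structure(panel, method_label = method_label, metric = metric,
            class = c("score_panel", "data.frame"))
}

panel_meta <- function(panel) {
  list(method = attr(panel, "method_label"), metric = attr(panel, "metric"))
}

#' Summarize embedding-method stability from score panels
#'
#' For each (method, metric, benchmark) the spread of the replicate
#' scores is summarized by min, max and SD of the signed scores (sign
#' flips across replicates are themselves instability). Per method and
#' metric, the mean of the per-benchmark SDs is the stability figure of
#' merit; since SD measures variation, lower values mean more stable.
#' Methods are ranked by it. Where a method supplies both a WEAT and an
#' SD-WEAT panel, the paired per-benchmark comparison of the two spreads
#' is also emitted.
#'
#' @param panels A `score_panel` or list of them; panels must share the
#'   same benchmark set.
#' @return An object of class `stability_report` with elements
#'   `per_benchmark` (method, metric, benchmark_id, n, min, max, sd),
#'   `per_method` (method, metric, mean_sd), `ranking` (a data frame per
#'   metric, most stable first) and `comparison` (per method and
#'   benchmark, SD of SD-WEAT scores vs SD of WEAT scores, when both are
#'   available).
#' @export
summarize_stability <- function(panels) {
  if (inherits(panels, "score_panel")) panels <- list(panels)
  stopifnot(length(panels) >= 1L)
  bench_sets <- lapply(panels, function(p) sort(unique(p$benchmark_id)))
  if (length(unique(vapply(bench_sets, paste, "", collapse = "\u1f"))) != 1L) {
    stop("summarize_stability: panels do not share the same benchmark set",
         call. = FALSE)
  }
  per_benchmark <- do.call(rbind, lapply(panels, function(p) {
    meta <- panel_meta(p)
    agg <- lapply(split(p$score, p$benchmark_id), function(x) {
      x <- x[!is.na(x)]
      data.frame(n = length(x), min = min(x), max = max(x), sd = stats::sd(x))
    })
    out <- do.call(rbind, agg)
    data.frame(method = meta$method, metric = meta$metric,
               benchmark_id = names(agg), out,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  per_method <- stats::aggregate(sd ~ method + metric, data = per_benchmark, FUN = mean)
  names(per_method)[names(per_method) == "sd"] <- "mean_sd"
  ranking <- lapply(split(per_method, per_method$metric), function(df) {
    df[order(df$mean_sd), c("method", "mean_sd")]
  })
  comparison <- NULL
  both <- intersect(per_benchmark$method[per_benchmark$metric == "weat"],
                    per_benchmark$method[per_benchmark$metric == "sdweat"])
  if (length(both) > 0L) {
    w <- per_benchmark[per_benchmark$metric == "weat" &
                         per_benchmark$method %in% both, ]
    s <- per_benchmark[per_benchmark$metric == "sdweat" &
                         per_benchmark$method %in% both, ]
    comparison <- merge(
      w[, c("method", "benchmark_id", "sd")],
      s[, c("method", "benchmark_id", "sd")],
      by = c("method", "benchmark_id"), suffixes = c("_weat", "_sdweat"))
    comparison$sdweat_tighter <- comparison$sd_sdweat <= comparison$sd_weat
  }
  structure(list(per_benchmark = per_benchmark, per_method = per_method,
                 ranking = ranking, comparison = comparison),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  cat("Per-method mean of per-benchmark SDs (lower = more stable):\n")
  print(x$per_method, digits = 4, row.names = FALSE)
  for (metric in names(x$ranking)) {
    cat(sprintf("Ranking (%s): %s\n", metric,
                paste(x$ranking[[metric]]$method, collapse = " < ")))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("SD-WEAT spread <= WEAT spread in %d / %d method-benchmark cells\n",
                sum(x$comparison$sdweat_tighter), nrow(x$comparison)))
  }
  invisible(x)
}
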