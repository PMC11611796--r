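#' Construct a term set
#'
#' A term set is an ordered list of distinct, non-empty terms under a short
#' label. Term sets are the building blocks of a bias benchmark: two target
#' sets (the concepts under test, e.g. science vs art terms) and two
#' attribute sets (the social categories they may associate with, e.g. male
#' vs female terms).
#'
#' @param label Short character label, e.g. `"pleasant"`.
#' @param terms Character vector of terms. Words or compound words
#'   (compounds may contain spaces or hyphens). Must be non-empty, contain
#'   no duplicates (exact, case-sensitive comparison) and no
#'   whitespace-only entries.
#' @return An object of class `term_set`: a list with elements `label` and
#'   `terms`.
#' @examples
#' term_set("career", c("executive", "salary", "office"))
#' @export
term_set <- function(label, terms) {
  stopifnot(is.character(label), length(label) == 1L)
  terms <- as.character(terms)
  ts <- structure(list(label = label, terms = terms), class = "term_set")
  validate_term_set(ts)
  ts
}

validate_term_set <- function(ts, where = ts$label) {
  if (length(ts$terms) == 0L) {
    stop(sprintf("term set '%s': terms must be non-empty", where), call. = FALSE)
  }
  if (any(is.na(ts$terms)) || any(!nzchar(trimws(ts$terms)))) {
    stop(sprintf("term set '%s': contains an empty or whitespace-only term", where),
         call. = FALSE)
  }
  dup <- ts$terms[duplicated(ts$terms)]
  if (length(dup) > 0L) {
    stop(sprintf("term set '%s': duplicate terms: %s", where,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  invisible(ts)
}

#' @export
print.term_set <- function(x, ...) {
  cat(sprintf("<term_set> %s (%d terms): %s\n", x$label, length(x$terms),
              paste(utils::head(x$terms, 6L), collapse = ", ")))
  invisible(x)
}

#' Construct a bias benchmark
#'
#' One benchmark is the unit of a single word embedding association test:
#' two disjoint target term sets `X` and `Y` and two disjoint attribute
#' term sets `A` and `B`. Equal target-set sizes are required for the exact
#' partition p-value and the canonical effect-size bound; unequal sizes are
#' flagged (`balanced_targets = FALSE`) but not fatal, since resampling
#' workflows may drop out-of-vocabulary terms.
#'
#' @param id Benchmark identifier, e.g. `"WEAT-1"`.
#' @param description Free-text description.
#' @param target_x,target_y Target [term_set]s; must be disjoint.
#' @param attribute_a,attribute_b Attribute [term_set]s; must be disjoint.
#' @return An object of class `bias_benchmark`.
#' @export
bias_benchmark <- function(id, description, target_x, target_y,
                           attribute_a, attribute_b) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  b <- structure(
    list(id = id, description = as.character(description)[1L],
         target_x = target_x, target_y = target_y,
         attribute_a = attribute_a, attribute_b = attribute_b),
    class = "bias_benchmark")
  validate_benchmark(b)
  b
}

validate_benchmark <- function(b) {
  for (slot in c("target_x", "target_y", "attribute_a", "attribute_b")) {
    ts <- b[[slot]]
    if (!inherits(ts, "term_set")) {
      stop(sprintf("benchmark '%s': %s is not a term_set", b$id, slot), call. = FALSE)
    }
    validate_term_set(ts, where = sprintf("%s/%s", b$id, slot))
  }
  shared_t <- intersect(b$target_x$terms, b$target_y$terms)
  if (length(shared_t) > 0L) {
    stop(sprintf("benchmark '%s': target sets are not disjoint (shared: %s)",
                 b$id, paste(shared_t, collapse = ", ")), call. = FALSE)
  }
  shared_a <- intersect(b$attribute_a$terms, b$attribute_b$terms)
  if (length(shared_a) > 0L) {
    stop(sprintf("benchmark '%s': attribute sets are not disjoint (shared: %s)",
                 b$id, paste(shared_a, collapse = ", ")), call. = FALSE)
  }
  invisible(b)
}

#' Is a benchmark balanced?
#'
#' `TRUE` when the two target sets have equal size, the condition under
#' which the exact partition p-value is well defined on the original sets
#' and the effect size obeys the canonical bound of 2.
#'
#' @param b A [bias_benchmark].
#' @return Logical scalar.
#' @export
balanced_targets <- function(b) {
  stopifnot(inherits(b, "bias_benchmark"))
  length(b$target_x$terms) == length(b$target_y$terms)
}

#' @export
print.bias_benchmark <- function(x, ...) {
  d <- describe_benchmark(x)
  cat(sprintf("<bias_benchmark> %s: %s\n", x$id, x$description))
  cat(sprintf("  targets  %s (%d) vs %s (%d)\n",
              x$target_x$label, d$n_target_x, x$target_y$label, d$n_target_y))
  cat(sprintf("  attrs    %s (%d) vs %s (%d), pooled %d\n",
              x$attribute_a$label, d$n_attribute_a,
              x$attribute_b$label, d$n_attribute_b, d$n_pooled))
  invisible(x)
}

#' Summarize a benchmark's set sizes
#'
#' @param b A [bias_benchmark].
#' @return A one-row data frame with the benchmark id, the four set sizes
#'   and the pooled attribute count |A ∪ B|.
#' @export
describe_benchmark <- function(b) {
  stopifnot(inherits(b, "bias_benchmark"))
  data.frame(
    id = b$id,
    n_target_x = length(b$target_x$terms),
    n_target_y = length(b$target_y$terms),
    n_attribute_a = length(b$attribute_a$terms),
    n_attribute_b = length(b$attribute_b$terms),
    n_pooled = length(union(b$attribute_a$terms, b$attribute_b$terms)),
    balanced = balanced_targets(b),
    stringsAsFactors = FALSE)
}

benchmark_from_record <- function(rec, index) {
  need <- function(x, field, record_name) {
    if (is.null(x)) {
      stop(sprintf("benchmark file: record %s is missing field '%s'",
                   record_name, field), call. = FALSE)
    }
    x
  }
  rid <- if (!is.null(rec$id)) rec$id else sprintf("#%d", index)
  set_of <- function(node, field) {
    node <- need(node, field, rid)
    term_set(need(node$label, paste0(field, "/label"), rid),
             need(node$terms, paste0(field, "/terms"), rid))
  }
  bias_benchmark(
    id = need(rec$id, "id", rid),
    description = if (is.null(rec$description)) "" else rec$description,
    target_x = set_of(rec$targets$X, "targets/X"),
    target_y = set_of(rec$targets$Y, "targets/Y"),
    attribute_a = set_of(rec$attributes$A, "attributes/A"),
    attribute_b = set_of(rec$attributes$B, "attributes/B"))
}

#' Load bias benchmarks from a JSON file
#'
#' The file holds either a JSON array of benchmark records, or an object
#' with a `provenance` string and a `benchmarks` array. Each record has
#' keys `id`, `description`, `targets` (`X`, `Y`) and `attributes`
#' (`A`, `B`), where every set is `{label, terms}`. Records are validated
#' (non-empty, duplicate-free sets; disjoint targets; disjoint attributes)
#' and returned in file order.
#'
#' @param path Path to a benchmark JSON file.
#' @return A named list of [bias_benchmark] objects (names are the ids).
#' @seealso [weat_benchmarks()] for the bundled classic battery,
#'   [write_benchmarks()] for the inverse operation.
#' @export
load_benchmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("benchmark file not found: %s", path), call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  recs <- if (!is.null(names(doc)) && "benchmarks" %in% names(doc)) doc$benchmarks else doc
  if (length(recs) == 0L) stop("benchmark file contains no records", call. = FALSE)
  out <- lapply(seq_along(recs), function(i) benchmark_from_record(recs[[i]], i))
  ids <- vapply(out, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("benchmark file: duplicate ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  names(out) <- ids
  out
}

#' Write bias benchmarks to a JSON file
#'
#' Inverse of [load_benchmarks()]: `load_benchmarks(write_benchmarks(b, f))`
#' reproduces the data model exactly.
#'
#' @param benchmarks A list of [bias_benchmark] objects.
#' @param path Output path.
#' @param provenance Optional provenance string stored in the file header.
#' @return `path`, invisibly.
#' @export
write_benchmarks <- function(benchmarks, path, provenance = NULL) {
  if (inherits(benchmarks, "bias_benchmark")) benchmarks <- list(benchmarks)
  recs <- lapply(benchmarks, function(b) {
    set <- function(ts) list(label = jsonlite::unbox(ts$label), terms = ts$terms)
    list(id = jsonlite::unbox(b$id),
         description = jsonlite::unbox(b$description),
         targets = list(X = set(b$target_x), Y = set(b$target_y)),
         attributes = list(A = set(b$attribute_a), B = set(b$attribute_b)))
  })
  doc <- if (is.null(provenance)) recs else {
    list(provenance = jsonlite::unbox(provenance), benchmarks = recs)
  }
  jsonlite::write_json(doc, path, auto_unbox = FALSE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' The classic WEAT benchmark battery
#'
#' Loads the ten classic word embedding association test benchmarks
#' (WEAT-1 … WEAT-10) bundled with the package: flowers/insects and
#' instruments/weapons vs pleasant/unpleasant, European- vs
#' African-American names vs pleasant/unpleasant (three variants),
#' male/female names vs career/family, math/arts and science/arts vs
#' male/female terms, mental/physical disease vs temporary/permanent, and
#' young/old names vs pleasant/unpleasant. Term lists follow the original
#' association-test battery of Caliskan, Bryson and Narayanan (2017).
#'
#' @return A named list of ten [bias_benchmark] objects.
#' @examples
#' bm <- weat_benchmarks()
#' describe_benchmark(bm[["WEAT-7"]])
#' @export
weat_benchmarks <- function() {
  load_benchmarks(system.file("extdata", "weat_benchmarks.json",
                              package = "sdweat", mustWork = TRUE))
}
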