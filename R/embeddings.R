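#' Construct an embedding store
#'
#' An embedding store is a term-to-vector mapping of fixed dimension: any
#' source of vectors (a static vector file, a synthetic generator, or a
#' contextual encoder queried without context) can be wrapped as one. All
#' downstream statistics depend on the vectors only through cosine
#' similarity and so are invariant to positive per-vector rescaling.
#'
#' @param vectors Numeric matrix, one row per term; row names are the
#'   terms. All components must be finite and no row may be all zeros.
#' @param source_label Character label describing the provenance.
#' @return An object of class `embedding_store` with fields `vectors`,
#'   `dimension` and `source_label`.
#' @export
embedding_store <- function(vectors, source_label = "unknown") {
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  if (is.null(rownames(vectors)) || any(!nzchar(rownames(vectors)))) {
    stop("embedding_store: vectors must have non-empty row names (the terms)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(vectors))) {
    stop("embedding_store: duplicate terms in row names", call. = FALSE)
  }
  if (!all(is.finite(vectors))) {
    stop("embedding_store: vectors contain non-finite components", call. = FALSE)
  }
  zero <- rowSums(vectors != 0) == 0L
  if (any(zero)) {
    stop(sprintf("embedding_store: all-zero vector for term(s): %s",
                 paste(utils::head(rownames(vectors)[zero], 5L), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(vectors = vectors, dimension = ncol(vectors),
                 source_label = source_label),
            class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store> %s: %d terms x %d dimensions\n",
              x$source_label, nrow(x$vectors), x$dimension))
  invisible(x)
}

#' Vocabulary of an embedding store
#' @param store An [embedding_store].
#' @return Character vector of terms in store order.
#' @export
vocabulary <- function(store) {
  stopifnot(inherits(store, "embedding_store"))
  rownames(store$vectors)
}

open_text <- function(path) {
  # gzfile() transparently reads both plain and gzip-compressed text
  con <- gzfile(path, open = "rt", encoding = "UTF-8")
  con
}

#' Read word vectors from a text file
#'
#' Supports the two standard whitespace-delimited text dialects:
#' `word2vec-text` (first line is a `count dim` header) and `glove-text`
#' (no header; every line is `term v1 ... vd`). Gzip-compressed files are
#' read transparently. With `format = "auto"` the dialect is detected from
#' the first line. Duplicate terms keep the first occurrence; later ones
#' are dropped with a warning. Lines whose dimension disagrees with the
#' first data line are a format error, as are all-zero vectors.
#'
#' @param path Path to the vector file (optionally `.gz`).
#' @param format One of `"auto"`, `"word2vec-text"`, `"glove-text"`.
#' @param source_label Label for the store; defaults to the file name.
#' @return An [embedding_store].
#' @export
read_word_vectors <- function(path,
                              format = c("auto", "word2vec-text", "glove-text"),
                              source_label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("vector file not found: %s", path), call. = FALSE)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("vector file is empty: %s", path), call. = FALSE)

  first <- strsplit(trimws(lines[[1L]]), "[[:space:]]+")[[1L]]
  has_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.numeric(first))) &&
    all(as.numeric(first) == round(as.numeric(first)))
  if (format == "auto") {
    format <- if (has_header) "word2vec-text" else "glove-text"
  }
  offset <- 0L
  declared <- NULL
  if (format == "word2vec-text") {
    if (!has_header) {
      stop(sprintf("%s: word2vec-text requires a 'count dim' header line", path),
           call. = FALSE)
    }
    declared <- as.integer(first[2L])
    offset <- 1L
  }
  body <- lines[seq.int(offset + 1L, length(lines))]
  parts <- strsplit(body, "[[:space:]]+")
  terms <- vapply(parts, `[[`, "", 1L)
  dims <- lengths(parts) - 1L
  dim0 <- if (!is.null(declared)) declared else dims[[1L]]
  bad <- which(dims != dim0)
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d has %d components, expected %d",
                 path, bad[[1L]] + offset, dims[[bad[[1L]]]], dim0), call. = FALSE)
  }
  vec <- vapply(parts, function(p) as.numeric(p[-1L]), numeric(dim0))
  m <- if (dim0 == 1L) matrix(vec, ncol = 1L) else t(vec)
  if (!all(is.finite(m))) {
    stop(sprintf("%s: non-numeric or non-finite vector component", path), call. = FALSE)
  }
  dup <- duplicated(terms)
  if (any(dup)) {
    warning(sprintf("%s: %d duplicate term(s) dropped (first occurrence kept): %s",
                    path, sum(dup),
                    paste(utils::head(unique(terms[dup]), 5L), collapse = ", ")),
            call. = FALSE)
    m <- m[!dup, , drop = FALSE]
    terms <- terms[!dup]
  }
  zero <- rowSums(m != 0) == 0L
  if (any(zero)) {
    stop(sprintf("%s: all-zero vector rejected for term(s): %s", path,
                 paste(utils::head(terms[zero], 5L), collapse = ", ")), call. = FALSE)
  }
  rownames(m) <- terms
  embedding_store(m, source_label = source_label)
}

#' Write word vectors to a text file
#'
#' @param store An [embedding_store].
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @param format `"glove-text"` (no header) or `"word2vec-text"`
#'   (`count dim` header).
#' @param digits Number of significant digits to print.
#' @return `path`, invisibly.
#' @export
write_word_vectors <- function(store, path,
                               format = c("glove-text", "word2vec-text"),
                               digits = 8L) {
  stopifnot(inherits(store, "embedding_store"))
  format <- match.arg(format)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (format == "word2vec-text") {
    writeLines(sprintf("%d %d", nrow(store$vectors), store$dimension), con)
  }
  num <- formatC(store$vectors, digits = digits, format = "g")
  lines <- paste(rownames(store$vectors),
                 apply(num, 1L, paste, collapse = " "))
  writeLines(lines, con)
  invisible(path)
}

new_resolution_report <- function(terms, kinds, missing) {
  structure(list(
    resolved = data.frame(term = terms, kind = kinds, stringsAsFactors = FALSE),
    missing = missing), class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf("<resolution_report> %d resolved (%s), %d missing\n",
              nrow(x$resolved),
              paste(sprintf("%s: %d", names(table(x$resolved$kind)),
                            table(x$resolved$kind)), collapse = ", "),
              length(x$missing)))
  invisible(x)
}

resolve_one <- function(store, term, lowercase) {
  vocab_hit <- function(t) !is.na(match(t, rownames(store$vectors)))
  if (vocab_hit(term)) {
    return(list(vec = store$vectors[term, ], kind = "exact"))
  }
  if (lowercase && vocab_hit(tolower(term))) {
    return(list(vec = store$vectors[tolower(term), ], kind = "lowercased"))
  }
  if (grepl("[ -]", term)) {
    tokens <- strsplit(term, "[ -]+")[[1L]]
    tokens <- tokens[nzchar(tokens)]
    tok_vecs <- lapply(tokens, function(tk) {
      if (vocab_hit(tk)) store$vectors[tk, ]
      else if (lowercase && vocab_hit(tolower(tk))) store$vectors[tolower(tk), ]
      else NULL
    })
    if (!any(vapply(tok_vecs, is.null, TRUE))) {
      return(list(vec = colMeans(do.call(rbind, tok_vecs)), kind = "multi-token-mean"))
    }
  }
  NULL
}

#' Resolve terms against an embedding store
#'
#' Looks each term up in the store. Resolution order: exact match; under
#' `lowercase_fallback`, a lowercased match; for compound terms (containing
#' a space or hyphen) that miss as a whole, the arithmetic mean of their
#' constituent token vectors. The out-of-vocabulary policy decides what
#' happens to terms that still miss: `"error"` aborts listing them,
#' `"skip"` drops and reports them, `"lowercase_fallback"` enables the
#' lowercase step and then drops remaining misses with a warning.
#'
#' @param store An [embedding_store].
#' @param terms Non-empty character vector of terms.
#' @param oov_policy `"error"`, `"skip"` or `"lowercase_fallback"`.
#' @return A list with `vectors` (matrix, one row per resolved term) and
#'   `report` (a `resolution_report`: resolved terms with their resolution
#'   kind, plus the missing terms).
#' @export
resolve_terms <- function(store, terms,
                          oov_policy = c("error", "skip", "lowercase_fallback")) {
  stopifnot(inherits(store, "embedding_store"))
  oov_policy <- match.arg(oov_policy)
  terms <- as.character(terms)
  if (length(terms) == 0L) stop("resolve_terms: terms must be non-empty", call. = FALSE)
  lowercase <- oov_policy == "lowercase_fallback"
  hits <- lapply(terms, function(t) resolve_one(store, t, lowercase))
  ok <- !vapply(hits, is.null, TRUE)
  missing <- terms[!ok]
  if (length(missing) > 0L) {
    if (oov_policy == "error") {
      stop(sprintf("resolve_terms: term(s) not in vocabulary: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    if (oov_policy == "lowercase_fallback") {
      warning(sprintf("resolve_terms: dropped out-of-vocabulary term(s): %s",
                      paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  if (!any(ok)) {
    stop("resolve_terms: no terms could be resolved against the store", call. = FALSE)
  }
  vecs <- do.call(rbind, lapply(hits[ok], `[[`, "vec"))
  rownames(vecs) <- terms[ok]
  kinds <- vapply(hits[ok], `[[`, "", "kind")
  list(vectors = vecs,
       report = new_resolution_report(terms[ok], kinds, missing))
}

#' Sample terms from a store's vocabulary
#'
#' Draws `n` distinct terms uniformly without replacement from the filtered
#' vocabulary, for use as the random-word pool of the negative control.
#' The default filter keeps purely alphabetic terms of length at least 2,
#' and the pool is restricted to the first `pool_size` vocabulary entries
#' (file order proxies frequency in standard GloVe releases).
#'
#' @param store An [embedding_store].
#' @param n Number of terms to draw.
#' @param seed Integer seed; identical seeds give identical draws.
#' @param filter Predicate on terms (vectorized); defaults to alphabetic
#'   terms of length >= 2.
#' @param pool_size Restrict the candidate pool to the first `pool_size`
#'   vocabulary entries (default 50000).
#' @return Character vector of `n` distinct terms.
#' @export
sample_vocabulary <- function(store, n, seed = 1L,
                              filter = function(t) grepl("^[A-Za-z]+$", t) & nchar(t) >= 2L,
                              pool_size = 50000L) {
  stopifnot(inherits(store, "embedding_store"), n >= 1L)
  vocab <- utils::head(vocabulary(store), pool_size)
  pool <- vocab[filter(vocab)]
  if (n > length(pool)) {
    stop(sprintf("sample_vocabulary: requested %d terms but filtered pool has %d",
                 n, length(pool)), call. = FALSE)
  }
  withr::with_seed(as.integer(seed), sample(pool, size = n, replace = FALSE))
}
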