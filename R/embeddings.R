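#' Embedding store
#'
#' A token -> vector map of fixed dimension, as produced by word2vec-style
#' models.  Tokens are lowercased at construction and queries are
#' lowercased before lookup, so matching is effectively case-insensitive.
#'
#' @param vectors numeric matrix, one row per token; rownames are the
#'   tokens.
#' @return an object of class `embedding_store` with fields `vectors`
#'   and `dim`.
#' @export
embedding_store <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors),
            !is.null(rownames(vectors)))
  rownames(vectors) <- tolower(rownames(vectors))
  if (anyDuplicated(rownames(vectors))) {
    warning("duplicate embedding tokens: keeping the last occurrence")
    keep <- !duplicated(rownames(vectors), fromLast = TRUE)
    vectors <- vectors[keep, , drop = FALSE]
  }
  structure(list(vectors = vectors, dim = ncol(vectors)),
            class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store> %d token(s), dimension %d\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Look up a single token
#'
#' @param store an `embedding_store`.
#' @param token character token (lowercased before lookup).
#' @return numeric vector, or `NULL` when out of vocabulary.
#' @export
emb_lookup <- function(store, token) {
  i <- match(tolower(token), rownames(store$vectors))
  if (is.na(i)) NULL else store$vectors[i, ]
}

#' Read / write word2vec text format
#'
#' The text format starts with a header line `<vocab_size> <dim>`
#' followed by one line per token: the token then `dim`
#' whitespace-separated reals.  Rows whose value count differs from the
#' declared dimension are format errors; duplicate tokens keep the last
#' occurrence with a warning.
#'
#' @param path file path.
#' @return `read_word2vec()` an `embedding_store`;
#'   `write_word2vec()` the path invisibly.
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    kgpr_stop("empty word2vec file", "kgpr_format")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]),
                                              "[[:space:]]+")[[1]]))
  if (length(hdr) != 2 || any(is.na(hdr)))
    kgpr_stop("word2vec header must be '<vocab_size> <dim>'", "kgpr_format")
  dim <- hdr[2]
  body <- lines[-1]
  if (length(body) != hdr[1])
    warning(sprintf("word2vec header declares %d tokens but file has %d rows",
                    hdr[1], length(body)))
  toks <- character(length(body))
  mat <- matrix(NA_real_, nrow = length(body), ncol = dim)
  for (i in seq_along(body)) {
    f <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
    if (length(f) != dim + 1)
      kgpr_stop(sprintf("word2vec row %d: expected %d values, got %d",
                        i, dim, length(f) - 1), "kgpr_format")
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(vals)))
      kgpr_stop(sprintf("word2vec row %d: non-numeric value", i),
                "kgpr_format")
    toks[i] <- f[1]
    mat[i, ] <- vals
  }
  rownames(mat) <- toks
  embedding_store(mat)
}

#' @rdname read_word2vec
#' @param store an `embedding_store`.
#' @export
write_word2vec <- function(store, path) {
  v <- store$vectors
  lines <- c(sprintf("%d %d", nrow(v), ncol(v)),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], formatC(v[i, ], format = "g",
                                               digits = 12)),
                     collapse = " "), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Embedding vector of an entity name
#'
#' Entity names can be multi-word while embedding vocabularies are
#' token-based.  The name (normalized) is first tried as a phrase: as-is,
#' then with spaces replaced by `"_"`, then by `"-"` (common phrase
#' conventions).  If no phrase token exists, the name is tokenized on
#' whitespace and the vectors of in-vocabulary tokens are averaged
#' componentwise.  When nothing is in vocabulary the entity has no
#' vector and `NULL` is returned; paths through such nodes are dropped
#' by [score_paths()] rather than zero-scored.
#'
#' @param store an `embedding_store`.
#' @param name entity name.
#' @return numeric vector or `NULL`.
#' @export
entity_vector <- function(store, name) {
  nm <- normalize_name(name)
  for (cand in unique(c(nm, gsub(" ", "_", nm, fixed = TRUE),
                        gsub(" ", "-", nm, fixed = TRUE)))) {
    v <- emb_lookup(store, cand)
    if (!is.null(v)) return(v)
  }
  toks <- strsplit(nm, " ", fixed = TRUE)[[1]]
  vs <- lapply(toks, emb_lookup, store = store)
  vs <- vs[!vapply(vs, is.null, logical(1))]
  if (length(vs) == 0) return(NULL)
  colMeans(do.call(rbind, vs))
}

#' Cosine similarity
#'
#' `u . v / (||u|| ||v||)`, in `[-1, 1]`.  Vectors must share a
#' dimension and be nonzero.
#'
#' @param u,v numeric vectors.
#' @return numeric scalar.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    kgpr_stop("cosine: dimension mismatch", "kgpr_bad_parameter")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    kgpr_stop("cosine undefined for a zero vector", "kgpr_zero_vector")
  sum(u * v) / (nu * nv)
}
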