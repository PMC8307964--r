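#' Enumerate exact-depth simple paths between two entities
#'
#' All node-simple paths with exactly `depth` edges from `source` to
#' `target`, traversing the multigraph as undirected.  Parallel edge
#' instances yield distinct paths: the same node sequence appears once
#' per combination of edge instances along it, so two parallel edges
#' labelled `co_occur` and `gene_gene` on the first hop give two paths
#' differing only in that label (and duplicate instances of an identical
#' edge give duplicate paths).  Output is deterministically ordered by
#' node sequence, then label sequence.
#'
#' @param graph a `knowledge_graph`.
#' @param source,target entity ids or unique names; must differ.
#' @param depth exact number of edges, >= 1.
#' @return list of [kg_path()] (node names, not ids).
#' @export
enumerate_paths <- function(graph, source, target, depth) {
  src <- resolve_entity(graph, source)
  dst <- resolve_entity(graph, target)
  if (identical(src, dst))
    kgpr_stop("source and target must differ", "kgpr_bad_query")
  if (!is.numeric(depth) || depth < 1)
    kgpr_stop("depth must be a positive integer", "kgpr_bad_parameter")
  depth <- as.integer(depth)

  e <- graph$edges
  if (nrow(e) == 0) return(list())
  a <- pmin(e$head, e$tail)
  b <- pmax(e$head, e$tail)
  pkey <- paste(a, b, sep = "\r")
  labs_by_pair <- split(e$label, pkey)
  nbr <- split(c(b, a), c(a, b))
  nbr <- lapply(nbr, unique)

  # prune: nodes farther than the remaining step budget from the target
  # (ignoring labels) cannot complete a path
  ig <- as_igraph(graph)
  dist_t <- igraph::distances(ig, v = dst, weights = NA)[1, ]

  seqs <- list()
  walk <- function(node, trail) {
    steps_left <- depth - (length(trail) - 1L)
    if (steps_left == 0L) {
      if (node == dst) seqs[[length(seqs) + 1L]] <<- trail
      return(invisible())
    }
    for (nxt in nbr[[node]] %||% character()) {
      if (nxt %in% trail) next
      if (nxt == dst && steps_left > 1L) next  # simple path: no revisit
      d <- dist_t[[nxt]]
      if (!is.finite(d) || d > steps_left - 1L) next
      walk(nxt, c(trail, nxt))
    }
  }
  walk(src, src)
  if (length(seqs) == 0) return(list())

  id2name <- graph$entities$name
  names(id2name) <- graph$entities$id
  paths <- list()
  for (s in seqs) {
    step_labels <- lapply(seq_len(depth), function(i) {
      k <- paste(min(s[i], s[i + 1]), max(s[i], s[i + 1]), sep = "\r")
      sort(labs_by_pair[[k]])
    })
    combos <- expand.grid(step_labels, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    nodes <- unname(id2name[s])
    for (r in seq_len(nrow(combos)))
      paths[[length(paths) + 1L]] <-
        kg_path(nodes, as.character(unlist(combos[r, ], use.names = FALSE)))
  }
  keys <- vapply(paths, function(p)
    paste(paste(p$nodes, collapse = "\r"), paste(p$labels, collapse = "\r"),
          sep = "\n"), character(1))
  paths[order(keys)]
}

#' Score paths by summed embedding cosine similarity
#'
#' The score of a depth-`d` path is `S = sum_i cos(v(n_{i-1}), v(n_i))`
#' over its `d` consecutive node pairs, where `v()` is
#' [entity_vector()]; `S` lies in `[-d, d]`.  Paths containing a node
#' with no embedding vector are dropped (not zero-scored) and recorded
#' in the `dropped` attribute.  The result is sorted by score
#' descending, ties broken by the rendered path record.
#'
#' @param paths list of `kg_path` (or character path records).
#' @param store an `embedding_store`.
#' @return data frame with columns `record`, `depth`, `score`, ordered
#'   by decreasing score; attribute `dropped` is a list with the count
#'   and records of unembeddable paths.
#' @export
score_paths <- function(paths, store) {
  paths <- as_path_list(paths)
  rec <- vapply(paths, render_path_record, character(1))
  dep <- vapply(paths, function(p) p$depth, numeric(1))
  vec_cache <- new.env(parent = emptyenv())
  getv <- function(nm) {
    if (exists(nm, envir = vec_cache, inherits = FALSE))
      return(get(nm, envir = vec_cache, inherits = FALSE))
    v <- entity_vector(store, nm)
    if (is.null(v)) v <- list(NULL)  # sentinel: no embedding for this node
    assign(nm, v, envir = vec_cache)
    v
  }
  score1 <- function(p) {
    vs <- lapply(p$nodes, getv)
    if (any(vapply(vs, is.list, logical(1)))) return(NA_real_)
    sum(vapply(seq_len(p$depth), function(i)
      cosine_similarity(vs[[i]], vs[[i + 1]]), numeric(1)))
  }
  s <- vapply(paths, score1, numeric(1))
  dropped <- is.na(s)
  out <- data.frame(record = rec[!dropped], depth = dep[!dropped],
                    score = s[!dropped], stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$record), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- list(count = sum(dropped),
                               records = rec[dropped])
  out
}

as_path_list <- function(paths) {
  if (is.character(paths)) return(lapply(paths, parse_path_record))
  if (inherits(paths, "kg_path")) return(list(paths))
  if (is.data.frame(paths) && "record" %in% names(paths))
    return(lapply(paths$record, parse_path_record))
  stopifnot(is.list(paths))
  lapply(paths, function(p)
    if (inherits(p, "kg_path")) p else parse_path_record(p))
}

#' Strict nearest-rank top-percentile filter
#'
#' The q-th percentile of n ordered scores is the `ceiling(q/100 * n)`-th
#' smallest value (nearest-rank convention); the filter retains the
#' paths whose score is strictly greater than that value.  With 202
#' distinct scores and q = 95 exactly 10 paths survive; when many paths
#' tie at the percentile value, all of them are excluded (strict
#' inequality), so tied distributions can retain fewer — or with ties
#' only above the cut, more — than `n * (1 - q/100)` paths.
#'
#' @param scored data frame from [score_paths()] (columns `record`,
#'   `depth`, `score`), non-empty.
#' @param q percentile in the open interval (0, 100); default 95.
#' @return the retained rows, descending-score order preserved.
#' @export
top_percentile <- function(scored, q = 95) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 100)
    kgpr_stop("q must lie strictly between 0 and 100", "kgpr_bad_parameter")
  if (!is.data.frame(scored) || nrow(scored) == 0)
    kgpr_stop("top_percentile needs a non-empty scored data frame",
              "kgpr_bad_parameter")
  s <- sort(scored$score)
  cut <- s[ceiling(q / 100 * length(s))]
  out <- scored[scored$score > cut, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count distinct relationships across paths
#'
#' A relationship is one edge of a path.  With `typed = TRUE` (default)
#' relationships are undirected `(node, label, node)` triples; with
#' `typed = FALSE` they are unordered node pairs regardless of label.
#' Counting is set-valued: repeated paths or repeated edges count once.
#'
#' @param paths list of `kg_path`, character records, or a scored data
#'   frame.
#' @param typed logical, see above.
#' @return non-negative integer.
#' @export
count_distinct_relationships <- function(paths, typed = TRUE) {
  paths <- as_path_list(paths)
  keys <- unlist(lapply(paths, function(p) {
    a <- p$nodes[-length(p$nodes)]
    b <- p$nodes[-1]
    lo <- pmin(a, b); hi <- pmax(a, b)
    if (typed) paste(lo, p$labels, hi, sep = "\r") else
      paste(lo, hi, sep = "\r")
  }), use.names = FALSE)
  length(unique(keys))
}

#' Run a full path-ranking query
#'
#' For each requested depth: enumerate all exact-depth simple paths
#' between source and target, score them by summed cosine similarity,
#' select the strict top-`percentile` subset, and count distinct
#' relationships among the selected paths (both typed triples and
#' untyped node pairs).  Scores in the report are rounded to 6 decimals
#' for serialization; identical inputs give identical reports.
#'
#' @param graph a `knowledge_graph`.
#' @param store an `embedding_store`.
#' @param source,target entity ids or unique names.
#' @param depths integer vector of path depths, default `c(2, 3, 4)`.
#' @param percentile percentile for [top_percentile()], default 95.
#' @return an object of class `path_query_report`: a list with the
#'   query parameters and one entry per depth holding `n_paths`,
#'   `n_scored`, `n_dropped`, `n_top`, `distinct_relationships_typed`,
#'   `distinct_relationships_untyped` and the `scored` and `top` tables.
#' @export
run_path_query <- function(graph, store, source, target,
                           depths = c(2, 3, 4), percentile = 95) {
  per_depth <- list()
  for (d in depths) {
    paths <- enumerate_paths(graph, source, target, d)
    if (length(paths) == 0) {
      per_depth[[as.character(d)]] <- list(
        n_paths = 0L, n_scored = 0L, n_dropped = 0L, n_top = 0L,
        distinct_relationships_typed = 0L,
        distinct_relationships_untyped = 0L,
        scored = data.frame(record = character(), depth = numeric(),
                            score = numeric(), stringsAsFactors = FALSE),
        top = data.frame(record = character(), depth = numeric(),
                         score = numeric(), stringsAsFactors = FALSE))
      next
    }
    scored <- score_paths(paths, store)
    dropped <- attr(scored, "dropped")
    top <- if (nrow(scored)) top_percentile(scored, percentile) else scored
    scored$score <- round(scored$score, 6)
    top$score <- round(top$score, 6)
    per_depth[[as.character(d)]] <- list(
      n_paths = length(paths),
      n_scored = nrow(scored),
      n_dropped = dropped$count,
      n_top = nrow(top),
      distinct_relationships_typed =
        if (nrow(top)) count_distinct_relationships(top, typed = TRUE) else 0L,
      distinct_relationships_untyped =
        if (nrow(top)) count_distinct_relationships(top, typed = FALSE) else 0L,
      scored = scored, top = top)
  }
  structure(list(source = normalize_name(source),
                 target = normalize_name(target),
                 percentile = percentile, depths = per_depth),
            class = "path_query_report")
}

#' @export
print.path_query_report <- function(x, ...) {
  cat(sprintf("<path_query_report> %s -> %s (top %g percentile)\n",
              x$source, x$target, x$percentile))
  for (d in names(x$depths)) {
    r <- x$depths[[d]]
    cat(sprintf("  depth %s: %d path(s), %d scored, %d top-ranked, %d typed relationship(s)\n",
                d, r$n_paths, r$n_scored, r$n_top,
                r$distinct_relationships_typed))
  }
  invisible(x)
}
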