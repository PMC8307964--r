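# Independent oracles used to cross-check the implementation.  These are
# deliberately written against the raw entity/edge tables with different
# algorithms (brute force, dynamic programming) than the package code.

# Hop distances from a center by hand-rolled breadth-first search.
oracle_bfs_dist <- function(g, center_id) {
  e <- g$edges
  adj <- split(c(e$tail, e$head), c(e$head, e$tail))
  dist <- setNames(rep(Inf, nrow(g$entities)), g$entities$id)
  dist[center_id] <- 0
  frontier <- center_id
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# Exhaustive exact-depth simple-path enumeration: generate every node
# sequence over the whole entity set, filter, then expand per-step edge
# instances.  Returns the sorted multiset of rendered path records.
oracle_path_records <- function(g, src_id, dst_id, depth) {
  ids <- g$entities$id
  e <- g$edges
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  labs <- split(e$label, pair_key(e$head, e$tail))
  mids <- setdiff(ids, c(src_id, dst_id))
  if (depth == 1) {
    seqs <- list(c(src_id, dst_id))
  } else {
    grid <- expand.grid(rep(list(mids), depth - 1),
                        stringsAsFactors = FALSE)
    ok <- apply(grid, 1, function(r) !anyDuplicated(r))
    if (!any(ok)) return(character())
    seqs <- lapply(which(ok), function(i)
      c(src_id, unlist(grid[i, ], use.names = FALSE), dst_id))
  }
  id2name <- setNames(g$entities$name, g$entities$id)
  out <- character()
  for (s in seqs) {
    step <- lapply(seq_len(depth), function(i) labs[[pair_key(s[i], s[i + 1])]])
    if (any(vapply(step, is.null, logical(1)))) next
    combos <- expand.grid(step, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      toks <- character(2 * depth + 1)
      toks[seq(1, 2 * depth + 1, 2)] <- id2name[s]
      toks[seq(2, 2 * depth, 2)] <- unlist(combos[r, ], use.names = FALSE)
      out <- c(out, paste(toks, collapse = "--"))
    }
  }
  sort(out)
}

# Per-document binary pair counting by explicit double loop.
oracle_pair_counts <- function(docs) {
  counts <- new.env(parent = emptyenv())
  for (d in docs) {
    m <- d$mentions
    ent <- sort(unique(paste(m$name, m$type, sep = "\t")))
    if (length(ent) < 2) next
    for (i in seq_len(length(ent) - 1))
      for (j in (i + 1):length(ent)) {
        k <- paste(ent[i], ent[j], sep = "\r")
        counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
      }
  }
  out <- unlist(as.list(counts))
  out[order(names(out))]
}

# Textbook dynamic-programming Levenshtein distance.
oracle_levenshtein <- function(a, b) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  n <- length(sa); m <- length(sb)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- 0:n; D[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    D[i + 1, j + 1] <- min(D[i, j + 1] + 1, D[i + 1, j] + 1,
                           D[i, j] + (sa[i] != sb[j]))
  D[n + 1, m + 1]
}

# Random typed multigraph (<= 3 parallel edges per pair) built by direct
# kg_add_* calls; independent of the fixture generator.
random_test_kg <- function(seed, n_nodes = 10, p_pair = 0.3) {
  set.seed(seed)
  types <- sample(c("gene", "chemical", "disease"), n_nodes, replace = TRUE)
  names <- paste0("n", seq_len(n_nodes))
  g <- kg_new()
  for (i in seq_len(n_nodes)) g <- kg_add_entity(g, names[i], types[i])
  ids <- g$entities$id
  labels <- c("co_occur", "gene_gene", "gene_disease")
  for (i in seq_len(n_nodes - 1)) for (j in (i + 1):n_nodes) {
    if (runif(1) > p_pair) next
    for (k in seq_len(sample(3, 1)))
      g <- kg_add_edge(g, ids[i], ids[j], sample(labels, 1))
  }
  g
}

render_records <- function(paths) {
  sort(vapply(paths, render_path_record, character(1)))
}
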