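#' Synthetic fixture plans
#'
#' A fixture plan deterministically describes a small synthetic world:
#' entity counts per type, random edge densities per relation label,
#' planted paths with target per-step cosines, a pairwise co-mention
#' plan for document generation, and a synonym-lexicon plan.  All
#' randomness flows from the plan's seed through a private RNG stream;
#' no global random state is consumed or disturbed.
#'
#' Entity names are generated as `<type><index>` with underscores in
#' type names mapped to hyphens (e.g. `cell-line1`), so every generated
#' name is a single normalized token.
#'
#' @param seed integer RNG seed.
#' @param entities named integer vector: entities per type, e.g.
#'   `c(gene = 6, chemical = 3)`.
#' @param edge_density named numeric vector in `[0, 1]`: for each
#'   relation label, the fraction of all unordered entity pairs that
#'   receive a random edge with that label.
#' @param planted_paths list of plans, each a list with `nodes`
#'   (generated entity names), optional `labels` (default `co_occur`)
#'   and `cosines` (per-step target cosine in `[-1, 1]`, default 0.9).
#' @param comentions list of plans, each a list with entity names `a`,
#'   `b` and document count `n`.
#' @param lexicon list of plans, each a list with `canonical`, `type`
#'   and `synonyms`.
#' @param embedding_dim dimension of generated vectors; must be at
#'   least the number of planted-path-constrained entities.
#' @return an object of class `fixture_plan`.
#' @export
fixture_plan <- function(seed = 1L,
                         entities = c(gene = 6, chemical = 3, disease = 3),
                         edge_density = c(co_occur = 0.1),
                         planted_paths = list(),
                         comentions = list(),
                         lexicon = list(),
                         embedding_dim = 16L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (is.null(names(entities)) || any(!nzchar(names(entities))))
    kgpr_stop("entities must be a named count vector", "kgpr_bad_plan")
  types <- normalize_entity_type(names(entities))
  if (length(edge_density)) {
    normalize_relation_label(names(edge_density))
    if (any(edge_density < 0 | edge_density > 1))
      kgpr_stop("edge densities must lie in [0, 1] (1 = complete graph)",
                "kgpr_bad_plan")
  }
  name_list <- unlist(Map(function(t, k)
    paste0(gsub("_", "-", t, fixed = TRUE), seq_len(k)),
    types, as.integer(entities)), use.names = FALSE)
  type_of <- rep(types, as.integer(entities))
  names(type_of) <- name_list

  planted_paths <- lapply(planted_paths, function(p) {
    stopifnot(is.list(p), length(p$nodes) >= 2)
    p$nodes <- normalize_name(p$nodes)
    d <- length(p$nodes) - 1
    p$labels <- p$labels %||% rep("co_occur", d)
    p$labels <- normalize_relation_label(p$labels)
    p$cosines <- p$cosines %||% rep(0.9, d)
    if (length(p$labels) != d || length(p$cosines) != d)
      kgpr_stop("planted path: labels and cosines must have one entry per step",
                "kgpr_bad_plan")
    if (any(p$cosines < -1 | p$cosines > 1))
      kgpr_stop("planted cosines must lie in [-1, 1]", "kgpr_bad_plan")
    if (anyDuplicated(p$nodes))
      kgpr_stop("planted paths must be node-simple", "kgpr_bad_plan")
    bad <- setdiff(p$nodes, name_list)
    if (length(bad))
      kgpr_stop(sprintf("planted path references unknown entities: %s",
                        paste(bad, collapse = ", ")), "kgpr_bad_plan")
    p
  })
  comentions <- lapply(comentions, function(cm) {
    stopifnot(is.list(cm), !is.null(cm$a), !is.null(cm$b))
    cm$a <- normalize_name(cm$a); cm$b <- normalize_name(cm$b)
    cm$n <- as.integer(cm$n %||% 1L)
    if (cm$a == cm$b || cm$n < 1)
      kgpr_stop("co-mention plan needs two distinct entities and n >= 1",
                "kgpr_bad_plan")
    bad <- setdiff(c(cm$a, cm$b), name_list)
    if (length(bad))
      kgpr_stop(sprintf("co-mention plan references unknown entities: %s",
                        paste(bad, collapse = ", ")), "kgpr_bad_plan")
    cm
  })
  structure(list(seed = as.integer(seed), entities = entities,
                 types = type_of, names = name_list,
                 edge_density = edge_density,
                 planted_paths = planted_paths,
                 comentions = comentions, lexicon = lexicon,
                 embedding_dim = as.integer(embedding_dim)),
            class = "fixture_plan")
}

# Evaluate fn with a private RNG stream seeded from the plan (offset
# decouples the generators); the caller's random state is untouched.
with_plan_seed <- function(plan, offset, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed((plan$seed + offset) %% .Machine$integer.max)
  fn()
}

#' Generate a synthetic knowledge graph
#'
#' Creates the plan's entities, draws `round(density * choose(N, 2))`
#' random label-specific edges among all unordered entity pairs for each
#' entry of the density plan, then adds every planted path's edges.
#' Identical plans produce identical graphs.
#'
#' @param plan a [fixture_plan()].
#' @return a `knowledge_graph`.
#' @export
make_synthetic_kg <- function(plan) {
  stopifnot(inherits(plan, "fixture_plan"))
  g <- kg_new()
  for (nm in plan$names)
    g <- kg_add_entity(g, nm, plan$types[[nm]], sources = "synthetic")
  ids <- g$entities$id
  name2id <- ids
  names(name2id) <- g$entities$name
  n <- length(ids)
  edges <- with_plan_seed(plan, 101L, function() {
    out <- list()
    if (n >= 2 && length(plan$edge_density)) {
      pairs <- utils::combn(sort(ids), 2)
      npair <- ncol(pairs)
      for (lab in names(plan$edge_density)) {
        m <- round(plan$edge_density[[lab]] * npair)
        if (m == 0) next
        take <- sort(sample.int(npair, m))
        out[[lab]] <- data.frame(head = pairs[1, take],
                                 tail = pairs[2, take],
                                 label = normalize_relation_label(lab),
                                 stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  if (!is.null(edges))
    for (i in seq_len(nrow(edges)))
      g <- kg_add_edge(g, edges$head[i], edges$tail[i], edges$label[i])
  for (p in plan$planted_paths) {
    for (i in seq_len(length(p$nodes) - 1))
      g <- kg_add_edge(g, unname(name2id[p$nodes[i]]),
                       unname(name2id[p$nodes[i + 1]]), p$labels[i])
  }
  g
}

# Pairwise cosine matrix implied by the planted paths: consecutive pairs
# take the planted value and non-consecutive pairs within one path take
# the product of the step cosines between them (the Markov completion,
# which is always PSD for a chain).  Conflicting assignments are errors.
planted_gram <- function(plan) {
  nodes <- unique(unlist(lapply(plan$planted_paths, `[[`, "nodes")))
  k <- length(nodes)
  if (k == 0) return(list(nodes = character(), gram = NULL))
  G <- matrix(NA_real_, k, k, dimnames = list(nodes, nodes))
  diag(G) <- 1
  set_cos <- function(G, a, b, v) {
    cur <- G[a, b]
    if (!is.na(cur) && abs(cur - v) > 1e-9)
      kgpr_stop(sprintf("conflicting planted cosines for (%s, %s)", a, b),
                "kgpr_bad_plan")
    G[a, b] <- v; G[b, a] <- v
    G
  }
  for (p in plan$planted_paths) {
    d <- length(p$cosines)
    for (i in seq_len(d))
      for (j in i:d) {
        v <- prod(p$cosines[i:j])
        G <- set_cos(G, p$nodes[i], p$nodes[j + 1], v)
      }
  }
  G[is.na(G)] <- 0
  list(nodes = nodes, gram = G)
}

#' Generate synthetic embeddings with planted cosine structure
#'
#' Entities constrained by planted paths receive vectors constructed by
#' factorizing the implied pairwise-cosine Gram matrix
#' (eigendecomposition; eigenvalues below `-1e-9` make the constraint
#' set infeasible, tiny negative ones are clipped to zero), so each
#' planted pair `(a, b)` satisfies `|cos(v_a, v_b) - target| <= 1e-6`.
#' All remaining entities receive seeded random unit vectors.
#'
#' @param plan a [fixture_plan()].
#' @param names entity names to embed; defaults to all plan entities.
#' @param dim vector dimension; defaults to the plan's `embedding_dim`
#'   and must be at least the number of constrained entities.
#' @return an `embedding_store`.
#' @export
make_synthetic_embeddings <- function(plan, names = NULL, dim = NULL) {
  stopifnot(inherits(plan, "fixture_plan"))
  names <- names %||% plan$names
  dim <- as.integer(dim %||% plan$embedding_dim)
  pg <- planted_gram(plan)
  k <- length(pg$nodes)
  if (dim < k)
    kgpr_stop(sprintf("embedding_dim %d < %d constrained entities", dim, k),
              "kgpr_bad_plan")
  mat <- matrix(NA_real_, nrow = length(names), ncol = dim,
                dimnames = list(names, NULL))
  if (k > 0) {
    eg <- eigen(pg$gram, symmetric = TRUE)
    if (min(eg$values) < -1e-9)
      kgpr_stop("planted cosine constraints are not PSD-completable",
                "kgpr_bad_plan")
    ev <- pmax(eg$values, 0)
    V <- eg$vectors %*% diag(sqrt(ev), nrow = k)
    V <- V / sqrt(rowSums(V^2))
    for (i in seq_len(k)) {
      if (!pg$nodes[i] %in% names) next
      mat[pg$nodes[i], ] <- c(V[i, ], rep(0, dim - k))
    }
  }
  free <- rownames(mat)[!stats::complete.cases(mat)]
  if (length(free)) {
    rnd <- with_plan_seed(plan, 202L, function()
      matrix(stats::rnorm(length(free) * dim), nrow = length(free)))
    rnd <- rnd / sqrt(rowSums(rnd^2))
    mat[free, ] <- rnd
  }
  embedding_store(mat)
}

#' Generate synthetic annotated documents
#'
#' Emits, for every co-mention plan entry `(a, b, n)`, exactly `n`
#' documents whose titles mention both entities, so
#' [build_cooccurrence()] on the output recovers the plan's pairwise
#' document counts exactly.
#'
#' @param plan a [fixture_plan()].
#' @return list of `annotated_document`.
#' @export
make_synthetic_documents <- function(plan) {
  stopifnot(inherits(plan, "fixture_plan"))
  docs <- list()
  serial <- 0L
  for (cm in plan$comentions) {
    for (r in seq_len(cm$n)) {
      serial <- serial + 1L
      title <- sprintf("A study of %s and %s.", cm$a, cm$b)
      s1 <- as.integer(regexpr(cm$a, title, fixed = TRUE)) - 1L
      s2 <- as.integer(regexpr(cm$b, title, fixed = TRUE)) - 1L
      mentions <- data.frame(
        start = c(s1, s2),
        end = c(s1 + nchar(cm$a), s2 + nchar(cm$b)),
        text = c(cm$a, cm$b),
        name = c(cm$a, cm$b),
        type = c(plan$types[[cm$a]], plan$types[[cm$b]]),
        identifier = "", stringsAsFactors = FALSE)
      docs[[serial]] <- annotated_document(sprintf("SYN%05d", serial),
                                           title, "", mentions)
    }
  }
  docs
}

#' Generate a synthetic synonym lexicon
#'
#' Builds a [synonym_lexicon()] from the plan's lexicon entries.
#'
#' @param plan a [fixture_plan()].
#' @return a `synonym_lexicon`.
#' @export
make_synthetic_lexicon <- function(plan) {
  stopifnot(inherits(plan, "fixture_plan"))
  if (length(plan$lexicon) == 0)
    return(synonym_lexicon(character(), character()))
  synonym_lexicon(
    canonical = vapply(plan$lexicon, `[[`, character(1), "canonical"),
    type = vapply(plan$lexicon, `[[`, character(1), "type"),
    synonyms = lapply(plan$lexicon, function(e)
      as.character(e$synonyms %||% character())))
}

#' Materialize a fixture plan as files
#'
#' Writes the four external formats the tool consumes into a directory:
#' `edges.csv` (typed edge table), `corpus.pubtator.txt` (annotated
#' documents), `lexicon.tsv` and `embeddings.vec.txt` (word2vec text).
#'
#' @param plan a [fixture_plan()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_files <- function(plan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(edges = file.path(dir, "edges.csv"),
             corpus = file.path(dir, "corpus.pubtator.txt"),
             lexicon = file.path(dir, "lexicon.tsv"),
             embeddings = file.path(dir, "embeddings.vec.txt"))
  write_edge_table(make_synthetic_kg(plan), paths[["edges"]])
  write_pubtator(make_synthetic_documents(plan), paths[["corpus"]])
  write_lexicon(make_synthetic_lexicon(plan), paths[["lexicon"]])
  write_word2vec(make_synthetic_embeddings(plan), paths[["embeddings"]])
  invisible(paths)
}
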