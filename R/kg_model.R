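#' Create an empty knowledge graph
#'
#' A knowledge graph is a typed multigraph: entities carry a type from
#' [kg_entity_types()] and edges a relation label from
#' [kg_relation_labels()].  Parallel edges between the same pair of
#' entities (different labels, or duplicate provenance of the same label)
#' coexist as distinct edge instances.  Stored edge orientation is
#' preserved from source files, but all queries (degree, ego networks,
#' path enumeration) traverse edges as undirected.
#'
#' Internally entities are a data frame with columns `id`, `name`, `type`,
#' `synonyms`, `sources` and edges a data frame with columns `head`,
#' `tail`, `label`, `weight`, `directed`; `head`/`tail` reference entity
#' ids.  The default id of an entity is `"<type>:<name>"`, so the same
#' surface name may exist once per type.
#'
#' @return an object of class `knowledge_graph`.
#' @examples
#' g <- kg_new()
#' g <- kg_add_entity(g, "ace", "gene")
#' kg_entity_count(g)
#' @export
kg_new <- function() {
  new_knowledge_graph(
    entities = data.frame(id = character(), name = character(),
                          type = character(), synonyms = character(),
                          sources = character(), stringsAsFactors = FALSE),
    edges = data.frame(head = character(), tail = character(),
                       label = character(), weight = numeric(),
                       directed = logical(), stringsAsFactors = FALSE))
}

new_knowledge_graph <- function(entities, edges) {
  structure(list(entities = entities, edges = edges),
            class = "knowledge_graph")
}

#' Default entity identifier
#'
#' @param name normalized entity name.
#' @param type canonical entity type.
#' @return character id of the form `"<type>:<name>"`.
#' @export
kg_entity_id <- function(name, type) paste(type, name, sep = ":")

join_set <- function(x) {
  x <- sort(unique(x[nzchar(x)]))
  paste(x, collapse = "|")
}

split_set <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) character() else
    strsplit(x, "|", fixed = TRUE)[[1]]
}

#' Add an entity to a knowledge graph
#'
#' Names are normalized with [normalize_name()] before insertion.  Adding
#' an identical entity twice is a no-op; re-adding an existing id with
#' extra synonyms or sources unions them; re-adding an existing id with a
#' different type or name is a conflict error.
#'
#' @param graph a `knowledge_graph`.
#' @param name entity display name (normalized internally).
#' @param type entity type, validated against [kg_entity_types()].
#' @param id entity id; defaults to [kg_entity_id()] of the normalized
#'   name and type.
#' @param synonyms,sources character vectors recorded with the entity.
#' @param allow_unknown_type accept types outside the closed vocabulary.
#' @return the updated `knowledge_graph`.
#' @export
kg_add_entity <- function(graph, name, type, id = NULL,
                          synonyms = character(), sources = character(),
                          allow_unknown_type = FALSE) {
  stopifnot(inherits(graph, "knowledge_graph"))
  nm <- normalize_name(name)
  if (!nzchar(nm)) kgpr_stop("entity name must be non-empty", "kgpr_bad_entity")
  ty <- normalize_entity_type(type, allow_unknown = allow_unknown_type)
  id <- id %||% kg_entity_id(nm, ty)
  i <- match(id, graph$entities$id)
  if (!is.na(i)) {
    if (graph$entities$type[i] != ty) {
      kgpr_stop(sprintf("entity id '%s' already present with type '%s' (got '%s')",
                        id, graph$entities$type[i], ty), "kgpr_conflict")
    }
    if (graph$entities$name[i] != nm) {
      kgpr_stop(sprintf("entity id '%s' already present with name '%s' (got '%s')",
                        id, graph$entities$name[i], nm), "kgpr_conflict")
    }
    graph$entities$synonyms[i] <-
      join_set(c(split_set(graph$entities$synonyms[i]), normalize_name(synonyms)))
    graph$entities$sources[i] <-
      join_set(c(split_set(graph$entities$sources[i]), sources))
    return(graph)
  }
  graph$entities <- rbind(graph$entities, data.frame(
    id = id, name = nm, type = ty,
    synonyms = join_set(normalize_name(synonyms)),
    sources = join_set(sources), stringsAsFactors = FALSE))
  graph
}

#' Add an edge to a knowledge graph
#'
#' Edges form a multiset: adding the identical edge twice yields two edge
#' instances, and distinct paths can later traverse each instance.
#' Self-loops are rejected.
#'
#' @param graph a `knowledge_graph`.
#' @param head,tail entity ids (both must already be present).
#' @param label relation label, validated against [kg_relation_labels()].
#' @param weight non-negative count; for `co_occur` edges the number of
#'   supporting documents.  Must be >= 1.
#' @param directed stored orientation flag; defaults to `TRUE` for curated
#'   relations and `FALSE` for `co_occur`.  Traversal ignores it.
#' @param allow_unknown_label accept labels outside the vocabulary.
#' @return the updated `knowledge_graph`.
#' @export
kg_add_edge <- function(graph, head, tail, label, weight = 1,
                        directed = NULL, allow_unknown_label = FALSE) {
  stopifnot(inherits(graph, "knowledge_graph"))
  lab <- normalize_relation_label(label, allow_unknown = allow_unknown_label)
  if (!head %in% graph$entities$id)
    kgpr_stop(sprintf("edge head '%s' is not an entity of the graph", head),
              "kgpr_missing_entity")
  if (!tail %in% graph$entities$id)
    kgpr_stop(sprintf("edge tail '%s' is not an entity of the graph", tail),
              "kgpr_missing_entity")
  if (identical(head, tail))
    kgpr_stop(sprintf("self-loop rejected on '%s'", head), "kgpr_self_loop")
  if (!is.numeric(weight) || weight < 1)
    kgpr_stop("edge weight must be >= 1", "kgpr_bad_edge")
  directed <- directed %||% (lab != "co_occur")
  graph$edges <- rbind(graph$edges, data.frame(
    head = head, tail = tail, label = lab, weight = as.numeric(weight),
    directed = directed, stringsAsFactors = FALSE))
  graph
}

#' Graph size queries
#'
#' `kg_entity_count()` and `kg_edge_count()` return total counts;
#' `kg_type_counts()` tabulates entities per type (the per-type counts
#' always sum to the total).
#'
#' @param graph a `knowledge_graph`.
#' @return integer scalar, or a named integer vector for
#'   `kg_type_counts()`.
#' @export
kg_entity_count <- function(graph) nrow(graph$entities)

#' @rdname kg_entity_count
#' @export
kg_edge_count <- function(graph) nrow(graph$edges)

#' @rdname kg_entity_count
#' @export
kg_type_counts <- function(graph) {
  tab <- table(graph$entities$type)
  out <- as.integer(tab)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

# Resolve an entity reference given as id or (unique) normalized name.
resolve_entity <- function(graph, x) {
  if (x %in% graph$entities$id) return(x)
  nm <- normalize_name(x)
  hits <- graph$entities$id[graph$entities$name == nm]
  if (length(hits) == 0)
    kgpr_stop(sprintf("unknown entity '%s'", x), "kgpr_missing_entity")
  if (length(hits) > 1)
    kgpr_stop(sprintf("ambiguous entity name '%s' (matches ids: %s); use an id",
                      x, paste(hits, collapse = ", ")), "kgpr_ambiguous_entity")
  hits
}

# Distinct undirected neighbor ids of an entity id.
kg_neighbors <- function(graph, id) {
  e <- graph$edges
  unique(c(e$tail[e$head == id], e$head[e$tail == id]))
}

#' Degree of an entity
#'
#' Degree is the number of distinct connected entities, not the edge
#' multiplicity: three parallel edges to the same neighbor contribute 1.
#' Edge orientation and labels are ignored.
#'
#' @param graph a `knowledge_graph`.
#' @param entity entity id or unique entity name.
#' @return non-negative integer.
#' @export
kg_degree <- function(graph, entity) {
  id <- resolve_entity(graph, entity)
  length(kg_neighbors(graph, id))
}

# Induced subgraph on a set of entity ids: all parent-graph edges whose
# both endpoints are retained stay (parallel instances included).
kg_subgraph <- function(graph, ids) {
  ents <- graph$entities[graph$entities$id %in% ids, , drop = FALSE]
  e <- graph$edges
  keep <- e$head %in% ids & e$tail %in% ids
  new_knowledge_graph(entities = ents, edges = e[keep, , drop = FALSE])
}

#' Ego-centered network
#'
#' Extracts the induced subgraph on all entities within `radius`
#' undirected hops of a center entity.  Hop counting ignores edge labels
#' and weights.  Every parent-graph edge between retained entities is
#' retained.  Each retained entity is annotated with its degree inside
#' the ego subgraph (column `degree` of the result's entity table), the
#' quantity used for node sizing when the subgraph is rendered.
#'
#' @param graph a `knowledge_graph`.
#' @param center entity id or unique name.
#' @param radius non-negative integer hop limit; `0` yields the center
#'   alone.
#' @return a `knowledge_graph` whose entity table carries a `degree`
#'   column.
#' @export
kg_ego <- function(graph, center, radius = 1) {
  id <- resolve_entity(graph, center)
  if (!is.numeric(radius) || radius < 0)
    kgpr_stop("radius must be a non-negative integer", "kgpr_bad_parameter")
  if (radius == 0 || kg_edge_count(graph) == 0) {
    keep <- id
  } else {
    ig <- as_igraph(graph)
    d <- igraph::distances(ig, v = id, weights = NA)[1, ]
    keep <- names(d)[is.finite(d) & d <= radius]
  }
  sub <- kg_subgraph(graph, keep)
  sub$entities$degree <- vapply(sub$entities$id, function(i)
    length(kg_neighbors(sub, i)), integer(1), USE.NAMES = FALSE)
  sub
}

#' Convert a knowledge graph to an igraph object
#'
#' The igraph vertex `name` attribute holds the entity id; `entity_name`
#' and `entity_type` hold the display name and type.  Edge attributes
#' `label`, `weight` and `orientation` are carried over.  The igraph is
#' undirected (matching traversal semantics) and keeps parallel edges.
#'
#' @param graph a `knowledge_graph`.
#' @return an `igraph` object.
#' @export
as_igraph <- function(graph) {
  v <- data.frame(name = graph$entities$id,
                  entity_name = graph$entities$name,
                  entity_type = graph$entities$type,
                  stringsAsFactors = FALSE)
  e <- data.frame(from = graph$edges$head, to = graph$edges$tail,
                  label = graph$edges$label, weight = graph$edges$weight,
                  orientation = graph$edges$directed,
                  stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d entities, %d edges\n",
              kg_entity_count(x), kg_edge_count(x)))
  tc <- kg_type_counts(x)
  if (length(tc))
    cat("  types:", paste(sprintf("%s=%d", names(tc), tc), collapse = " "), "\n")
  lc <- table(x$edges$label)
  if (length(lc))
    cat("  labels:", paste(sprintf("%s=%d", names(lc), as.integer(lc)),
                           collapse = " "), "\n")
  invisible(x)
}
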