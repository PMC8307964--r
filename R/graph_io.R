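#' Edge-table dialect
#'
#' Describes the layout of a delimited typed edge table.  `columns` maps
#' the logical fields `head`, `head_type`, `relation`, `tail`,
#' `tail_type`, `weight` to column names (when `header = TRUE`) or
#' 1-based positions.  `head`, `relation` and `tail` are mandatory;
#' `weight` defaults to 1 when absent.
#'
#' @param delimiter field separator, default comma.
#' @param header whether the first row names the columns.
#' @param columns named character or integer vector mapping logical
#'   fields to columns.
#' @return an object of class `edge_table_dialect`.
#' @export
edge_table_dialect <- function(delimiter = ",", header = TRUE,
                               columns = c(head = "head",
                                           head_type = "head_type",
                                           relation = "relation",
                                           tail = "tail",
                                           tail_type = "tail_type",
                                           weight = "weight")) {
  need <- c("head", "relation", "tail")
  if (!all(need %in% names(columns)))
    kgpr_stop("dialect must map the head, relation and tail columns",
              "kgpr_bad_dialect")
  structure(list(delimiter = delimiter, header = isTRUE(header),
                 columns = columns),
            class = "edge_table_dialect")
}

# Header-inspection dialect sniffing: choose the delimiter that splits the
# first line into the most fields, then look for recognizable header names;
# otherwise fall back to positional head,head_type,relation,tail,tail_type
# (plus weight when a sixth column exists).
sniff_edge_dialect <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) == 0)
    return(edge_table_dialect())
  delims <- c(",", "\t", ";")
  nfield <- vapply(delims, function(d)
    length(strsplit(first, d, fixed = TRUE)[[1]]), integer(1))
  delim <- delims[which.max(nfield)]
  fields <- tolower(trimws(strsplit(first, delim, fixed = TRUE)[[1]]))
  known <- c("head", "head_type", "relation", "tail", "tail_type", "weight",
             "source", "source_type", "target", "target_type", "label")
  if (any(fields %in% known)) {
    pick <- function(...) {
      for (cand in c(...)) if (cand %in% fields) return(cand)
      NA_character_
    }
    cols <- c(head = pick("head", "source"),
              head_type = pick("head_type", "source_type"),
              relation = pick("relation", "label"),
              tail = pick("tail", "target"),
              tail_type = pick("tail_type", "target_type"),
              weight = pick("weight"))
    cols <- cols[!is.na(cols)]
    return(edge_table_dialect(delimiter = delim, header = TRUE,
                              columns = cols))
  }
  n <- length(fields)
  cols <- c(head = 1L, head_type = 2L, relation = 3L, tail = 4L,
            tail_type = 5L)
  if (n >= 6) cols <- c(cols, weight = 6L)
  edge_table_dialect(delimiter = delim, header = FALSE, columns = cols[cols <= n])
}

pick_column <- function(df, columns, field) {
  if (!field %in% names(columns)) return(NULL)
  ref <- columns[[field]]
  if (is.character(ref)) {
    i <- match(tolower(ref), tolower(names(df)))
    if (is.na(i)) return(NULL)
  } else i <- as.integer(ref)
  if (i > ncol(df)) return(NULL)
  df[[i]]
}

#' Read a typed edge table into a knowledge graph
#'
#' One edge per row, preserved as-is including duplicate rows (multiset
#' semantics).  Entities are created on first mention with the row's
#' declared type; names are normalized with [normalize_name()].  In
#' strict mode, relation labels outside the 28-label vocabulary, entity
#' types outside the type vocabulary, rows with missing mandatory
#' fields, self-loop rows and surface names declared with two different
#' types all raise format errors (with the offending line); lenient mode
#' keeps unknown labels/types, treats a name seen with two types as two
#' distinct entities and drops self-loop rows with a warning.
#'
#' @param path file path of the delimited table.
#' @param dialect an [edge_table_dialect()]; sniffed from the header when
#'   `NULL`.
#' @param strict logical, see above.
#' @param source provenance tag recorded on the created entities
#'   (e.g. `"AG"`, `"CORD19"`).
#' @return a `knowledge_graph`.
#' @export
read_edge_table <- function(path, dialect = NULL, strict = TRUE,
                            source = "AG") {
  dialect <- dialect %||% sniff_edge_dialect(path)
  df <- tryCatch(
    utils::read.table(path, sep = dialect$delimiter,
                      header = dialect$header, quote = "\"",
                      comment.char = "", stringsAsFactors = FALSE,
                      colClasses = "character", check.names = FALSE,
                      blank.lines.skip = TRUE),
    error = function(e) kgpr_stop(paste("cannot parse edge table:",
                                        conditionMessage(e)), "kgpr_format"))
  if (nrow(df) == 0) return(kg_new())
  cols <- dialect$columns
  get <- function(field) pick_column(df, cols, field)
  for (f in c("head", "relation", "tail")) {
    if (is.null(get(f)))
      kgpr_stop(sprintf("edge table lacks mandatory column '%s'", f),
                "kgpr_format")
  }
  head_n <- get("head"); rel <- get("relation"); tail_n <- get("tail")
  line_of <- function(i) i + as.integer(dialect$header)
  miss <- is.na(head_n) | !nzchar(trimws(head_n)) |
          is.na(rel)    | !nzchar(trimws(rel)) |
          is.na(tail_n) | !nzchar(trimws(tail_n))
  if (any(miss))
    kgpr_stop(sprintf("edge table line %d: missing mandatory field",
                      line_of(which(miss)[1])), "kgpr_format")
  ht <- get("head_type"); tt <- get("tail_type")
  if (is.null(ht) || is.null(tt)) {
    if (strict)
      kgpr_stop("edge table lacks head_type/tail_type columns", "kgpr_format")
    ht <- ht %||% rep("unknown", nrow(df))
    tt <- tt %||% rep("unknown", nrow(df))
  }
  w <- get("weight")
  w <- if (is.null(w)) rep(1, nrow(df)) else {
    wn <- suppressWarnings(as.numeric(w))
    wn[is.na(wn)] <- 1
    wn
  }

  head_n <- normalize_name(head_n); tail_n <- normalize_name(tail_n)
  ht <- normalize_entity_type(ht, allow_unknown = !strict)
  tt <- normalize_entity_type(tt, allow_unknown = !strict)
  rel <- normalize_relation_label(rel, allow_unknown = !strict)

  loop <- head_n == tail_n & ht == tt
  if (any(loop)) {
    if (strict)
      kgpr_stop(sprintf("edge table line %d: self-loop row",
                        line_of(which(loop)[1])), "kgpr_self_loop")
    warning(sprintf("dropping %d self-loop row(s)", sum(loop)))
    keep <- !loop
    head_n <- head_n[keep]; tail_n <- tail_n[keep]
    ht <- ht[keep]; tt <- tt[keep]; rel <- rel[keep]; w <- w[keep]
  }

  enames <- c(head_n, tail_n)
  etypes <- c(ht, tt)
  if (strict) {
    ntype <- tapply(etypes, enames, function(t) length(unique(t)))
    if (any(ntype > 1))
      kgpr_stop(sprintf("entity '%s' declared with conflicting types",
                        names(ntype)[ntype > 1][1]), "kgpr_conflict")
  }
  ekey <- paste(etypes, enames, sep = ":")
  first <- !duplicated(ekey)
  entities <- data.frame(id = ekey[first], name = enames[first],
                         type = etypes[first],
                         synonyms = "", sources = source,
                         stringsAsFactors = FALSE)
  entities <- entities[order(entities$id), , drop = FALSE]
  rownames(entities) <- NULL
  edges <- data.frame(head = paste(ht, head_n, sep = ":"),
                      tail = paste(tt, tail_n, sep = ":"),
                      label = rel, weight = pmax(w, 1),
                      directed = rel != "co_occur",
                      stringsAsFactors = FALSE)
  new_knowledge_graph(entities = entities, edges = edges)
}

#' Write a knowledge graph as a typed edge table
#'
#' Inverse of [read_edge_table()] under the default dialect: columns
#' `head,head_type,relation,tail,tail_type,weight`, one row per edge
#' instance.
#'
#' @param graph a `knowledge_graph`.
#' @param path output file path.
#' @param delimiter field separator.
#' @return the path, invisibly.
#' @export
write_edge_table <- function(graph, path, delimiter = ",") {
  i <- match(graph$edges$head, graph$entities$id)
  j <- match(graph$edges$tail, graph$entities$id)
  df <- data.frame(head = graph$entities$name[i],
                   head_type = graph$entities$type[i],
                   relation = graph$edges$label,
                   tail = graph$entities$name[j],
                   tail_type = graph$entities$type[j],
                   weight = graph$edges$weight,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Parse and render printed path records
#'
#' A path record is the textual form `node--label--node--label--...--node`
#' used to print ranked paths: node names alternate with relation labels,
#' separated by exactly two hyphens (node names themselves may contain
#' single hyphens and spaces, e.g. `"il-6 receptor"`).  Node names are
#' normalized with [normalize_name()] and labels lowercased, so the
#' spellings `"Il-6_receptor"` and `"il-6 receptor"` parse to the same
#' node.
#'
#' @param text a single path-record string.
#' @return `parse_path_record()` returns a `kg_path` (fields `nodes`,
#'   `labels`, `depth`); `render_path_record()` its inverse string.
#' @examples
#' p <- parse_path_record("a--co_occur--b--gene_gene--c")
#' p$depth  # 2
#' @export
parse_path_record <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  toks <- trimws(strsplit(text, "--", fixed = TRUE)[[1]])
  if (length(toks) < 3 || length(toks) %% 2 == 0)
    kgpr_stop("path record must have an odd number (>= 3) of '--'-separated tokens",
              "kgpr_parse")
  if (any(!nzchar(toks)))
    kgpr_stop("path record contains an empty token", "kgpr_parse")
  odd <- seq(1, length(toks), by = 2)
  kg_path(nodes = normalize_name(toks[odd]),
          labels = tolower(toks[-odd]))
}

#' @rdname parse_path_record
#' @param path a `kg_path`.
#' @export
render_path_record <- function(path) {
  stopifnot(inherits(path, "kg_path"))
  n <- length(path$nodes)
  out <- character(2 * n - 1)
  out[seq(1, 2 * n - 1, by = 2)] <- path$nodes
  out[seq(2, 2 * n - 2, by = 2)] <- path$labels
  paste(out, collapse = "--")
}

#' Simple path objects
#'
#' A `kg_path` holds an ordered node-name sequence and the relation
#' labels of the traversed edges; its depth is the number of edges (a
#' depth-2 path has three nodes).
#'
#' @param nodes character vector of normalized node names (length
#'   `depth + 1`).
#' @param labels character vector of relation labels (length `depth`).
#' @return an object of class `kg_path`.
#' @export
kg_path <- function(nodes, labels) {
  if (length(nodes) != length(labels) + 1 || length(labels) < 1)
    kgpr_stop("a path needs d >= 1 labels and d + 1 nodes", "kgpr_bad_path")
  structure(list(nodes = as.character(nodes),
                 labels = as.character(labels),
                 depth = length(labels)),
            class = "kg_path")
}

#' @export
print.kg_path <- function(x, ...) {
  cat(sprintf("<kg_path depth %d> %s\n", x$depth, render_path_record(x)))
  invisible(x)
}

#' GraphML export / import
#'
#' `write_graphml()` serializes a knowledge graph as GraphML with node
#' attributes `entity_name`, `entity_type` and `degree` (distinct
#' neighbors, used for node sizing in viewers) and edge attributes
#' `label` and `weight`.  `read_graphml()` reads the same layout back;
#' a write-then-read round trip preserves entity and edge counts and
#' per-label edge counts.
#'
#' @param graph a `knowledge_graph`.
#' @param path file path.
#' @return `write_graphml()` the path invisibly; `read_graphml()` a
#'   `knowledge_graph`.
#' @export
write_graphml <- function(graph, path) {
  ig <- as_igraph(graph)
  deg <- vapply(graph$entities$id, function(i)
    length(kg_neighbors(graph, i)), integer(1), USE.NAMES = FALSE)
  igraph::V(ig)$degree <- deg
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(ig)
  n <- igraph::vcount(ig)
  ids <- va$name %||% as.character(seq_len(n))
  entities <- data.frame(
    id = ids,
    name = va$entity_name %||% ids,
    type = va$entity_type %||% rep("unknown", n),
    synonyms = rep("", n), sources = rep("", n),
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(ig, names = TRUE)
  ea <- igraph::edge_attr(ig)
  m <- nrow(el)
  edges <- data.frame(
    head = if (m) el[, 1] else character(),
    tail = if (m) el[, 2] else character(),
    label = ea$label %||% rep("co_occur", m),
    weight = as.numeric(ea$weight %||% rep(1, m)),
    directed = as.logical(ea$orientation %||% rep(FALSE, m)),
    stringsAsFactors = FALSE)
  new_knowledge_graph(entities = entities, edges = edges)
}
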