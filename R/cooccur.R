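#' Build co-occurrence edges from annotated documents
#'
#' Two entities co-occur when both are mentioned in the same document's
#' title or abstract; each such document increases the pair's count by
#' one, regardless of how often either entity is mentioned within it
#' (per-document counting is binary).  Entities are `(name, type)`
#' pairs: the same surface name under two types is two distinct
#' entities, and they can co-occur with each other.  Output pairs are
#' canonicalized lexicographically (by name, then type) so results are
#' deterministic.
#'
#' @param docs list of `annotated_document`.
#' @param min_weight keep only pairs co-mentioned in at least this many
#'   documents (default 1, i.e. no thresholding).
#' @return data frame with columns `head_name`, `head_type`,
#'   `tail_name`, `tail_type`, `label` (always `"co_occur"`) and
#'   `weight` (number of supporting documents).
#' @export
build_cooccurrence <- function(docs, min_weight = 1) {
  if (!is.numeric(min_weight) || min_weight < 1)
    kgpr_stop("min_weight must be a positive integer", "kgpr_bad_parameter")
  keys <- character()
  for (d in docs) {
    m <- d$mentions
    if (nrow(m) == 0) next
    ent <- unique(paste(m$name, m$type, sep = "\t"))
    if (length(ent) < 2) next
    ent <- sort(ent)
    pr <- utils::combn(ent, 2)
    keys <- c(keys, paste(pr[1, ], pr[2, ], sep = "\r"))
  }
  if (length(keys) == 0)
    return(data.frame(head_name = character(), head_type = character(),
                      tail_name = character(), tail_type = character(),
                      label = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  tab <- table(keys)
  tab <- tab[tab >= min_weight]
  pair <- strsplit(names(tab), "\r", fixed = TRUE)
  a <- strsplit(vapply(pair, `[`, character(1), 1), "\t", fixed = TRUE)
  b <- strsplit(vapply(pair, `[`, character(1), 2), "\t", fixed = TRUE)
  out <- data.frame(
    head_name = vapply(a, `[`, character(1), 1),
    head_type = vapply(a, `[`, character(1), 2),
    tail_name = vapply(b, `[`, character(1), 1),
    tail_type = vapply(b, `[`, character(1), 2),
    label = "co_occur", weight = as.numeric(tab),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$head_name, out$head_type, out$tail_name, out$tail_type), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Co-occurrence knowledge graph
#'
#' Builds (or extends) a knowledge graph whose entities are all
#' mentioned `(name, type)` pairs — including entities mentioned alone —
#' and whose edges are the [build_cooccurrence()] output.
#'
#' @param docs list of `annotated_document`.
#' @param base optional `knowledge_graph` to extend; a fresh one by
#'   default.
#' @param min_weight passed to [build_cooccurrence()].
#' @param source provenance tag recorded on created entities.
#' @return a `knowledge_graph`.
#' @export
cooccurrence_graph <- function(docs, base = NULL, min_weight = 1,
                               source = "CORD19") {
  g <- base %||% kg_new()
  for (d in docs) {
    m <- d$mentions
    if (nrow(m) == 0) next
    u <- !duplicated(paste(m$name, m$type))
    for (i in which(u))
      g <- kg_add_entity(g, m$name[i], m$type[i], sources = source,
                         allow_unknown_type = TRUE)
  }
  co <- build_cooccurrence(docs, min_weight = min_weight)
  for (i in seq_len(nrow(co))) {
    g <- kg_add_edge(g,
                     kg_entity_id(co$head_name[i], co$head_type[i]),
                     kg_entity_id(co$tail_name[i], co$tail_type[i]),
                     "co_occur", weight = co$weight[i], directed = FALSE)
  }
  g
}
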