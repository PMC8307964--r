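#' Normalize an entity name
#'
#' Lowercases, maps underscores to spaces, collapses internal whitespace
#' and strips leading/trailing whitespace.  The underscore rule makes
#' spellings like `"Il-6_receptor"` and `"il-6 receptor"` — two surface
#' forms of the same entity — identical after normalization.
#'
#' @param raw character vector.
#' @return character vector of normalized names.
#' @examples
#' normalize_name("Il-6_receptor")  # "il-6 receptor"
#' @export
normalize_name <- function(raw) {
  x <- tolower(as.character(raw))
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Normalized string similarity
#'
#' Default metric for entity disambiguation: normalized Levenshtein
#' similarity `1 - dist(a, b) / max(nchar(a), nchar(b))`, in `[0, 1]`.
#' Identical strings score 1 (two empty strings are defined as identical);
#' the metric is symmetric.  Vectorized over its arguments with the usual
#' recycling.
#'
#' @param a,b character vectors of normalized strings.
#' @return numeric vector of similarities in `[0, 1]`.
#' @examples
#' string_similarity("kitten", "sitting")  # 1 - 3/7
#' @export
string_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  d <- diag(utils::adist(a, b))
  m <- pmax(nchar(a), nchar(b))
  ifelse(m == 0, 1, 1 - d / m)
}

#' Merge configuration
#'
#' Parameters governing entity disambiguation and graph merging.  The
#' similarity threshold was calibrated manually in the study this
#' framework reproduces and is therefore a first-class parameter here.
#'
#' @param threshold minimum similarity in `[0, 1]` for linking an entity
#'   to a lexicon term; exact matches (score 1) always link.
#' @param metric `"levenshtein"` (default, [string_similarity()]) or a
#'   function `(a, b) -> similarity` vectorized like it.
#' @param type_equivalence treat `chemical`/`compound` and
#'   `species`/`organism` as interchangeable type pairs when matching.
#'   Off by default: merged-graph statistics keep chemical and compound
#'   as separate types, so the conservative reading is identical types
#'   only.
#' @return an object of class `merge_config`.
#' @export
merge_config <- function(threshold = 0.95, metric = "levenshtein",
                         type_equivalence = FALSE) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    kgpr_stop("threshold must be in [0, 1]", "kgpr_bad_parameter")
  fn <- if (is.function(metric)) metric
        else if (identical(metric, "levenshtein")) string_similarity
        else kgpr_stop(sprintf("unknown similarity metric '%s'", metric),
                       "kgpr_bad_parameter")
  structure(list(threshold = threshold, metric = fn,
                 type_equivalence = isTRUE(type_equivalence)),
            class = "merge_config")
}

# Type equivalence class representative used for candidate matching.
merge_type_class <- function(type, equivalence) {
  if (!equivalence) return(type)
  cls <- c(chemical = "compound", organism = "species")
  out <- type
  hit <- type %in% names(cls)
  out[hit] <- cls[type[hit]]
  out
}

#' Read / construct a synonym lexicon
#'
#' A synonym lexicon maps canonical terms to their synonyms, per entity
#' type.  `read_lexicon()` parses the tab-delimited file format
#' `canonical<TAB>type<TAB>synonym1|synonym2|...` (the synonym field may
#' be empty); `synonym_lexicon()` builds one from vectors.  Canonical
#' terms must be unique within a type; a synonym may appear under several
#' canonicals (ties are broken deterministically by [link_entities()]).
#'
#' @param path file path.
#' @param canonical,type character vectors (recycled against each other).
#' @param synonyms list of character vectors, one per canonical.
#' @param allow_unknown_type accept types outside [kg_entity_types()].
#' @return an object of class `synonym_lexicon`: a data frame with
#'   columns `canonical`, `type` and list-column `synonyms`, all
#'   normalized.
#' @export
synonym_lexicon <- function(canonical, type, synonyms = NULL,
                            allow_unknown_type = FALSE) {
  canonical <- normalize_name(canonical)
  type <- normalize_entity_type(type, allow_unknown = allow_unknown_type)
  if (is.null(synonyms)) synonyms <- rep(list(character()), length(canonical))
  stopifnot(length(synonyms) == length(canonical),
            length(type) == length(canonical))
  synonyms <- lapply(synonyms, function(s) sort(unique(normalize_name(s))))
  key <- paste(canonical, type)
  if (anyDuplicated(key))
    kgpr_stop("canonical terms must be unique within a type", "kgpr_bad_lexicon")
  lex <- data.frame(canonical = canonical, type = type,
                    stringsAsFactors = FALSE)
  lex$synonyms <- synonyms
  structure(lex, class = c("synonym_lexicon", "data.frame"))
}

#' @rdname synonym_lexicon
#' @export
read_lexicon <- function(path, allow_unknown_type = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(synonym_lexicon(character(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 2
  if (any(bad))
    kgpr_stop(sprintf("lexicon line %d: expected at least 2 tab-separated fields",
                      which(bad)[1]), "kgpr_format")
  canonical <- vapply(parts, `[`, character(1), 1)
  type <- vapply(parts, `[`, character(1), 2)
  syn <- lapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) strsplit(p[3], "|", fixed = TRUE)[[1]]
    else character())
  synonym_lexicon(canonical, type, syn, allow_unknown_type = allow_unknown_type)
}

#' @rdname synonym_lexicon
#' @param lexicon a `synonym_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  lines <- vapply(seq_len(nrow(lexicon)), function(i)
    paste(lexicon$canonical[i], lexicon$type[i],
          paste(lexicon$synonyms[[i]], collapse = "|"), sep = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Link entities to canonical lexicon terms
#'
#' Each entity `(name, type)` is compared against all same-type lexicon
#' entries; the candidate score of an entry is the maximum similarity of
#' the entity name to the entry's canonical term or any of its synonyms.
#' The entity links to the best-scoring entry with score >= the
#' threshold; exact matches always link.  Unlinked entities keep their
#' own name as canonical.  Ties break deterministically: higher score
#' first, then lexicographically smaller canonical term.
#'
#' @param entities a `knowledge_graph` or a data frame with columns
#'   `name` and `type` (normalized).
#' @param lexicon a `synonym_lexicon`.
#' @param config a [merge_config()].
#' @return an `entity_mapping`: data frame with columns `name`, `type`,
#'   `canonical`, `score` (NA when unlinked) and `linked`.
#' @export
link_entities <- function(entities, lexicon, config = merge_config()) {
  if (inherits(entities, "knowledge_graph")) entities <- entities$entities
  stopifnot(all(c("name", "type") %in% names(entities)))
  n <- nrow(entities)
  out <- data.frame(name = entities$name, type = entities$type,
                    canonical = entities$name, score = rep(NA_real_, n),
                    linked = rep(FALSE, n), stringsAsFactors = FALSE)
  if (n == 0 || nrow(lexicon) == 0)
    return(structure(out, class = c("entity_mapping", "data.frame")))

  ecls <- merge_type_class(entities$type, config$type_equivalence)
  lcls <- merge_type_class(lexicon$type, config$type_equivalence)
  # candidate strings: one row per (lexicon entry, surface form)
  cand <- data.frame(
    entry = rep(seq_len(nrow(lexicon)),
                vapply(lexicon$synonyms, length, integer(1)) + 1L),
    stringsAsFactors = FALSE)
  cand$string <- unlist(Map(function(c, s) c(c, s),
                            lexicon$canonical, lexicon$synonyms),
                        use.names = FALSE)
  for (cl in unique(ecls)) {
    ei <- which(ecls == cl)
    ci <- which(lcls[cand$entry] == cl)
    if (length(ci) == 0) next
    sim <- 1 - utils::adist(entities$name[ei], cand$string[ci]) /
      outer(nchar(entities$name[ei]), nchar(cand$string[ci]), pmax)
    sim[is.nan(sim)] <- 1  # both strings empty
    for (k in seq_along(ei)) {
      s <- sim[k, ]
      # best score per lexicon entry, then deterministic tie-break
      entry <- cand$entry[ci]
      best <- tapply(s, entry, max)
      canon <- lexicon$canonical[as.integer(names(best))]
      ord <- order(-best, canon)
      top <- ord[1]
      if (best[top] >= config$threshold) {
        i <- ei[k]
        out$canonical[i] <- canon[top]
        out$score[i] <- best[top]
        out$linked[i] <- TRUE
      }
    }
  }
  structure(out, class = c("entity_mapping", "data.frame"))
}

# Identity mapping (every entity is its own canonical term).
identity_mapping <- function(entities) {
  if (inherits(entities, "knowledge_graph")) entities <- entities$entities
  structure(data.frame(name = entities$name, type = entities$type,
                       canonical = entities$name,
                       score = rep(NA_real_, nrow(entities)),
                       linked = rep(FALSE, nrow(entities)),
                       stringsAsFactors = FALSE),
            class = c("entity_mapping", "data.frame"))
}

#' Merge two knowledge graphs under an entity mapping
#'
#' Entities of both graphs are rewritten to their canonical term (same
#' type); two or more entities linking to the same `(canonical, type)`
#' collapse into one merged entity that records the union of synonyms
#' (including the absorbed surface names) and sources.  Every edge is
#' re-wired to canonical endpoints.  `co_occur` edges between the same
#' canonical pair are combined by summing their document counts;
#' parallel curated edges are all retained as-is.  Edges whose endpoints
#' collapse onto the same entity become self-loops and are dropped (the
#' count is reported).
#'
#' @param g1,g2 `knowledge_graph` objects.
#' @param mapping an `entity_mapping` from [link_entities()]; entities
#'   absent from it map to themselves.  Linked entities of different
#'   types must not share a canonical term.
#' @return the merged `knowledge_graph`, with a bookkeeping list in
#'   `attr(, "merge_report")`: entity/edge counts in and out, entities
#'   absorbed, `co_occur` instances combined and self-loops dropped.
#' @export
merge_graphs <- function(g1, g2, mapping = NULL) {
  stopifnot(inherits(g1, "knowledge_graph"), inherits(g2, "knowledge_graph"))
  ents <- rbind(g1$entities, g2$entities)
  if (is.null(mapping)) mapping <- identity_mapping(ents)

  mkey <- paste(mapping$name, mapping$type, sep = "\t")
  if (any(mapping$linked)) {
    lk <- mapping[mapping$linked, , drop = FALSE]
    ntype <- tapply(lk$type, lk$canonical, function(t) length(unique(t)))
    if (any(ntype > 1))
      kgpr_stop(sprintf(
        "mapping links entities of different types to canonical '%s'",
        names(ntype)[ntype > 1][1]), "kgpr_conflict")
  }

  ekey <- paste(ents$name, ents$type, sep = "\t")
  mi <- match(ekey, mkey)
  canon <- ifelse(is.na(mi), ents$name, mapping$canonical[mi])
  new_id <- kg_entity_id(canon, ents$type)

  # merged entity table, one row per (canonical, type)
  idx_by_id <- split(seq_len(nrow(ents)), new_id)
  me <- data.frame(
    id = names(idx_by_id),
    name = vapply(idx_by_id, function(i) canon[i[1]], character(1)),
    type = vapply(idx_by_id, function(i) ents$type[i[1]], character(1)),
    synonyms = vapply(idx_by_id, function(i) {
      syn <- unlist(lapply(ents$synonyms[i], split_set), use.names = FALSE)
      join_set(c(syn, setdiff(ents$name[i], canon[i[1]])))
    }, character(1)),
    sources = vapply(idx_by_id, function(i)
      join_set(unlist(lapply(ents$sources[i], split_set), use.names = FALSE)),
      character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  me <- me[order(me$id), , drop = FALSE]
  rownames(me) <- NULL

  entities_absorbed <- nrow(ents) - nrow(me)

  # re-wire edges to canonical ids
  edges <- rbind(g1$edges, g2$edges)
  edges_in <- nrow(edges)
  old_ids <- ents$id
  src <- c(rep("g1", nrow(g1$entities)), rep("g2", nrow(g2$entities)))
  map_g1 <- new_id[src == "g1"]; names(map_g1) <- old_ids[src == "g1"]
  map_g2 <- new_id[src == "g2"]; names(map_g2) <- old_ids[src == "g2"]
  n1 <- nrow(g1$edges)
  edges$head <- c(unname(map_g1[edges$head[seq_len(n1)]]),
                  unname(map_g2[edges$head[seq_len(nrow(edges)) > n1]]))
  edges$tail <- c(unname(map_g1[edges$tail[seq_len(n1)]]),
                  unname(map_g2[edges$tail[seq_len(nrow(edges)) > n1]]))

  loop <- edges$head == edges$tail
  self_loops_dropped <- sum(loop)
  edges <- edges[!loop, , drop = FALSE]

  co <- edges$label == "co_occur"
  cooc <- edges[co, , drop = FALSE]
  rest <- edges[!co, , drop = FALSE]
  cooccur_combined <- 0L
  if (nrow(cooc) > 0) {
    a <- pmin(cooc$head, cooc$tail)
    b <- pmax(cooc$head, cooc$tail)
    w <- tapply(cooc$weight, paste(a, b, sep = "\r"), sum)
    pair <- strsplit(names(w), "\r", fixed = TRUE)
    cooc2 <- data.frame(
      head = vapply(pair, `[`, character(1), 1),
      tail = vapply(pair, `[`, character(1), 2),
      label = "co_occur", weight = as.numeric(w), directed = FALSE,
      row.names = NULL, stringsAsFactors = FALSE)
    cooccur_combined <- nrow(cooc) - nrow(cooc2)
    cooc <- cooc2
  }
  out_edges <- rbind(rest, cooc)
  out_edges <- out_edges[order(out_edges$head, out_edges$tail,
                               out_edges$label), , drop = FALSE]
  rownames(out_edges) <- NULL

  g <- new_knowledge_graph(entities = me, edges = out_edges)
  attr(g, "merge_report") <- list(
    entities_in = nrow(ents), entities_out = nrow(me),
    entities_absorbed = entities_absorbed,
    edges_in = edges_in, edges_out = nrow(out_edges),
    cooccur_combined = as.integer(cooccur_combined),
    self_loops_dropped = as.integer(self_loops_dropped))
  g
}
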