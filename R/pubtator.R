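#' Annotated documents
#'
#' One publication's title and abstract together with its entity
#' mentions.  Mentions are `(name, type)` pairs with character spans;
#' the same name may be mentioned repeatedly.  Two mentions with the
#' same surface name but different entity types are distinct entities.
#'
#' @param doc_id document identifier (PMID or synthetic id).
#' @param title,abstract text fields.
#' @param mentions data frame with columns `start`, `end`, `text`,
#'   `name` (normalized), `type` (canonical entity type) and
#'   `identifier`.
#' @return an object of class `annotated_document`.
#' @export
annotated_document <- function(doc_id, title, abstract = "",
                               mentions = NULL) {
  if (is.null(mentions))
    mentions <- data.frame(start = integer(), end = integer(),
                           text = character(), name = character(),
                           type = character(), identifier = character(),
                           stringsAsFactors = FALSE)
  structure(list(doc_id = as.character(doc_id), title = title,
                 abstract = abstract, mentions = mentions),
            class = "annotated_document")
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document %s> %d mention(s)\n  %s\n",
              x$doc_id, nrow(x$mentions), x$title))
  invisible(x)
}

#' Read PubTator-format annotations
#'
#' Parses the standard PubTator export: for each document a
#' `PMID|t|<title>` line, a `PMID|a|<abstract>` line, then one
#' tab-separated mention line per entity occurrence
#' (`PMID<TAB>start<TAB>end<TAB>text<TAB>type[<TAB>identifier]`),
#' documents separated by blank lines.  Mention text is normalized with
#' [normalize_name()] and the mention type mapped into the entity-type
#' vocabulary.  A mention line referencing a PMID whose title has not
#' been seen, non-numeric or inverted offsets, and spans beyond the
#' title+abstract bounds are format errors.
#'
#' @param path file path.
#' @param allow_unknown_type keep mention types outside the vocabulary.
#' @return list of `annotated_document`, in file order.
#' @export
read_pubtator <- function(path, allow_unknown_type = FALSE) {
  lines <- readLines(path, warn = FALSE)
  docs <- list()
  cur <- NULL
  flush <- function(cur, docs) {
    if (is.null(cur)) return(docs)
    m <- do.call(rbind, cur$mentions) %||%
      data.frame(start = integer(), end = integer(), text = character(),
                 name = character(), type = character(),
                 identifier = character(), stringsAsFactors = FALSE)
    docs[[length(docs) + 1]] <-
      annotated_document(cur$doc_id, cur$title %||% "", cur$abstract %||% "", m)
    docs
  }
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (!nzchar(trimws(line))) {
      docs <- flush(cur, docs); cur <- NULL
      next
    }
    tm <- regmatches(line, regexec("^([^|\t]+)\\|t\\|(.*)$", line))[[1]]
    am <- regmatches(line, regexec("^([^|\t]+)\\|a\\|(.*)$", line))[[1]]
    if (length(tm) == 3) {
      if (!is.null(cur) && cur$doc_id != tm[2]) {
        docs <- flush(cur, docs); cur <- NULL
      }
      if (is.null(cur)) cur <- list(doc_id = tm[2], mentions = list())
      cur$title <- tm[3]
      next
    }
    if (length(am) == 3) {
      if (is.null(cur) || cur$doc_id != am[2])
        kgpr_stop(sprintf("line %d: abstract for unseen document '%s'",
                          k, am[2]), "kgpr_format")
      cur$abstract <- am[3]
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5)
      kgpr_stop(sprintf("line %d: malformed mention line", k), "kgpr_format")
    if (is.null(cur) || cur$doc_id != f[1])
      kgpr_stop(sprintf("line %d: mention references unseen document '%s'",
                        k, f[1]), "kgpr_format")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || end < start)
      kgpr_stop(sprintf("line %d: malformed mention offsets", k), "kgpr_format")
    bound <- nchar(cur$title %||% "") + nchar(cur$abstract %||% "") + 1L
    if (end > bound)
      kgpr_stop(sprintf("line %d: mention span beyond title+abstract", k),
                "kgpr_format")
    cur$mentions[[length(cur$mentions) + 1]] <- data.frame(
      start = start, end = end, text = f[4],
      name = normalize_name(f[4]),
      type = normalize_entity_type(f[5], allow_unknown = allow_unknown_type),
      identifier = if (length(f) >= 6) f[6] else "",
      stringsAsFactors = FALSE)
  }
  flush(cur, docs)
}

#' Write annotated documents in PubTator format
#'
#' Inverse of [read_pubtator()]; useful for emitting synthetic corpora.
#'
#' @param docs list of `annotated_document`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_pubtator <- function(docs, path) {
  out <- character()
  for (d in docs) {
    out <- c(out,
             sprintf("%s|t|%s", d$doc_id, d$title),
             sprintf("%s|a|%s", d$doc_id, d$abstract))
    if (nrow(d$mentions))
      out <- c(out, sprintf("%s\t%d\t%d\t%s\t%s\t%s", d$doc_id,
                            d$mentions$start, d$mentions$end,
                            d$mentions$text, d$mentions$type,
                            d$mentions$identifier))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
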