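#' Bundled reference path listings
#'
#' The package ships, as plain text under `inst/extdata/`, the published
#' top-ranked path listings of the two demonstration queries on the
#' full-scale merged coronavirus KG: IL-6 receptor to hydroxychloroquine
#' and STAT1 to chloroquine.  Each record is a printed path in the
#' `node--label--node` syntax with the depth it was listed under and its
#' cosine-sum score.  They serve as desk-scale worked examples: parsing
#' them and counting records, edges and distinct relationships exercises
#' the path-record machinery without any download.
#'
#' @param which which listing to load.
#' @return data frame with columns `depth` (the listed depth), `record`
#'   (raw path text), `score`, plus `parsed_depth` (edge count after
#'   parsing; one listed record deviates from its printed depth label).
#' @export
reference_path_listing <- function(which = c("il6_receptor_hydroxychloroquine",
                                             "stat1_chloroquine")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("top_paths_", which, ".tsv"),
                      package = "kgpathrank", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  names(df) <- c("depth", "record", "score")
  df$parsed_depth <- vapply(df$record, function(r)
    parse_path_record(r)$depth, numeric(1), USE.NAMES = FALSE)
  df
}
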