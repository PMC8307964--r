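Package: kgpathrank
Title: Typed Biomedical Knowledge Graphs with Embedding-Scored Path Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds typed biomedical knowledge graphs from heterogeneous
    sources: a curated relation table of chemogenomic edges and literature
    entity annotations in PubTator format. Literature co-mentions become
    weighted co-occurrence edges; the two graphs are merged through
    type-constrained synonym disambiguation against a lexicon. The merged
    multigraph supports ego-network extraction and a fixed-depth
    path-ranking framework for hypothesis generation: simple paths of an
    exact depth between two entities are enumerated, scored by summed
    cosine similarity of consecutive node word embeddings, and filtered to
    the top percentile of the per-depth score distribution. Deterministic
    synthetic-fixture generators (graphs, annotated documents, synonym
    lexica, and embeddings with planted pairwise cosines) make every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
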