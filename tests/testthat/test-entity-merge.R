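test_that("name normalization lowercases and maps underscores to spaces", {
  expect_equal(normalize_name("Il-6_receptor"), "il-6 receptor")
  expect_equal(normalize_name("  ACE  "), "ace")
  expect_equal(normalize_name(""), "")
  expect_equal(normalize_name("a   b\tc"), "a b c")
})

test_that("string similarity is normalized Levenshtein", {
  expect_equal(string_similarity("ace", "ace"), 1)
  expect_equal(string_similarity("ace", "xyz"), 0)
  expect_equal(string_similarity("kitten", "sitting"), 1 - 3 / 7)
  expect_equal(string_similarity("", ""), 1)
  # symmetric, and consistent with a DP oracle
  set.seed(11)
  alphabet <- letters[1:6]
  for (i in 1:25) {
    a <- paste(sample(alphabet, sample(0:8, 1), TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(0:8, 1), TRUE), collapse = "")
    expect_equal(string_similarity(a, b), string_similarity(b, a))
    m <- max(nchar(a), nchar(b))
    expected <- if (m == 0) 1 else 1 - oracle_levenshtein(a, b) / m
    expect_equal(string_similarity(a, b), expected)
  }
})

test_that("entities link to same-type lexicon terms via synonyms", {
  lex <- synonym_lexicon(
    canonical = c("cited1", "breast cancer"),
    type = c("gene", "disease"),
    synonyms = list("msg1", "breast carcinoma"))
  cfg <- merge_config(threshold = 0.95)
  ents <- data.frame(name = c("msg1", "breast carcinoma", "msg1"),
                     type = c("gene", "disease", "disease"),
                     stringsAsFactors = FALSE)
  m <- link_entities(ents, lex, cfg)
  expect_equal(m$canonical, c("cited1", "breast cancer", "msg1"))
  expect_equal(m$linked, c(TRUE, TRUE, FALSE))
  expect_equal(m$score[1:2], c(1, 1))
})

test_that("threshold 1 links only exact surface matches", {
  lex <- synonym_lexicon("interleukin 6", "gene", list(c("il6", "il-6")))
  cfg1 <- merge_config(threshold = 1)
  m <- link_entities(data.frame(name = c("il6", "il-7", "interleukin 6"),
                                type = "gene", stringsAsFactors = FALSE),
                     lex, cfg1)
  expect_equal(m$linked, c(TRUE, FALSE, TRUE))
  # the near-miss links once the threshold drops
  m2 <- link_entities(data.frame(name = "il-7", type = "gene",
                                 stringsAsFactors = FALSE),
                      lex, merge_config(threshold = 0.7))
  expect_true(m2$linked)
  expect_equal(m2$canonical, "interleukin 6")
})

test_that("tie-breaking is deterministic: score first, then canonical", {
  lex <- synonym_lexicon(c("zeta", "alpha"), c("gene", "gene"),
                         list("shared", "shared"))
  m <- link_entities(data.frame(name = "shared", type = "gene",
                                stringsAsFactors = FALSE),
                     lex, merge_config())
  expect_equal(m$canonical, "alpha")
  m2 <- link_entities(data.frame(name = "shared", type = "gene",
                                 stringsAsFactors = FALSE),
                      lex, merge_config())
  expect_identical(m, m2)
})

test_that("type equivalence classes are off by default and switchable", {
  lex <- synonym_lexicon("aspirin", "compound", list("acetylsalicylic acid"))
  ents <- data.frame(name = "acetylsalicylic acid", type = "chemical",
                     stringsAsFactors = FALSE)
  expect_false(link_entities(ents, lex, merge_config())$linked)
  expect_true(link_entities(ents, lex,
                            merge_config(type_equivalence = TRUE))$linked)
})

test_that("lexicon files round trip and reject duplicate canonicals", {
  lex <- synonym_lexicon(c("cited1", "breast cancer"), c("gene", "disease"),
                        list(c("msg1", "msg-1"), "breast carcinoma"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, f)
  lex2 <- read_lexicon(f)
  expect_equal(lex2$canonical, lex$canonical)
  expect_equal(lex2$synonyms, lex$synonyms)
  expect_error(synonym_lexicon(c("a", "a"), c("gene", "gene")),
               class = "kgpr_bad_lexicon")
})

test_that("merging rewires edges onto canonical entities", {
  # g1: gene cited1 with 2 edges; g2: gene msg1 with 3 edges, msg1 -> cited1
  g1 <- kg_new()
  for (n in c("n1", "n2")) g1 <- kg_add_entity(g1, n, "disease")
  g1 <- kg_add_entity(g1, "cited1", "gene")
  g1 <- kg_add_edge(g1, "gene:cited1", "disease:n1", "gene_disease")
  g1 <- kg_add_edge(g1, "gene:cited1", "disease:n2", "gene_disease")
  g2 <- kg_new()
  for (n in c("m1", "m2", "m3")) g2 <- kg_add_entity(g2, n, "disease")
  g2 <- kg_add_entity(g2, "msg1", "gene")
  for (n in c("m1", "m2", "m3"))
    g2 <- kg_add_edge(g2, "gene:msg1", paste0("disease:", n), "gene_disease")
  lex <- synonym_lexicon("cited1", "gene", list("msg1"))
  mapping <- link_entities(rbind(g1$entities[c("name", "type")],
                                 g2$entities[c("name", "type")]),
                           lex, merge_config())
  merged <- merge_graphs(g1, g2, mapping)
  expect_equal(kg_entity_count(merged), 6)  # 5 diseases + 1 merged gene
  expect_equal(kg_degree(merged, "cited1"), 5)
  expect_equal(kg_edge_count(merged), 5)
  # absorbed surface name is kept as a synonym of the canonical entity
  i <- match("gene:cited1", merged$entities$id)
  expect_true(grepl("msg1", merged$entities$synonyms[i]))
})

test_that("identity merge adds disjoint graphs exactly", {
  g1 <- kg_new()
  for (n in c("n1", "n2", "n3")) g1 <- kg_add_entity(g1, n, "gene")
  g1 <- kg_add_edge(g1, "gene:n1", "gene:n2", "co_occur")
  g1 <- kg_add_edge(g1, "gene:n2", "gene:n3", "gene_gene")
  g2 <- kg_new()
  for (n in c("x1", "x2")) g2 <- kg_add_entity(g2, n, "gene")
  g2 <- kg_add_edge(g2, "gene:x1", "gene:x2", "co_occur", weight = 4)
  m <- merge_graphs(g1, g2)
  expect_equal(kg_entity_count(m), kg_entity_count(g1) + kg_entity_count(g2))
  expect_equal(kg_edge_count(m), kg_edge_count(g1) + kg_edge_count(g2))
})

test_that("parallel co_occur weights sum while curated edges stay parallel", {
  mk <- function(w) {
    g <- kg_new()
    g <- kg_add_entity(g, "a", "gene")
    g <- kg_add_entity(g, "b", "gene")
    g <- kg_add_edge(g, "gene:a", "gene:b", "co_occur", weight = w)
    kg_add_edge(g, "gene:a", "gene:b", "gene_gene")
  }
  m <- merge_graphs(mk(2), mk(3))
  co <- m$edges[m$edges$label == "co_occur", ]
  expect_equal(nrow(co), 1)
  expect_equal(co$weight, 5)
  expect_equal(sum(m$edges$label == "gene_gene"), 2)
})

test_that("canonicalization-induced self-loops are dropped and reported", {
  g1 <- kg_new()
  g1 <- kg_add_entity(g1, "msg1", "gene")
  g1 <- kg_add_entity(g1, "cited1", "gene")
  g1 <- kg_add_edge(g1, "gene:msg1", "gene:cited1", "gene_gene")
  lex <- synonym_lexicon("cited1", "gene", list("msg1"))
  mapping <- link_entities(g1$entities[c("name", "type")], lex, merge_config())
  m <- merge_graphs(g1, kg_new(), mapping)
  rep <- attr(m, "merge_report")
  expect_equal(kg_edge_count(m), 0)
  expect_equal(rep$self_loops_dropped, 1)
  expect_equal(rep$entities_absorbed, 1)
})

test_that("cross-type links to one canonical are rejected", {
  g1 <- kg_new()
  g1 <- kg_add_entity(g1, "foo", "gene")
  g1 <- kg_add_entity(g1, "bar", "disease")
  mapping <- structure(data.frame(
    name = c("foo", "bar"), type = c("gene", "disease"),
    canonical = "baz", score = 1, linked = TRUE, stringsAsFactors = FALSE),
    class = c("entity_mapping", "data.frame"))
  expect_error(merge_graphs(g1, kg_new(), mapping), class = "kgpr_conflict")
})

test_that("merge bookkeeping balances on random graph pairs", {
  for (seed in 1:10) {
    g1 <- random_test_kg(seed, n_nodes = 8, p_pair = 0.3)
    g2 <- random_test_kg(seed + 100, n_nodes = 8, p_pair = 0.3)
    # random same-type lexicon over names occurring in either graph
    set.seed(seed)
    ents <- rbind(g1$entities, g2$entities)
    pickable <- ents[!duplicated(paste(ents$name, ents$type)), ]
    k <- min(3, nrow(pickable))
    chosen <- pickable[sample(nrow(pickable), k), ]
    lex <- synonym_lexicon(paste0("canon", seq_len(k)), chosen$type,
                           synonyms = as.list(chosen$name))
    mapping <- link_entities(pickable[c("name", "type")], lex, merge_config())
    m <- merge_graphs(g1, g2, mapping)
    rep <- attr(m, "merge_report")
    expect_equal(rep$entities_in, kg_entity_count(g1) + kg_entity_count(g2))
    expect_equal(rep$entities_out, rep$entities_in - rep$entities_absorbed)
    expect_equal(rep$entities_out, kg_entity_count(m))
    expect_equal(rep$edges_in, kg_edge_count(g1) + kg_edge_count(g2))
    expect_equal(kg_edge_count(m),
                 rep$edges_in - rep$cooccur_combined - rep$self_loops_dropped)
    # every edge endpoint exists after the rewiring
    expect_true(all(m$edges$head %in% m$entities$id))
    expect_true(all(m$edges$tail %in% m$entities$id))
  }
})
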