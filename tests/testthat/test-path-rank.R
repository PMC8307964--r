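store_from <- function(...) {
  v <- list(...)
  embedding_store(do.call(rbind, v))
}

test_that("entity vectors fall back from phrase to token averaging", {
  st <- store_from(ace = c(1, 0), ebola = c(1, 1), virus = c(1, -1),
                   "ebola_fever" = c(0, 1))
  expect_equal(entity_vector(st, "ace"), c(ace = 1, ace = 0),
               ignore_attr = TRUE)
  # phrase convention: spaces tried with "_" joining before token averaging
  expect_equal(unname(entity_vector(st, "ebola fever")), c(0, 1))
  # token averaging for multi-word names without a phrase vector
  expect_equal(unname(entity_vector(st, "ebola virus")), c(1, 0))
  expect_null(entity_vector(st, "совершенно unknown"))
})

test_that("cosine similarity matches closed forms and rejects zeros", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), class = "kgpr_zero_vector")
  expect_error(cosine_similarity(c(1, 0, 0), c(1, 0)),
               class = "kgpr_bad_parameter")
})

triangle_kg <- function() {
  g <- kg_new()
  for (n in c("a", "b", "c")) g <- kg_add_entity(g, n, "gene")
  g <- kg_add_edge(g, "gene:a", "gene:b", "gene_gene")
  g <- kg_add_edge(g, "gene:b", "gene:c", "gene_gene")
  g <- kg_add_edge(g, "gene:a", "gene:c", "gene_gene")
  g
}

test_that("exact-depth enumeration finds simple paths only", {
  g <- triangle_kg()
  p2 <- enumerate_paths(g, "a", "c", 2)
  expect_length(p2, 1)
  expect_equal(p2[[1]]$nodes, c("a", "b", "c"))
  # depth 1 direct edge
  expect_length(enumerate_paths(g, "a", "c", 1), 1)
  # no simple path of depth 3 from a to c in a triangle
  expect_length(enumerate_paths(g, "a", "c", 3), 0)
  expect_error(enumerate_paths(g, "a", "a", 2), class = "kgpr_bad_query")
  expect_error(enumerate_paths(g, "a", "zz", 2),
               class = "kgpr_missing_entity")
})

test_that("parallel edge instances yield distinct label-variant paths", {
  g <- kg_new()
  for (n in c("stat1", "mx2", "eif2ak2")) g <- kg_add_entity(g, n, "gene")
  g <- kg_add_edge(g, "gene:stat1", "gene:mx2", "co_occur")
  g <- kg_add_edge(g, "gene:stat1", "gene:mx2", "gene_gene")
  g <- kg_add_edge(g, "gene:mx2", "gene:eif2ak2", "co_occur")
  p <- enumerate_paths(g, "stat1", "eif2ak2", 2)
  expect_length(p, 2)
  expect_setequal(render_records(p),
                  c("stat1--co_occur--mx2--co_occur--eif2ak2",
                    "stat1--gene_gene--mx2--co_occur--eif2ak2"))
  # a duplicate instance of an existing edge doubles the path multiset
  g <- kg_add_edge(g, "gene:mx2", "gene:eif2ak2", "co_occur")
  expect_length(enumerate_paths(g, "stat1", "eif2ak2", 2), 4)
})

test_that("enumeration equals the brute-force oracle on random multigraphs", {
  for (seed in 1:25) {
    g <- random_test_kg(seed, n_nodes = sample(6:12, 1), p_pair = 0.3)
    ids <- g$entities$id
    st <- sample(ids, 2)
    for (d in 2:4) {
      got <- render_records(enumerate_paths(g, st[1], st[2], d))
      want <- oracle_path_records(g, st[1], st[2], d)
      expect_equal(got, want)
    }
  }
})

test_that("path scores sum cosines, drop unembeddable nodes, and sort", {
  st <- store_from(a = c(1, 0), b = c(1, 1), c = c(0, 1), d = c(1, 0))
  p <- list(parse_path_record("a--co_occur--b--co_occur--c"),
            parse_path_record("a--co_occur--d--co_occur--ghost"),
            parse_path_record("a--co_occur--d"))
  s <- score_paths(p, st)
  expect_equal(nrow(s), 2)
  expect_equal(s$score[1], sqrt(2), tolerance = 1e-12)
  expect_equal(s$score[2], 1)
  expect_true(all(diff(s$score) <= 0))
  d <- attr(s, "dropped")
  expect_equal(d$count, 1)
  expect_match(d$records, "ghost")

  # constant-vector path: every step contributes exactly 1
  st1 <- store_from(w = c(2, 3), x = c(2, 3), y = c(2, 3), z = c(2, 3))
  s1 <- score_paths(list(parse_path_record("w--co_occur--x--co_occur--y--co_occur--z")), st1)
  expect_equal(s1$score, 3)
})

test_that("scores are reversal-invariant and bounded by the depth", {
  set.seed(5)
  for (i in 1:20) {
    d <- sample(2:4, 1)
    nm <- paste0("v", 1:(d + 1))
    vecs <- matrix(rnorm((d + 1) * 6), ncol = 6,
                   dimnames = list(nm, NULL))
    st <- embedding_store(vecs)
    p <- kg_path(nm, rep("co_occur", d))
    rev_p <- kg_path(rev(nm), rep("co_occur", d))
    s <- score_paths(list(p), st)$score
    s_rev <- score_paths(list(rev_p), st)$score
    expect_equal(s, s_rev, tolerance = 1e-9)
    expect_true(s >= -d - 1e-9 && s <= d + 1e-9)
  }
})

test_that("scores are invariant under orthogonal transforms of the embeddings", {
  set.seed(9)
  nm <- paste0("v", 1:6)
  vecs <- matrix(rnorm(6 * 5), ncol = 5, dimnames = list(nm, NULL))
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  p <- list(kg_path(nm[1:4], rep("co_occur", 3)),
            kg_path(nm[c(1, 5, 6)], rep("gene_gene", 2)))
  s1 <- score_paths(p, embedding_store(vecs))$score
  s2 <- score_paths(p, embedding_store(vecs %*% Q))$score
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("strict nearest-rank percentile filter matches its definition", {
  mk <- function(scores) data.frame(
    record = sprintf("p%04d--co_occur--q", seq_along(scores)),
    depth = 2, score = scores, stringsAsFactors = FALSE)
  # 202 distinct scores -> exactly 10 retained
  s202 <- mk(rev(seq_len(202)))
  expect_equal(nrow(top_percentile(s202, 95)), 10)
  # scores 1..100: percentile value 95, retained {96..100}
  s100 <- mk(rev(seq_len(100)))
  top <- top_percentile(s100, 95)
  expect_equal(nrow(top), 5)
  expect_setequal(top$score, 96:100)
  # ties at the cut are excluded by strictness
  expect_equal(nrow(top_percentile(mk(rep(1, 50)), 95)), 0)
  expect_error(top_percentile(s100, 0), class = "kgpr_bad_parameter")
  expect_error(top_percentile(s100, 100), class = "kgpr_bad_parameter")
  empty <- data.frame(record = character(), depth = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  expect_error(top_percentile(empty, 95), class = "kgpr_bad_parameter")
  # retained fraction bound for distinct scores
  for (n in c(7, 33, 101, 202, 642)) {
    got <- nrow(top_percentile(mk(seq_len(n) / n), 95))
    expect_lte(got / n, 1 - 95 / 100 + 1 / n)
  }
})

test_that("distinct relationships count typed triples or node pairs", {
  p <- parse_path_record("a--co_occur--b--gene_disease--c")
  expect_equal(count_distinct_relationships(list(p)), 2)
  # duplicates of a path add nothing (set semantics)
  expect_equal(count_distinct_relationships(list(p, p)), 2)
  # same pair under two labels: 2 typed, 1 untyped
  q <- parse_path_record("a--gene_gene--b")
  r <- parse_path_record("a--co_occur--b")
  expect_equal(count_distinct_relationships(list(q, r), typed = TRUE), 2)
  expect_equal(count_distinct_relationships(list(q, r), typed = FALSE), 1)
  # direction does not matter
  s <- parse_path_record("b--co_occur--a")
  expect_equal(count_distinct_relationships(list(r, s)), 1)
})

test_that("full path queries report per-depth results deterministically", {
  plan <- fixture_plan(
    seed = 33, entities = c(gene = 7, chemical = 2, disease = 3),
    edge_density = c(co_occur = 0.2, gene_gene = 0.08),
    planted_paths = list(list(nodes = c("gene1", "gene2", "disease1",
                                        "chemical1"),
                              cosines = c(0.95, 0.95, 0.95))))
  g <- make_synthetic_kg(plan)
  st <- make_synthetic_embeddings(plan)
  rep1 <- run_path_query(g, st, "gene1", "chemical1", depths = c(2, 3))
  expect_named(rep1$depths, c("2", "3"))
  d3 <- rep1$depths[["3"]]
  expect_equal(d3$n_paths, d3$n_scored + d3$n_dropped)
  expect_equal(d3$scored$record[1],
               "gene1--co_occur--gene2--co_occur--disease1--co_occur--chemical1")
  expect_equal(d3$scored$score[1], 2.85, tolerance = 1e-5)
  # serialization determinism: identical inputs, identical reports
  rep2 <- run_path_query(g, st, "gene1", "chemical1", depths = c(2, 3))
  expect_identical(jsonlite::toJSON(unclass(rep1), auto_unbox = TRUE, digits = NA),
                   jsonlite::toJSON(unclass(rep2), auto_unbox = TRUE, digits = NA))
})

test_that("queries with no connection report zero counts", {
  g <- kg_new()
  g <- kg_add_entity(g, "a", "gene")
  g <- kg_add_entity(g, "b", "gene")
  st <- store_from(a = c(1, 0), b = c(0, 1))
  rep <- run_path_query(g, st, "a", "b", depths = c(2, 3, 4))
  for (d in rep$depths) {
    expect_equal(d$n_paths, 0)
    expect_equal(d$n_top, 0)
    expect_equal(d$distinct_relationships_typed, 0)
  }
})
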