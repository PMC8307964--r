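---
title: "Methods: graph fusion and embedding-scored path ranking in kgpathrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph fusion and embedding-scored path ranking in kgpathrank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgpathrank)
```

## The problem

Drug-repurposing and hypothesis-generation work over biomedical knowledge
graphs (KGs) needs two ingredients that rarely come from one source: curated
relations (compound–gene bindings, gene–disease associations, pathways) and
up-to-date literature signal.  `kgpathrank` builds a typed multigraph from
both — a curated chemogenomic edge table and PubTator-annotated
titles/abstracts turned into weighted co-occurrence edges — merges the two
vocabularies through type-constrained synonym disambiguation, and then
interrogates the merged graph: ego-centered subgraphs around an entity of
interest, and a fixed-depth path-ranking framework that scores connecting
paths between two entities by word-embedding similarity.

## The graph model

Entities carry one of 18 closed types (gene, disease, compound, chemical,
phenotype, ...) and edges one of 28 relation labels: 27 curated relation
types (`compound_gene`, `gene_disease`, `gene_gene`, ...) plus the
literature-derived `co_occur`.  Three modelling decisions matter downstream:

* **Multiset edges.** Parallel edges between the same entity pair coexist,
  whether they differ in label or are duplicate instances of the same
  relation from different provenance.  Path enumeration treats each instance
  as distinct, which is why ranked-path listings legitimately contain rows
  differing only in one edge label, or repeated verbatim.
* **Undirected traversal.** Curated edges keep their stored orientation, but
  degree, ego extraction and path enumeration all ignore it: association-type
  relations (`gene_disease`, `co_occur`) are traversed in both directions in
  practice, and a direction-respecting walk would make most published paths
  unreachable.
* **Degree = distinct neighbors.** Node "size" in ego-network rendering is
  the number of connected entities, not the incident edge count; three
  parallel edges to one neighbor contribute 1.  Self-loops are rejected at
  construction: no curated relation relates an entity to itself and path
  semantics assume distinct endpoints.

The ego network of radius `r` is the induced subgraph on all entities within
`r` undirected hops; every parent edge between retained entities is
retained.  The hop radius is a required parameter with default 1 (a
one-hop neighborhood is the common published rendering; nothing in the
framework depends on the default).

## Co-occurrence extraction

Two entities co-occur when both are mentioned in one document's title or
abstract; each such document adds exactly 1 to the pair's weight, however
many times either entity is repeated inside it.  Mentions are `(name, type)`
pairs after normalization (lowercasing, underscore-to-space, whitespace
collapse), so one surface form annotated as both a gene and a chemical is
two entities — and the pair can itself co-occur.  No association weighting
(PMI, Jaccard) is applied and no minimum count is imposed by default
(`min_weight = 1`); the raw document count is the published convention, and
thresholding is left as an explicit user decision.  Mentions without a
database identifier are kept: identifier coverage in literature annotation
is uneven, and dropping them would silently thin the co-occurrence layer.

## Entity disambiguation and merging

Surface names are linked to canonical terms in a synonym lexicon.  The
candidate score of a lexicon entry is the maximum normalized Levenshtein
similarity (`1 - dist/max(nchar)`) between the entity name and the entry's
canonical term or any synonym; the entity links to the best same-type entry
scoring at least the threshold `tau`.  Three choices were genuinely open:

* **`tau` default 0.95.** The calibration that produced the original merged
  KG was manual and unreported, so the threshold is a first-class
  `merge_config()` parameter.  0.95 is deliberately conservative: on typical
  entity-name lengths (8–20 characters) it tolerates roughly one edit, which
  absorbs hyphenation and pluralization variants without inviting the
  classic one-letter gene-symbol collisions.  Exact matches always link.
* **Type constraint.** "Similar types" is implemented as *identical* types.
  The merged-KG statistics keep `chemical` and `compound` as separate types,
  so cross-type merging is off by default; a switch
  (`type_equivalence = TRUE`) treats chemical≡compound and species≡organism
  as equivalence pairs for users whose sources disagree on those labels.
* **Tie-breaking.** Higher score, then lexicographically smaller canonical —
  reproducibility over cleverness.  A synonym listed under several
  canonicals resolves the same way on every run.

Merging rewrites both graphs onto `(canonical, type)` entities.  `co_occur`
edges between the same canonical pair are combined by summing their document
counts (they are counts of the same observable); curated parallel edges are
all kept.  Edges whose endpoints collapse together are dropped as
self-loops, with a reported count, and the merge report carries the full
bookkeeping (entities absorbed, instances combined, loops dropped) so that
conservation can be asserted mechanically.

## Path ranking

Given source and target entities and a set of depths (default 2, 3, 4,
where depth = edge count, so a depth-2 path has three nodes):

1. **Enumeration.** All node-simple paths with *exactly* `d` edges under
   undirected traversal.  Exact depth, rather than shortest-path semantics,
   is the reading consistent with reporting separate path counts per depth;
   parallel edge instances multiply paths combinatorially.
2. **Scoring.** `S = sum of cos(v(n_i-1), v(n_i))` over consecutive nodes,
   `S` in `[-d, d]`.  Entity vectors come from a word2vec-style store:
   the full name is tried as a phrase token (as-is, `_`-joined, `-`-joined),
   otherwise in-vocabulary word tokens are averaged.  Paths containing a
   node with no vector are dropped and counted in diagnostics, not
   zero-scored — zero-filling would systematically favor paths that chain
   out-of-vocabulary nodes.
3. **Selection.** Scores are sorted per depth and filtered by the *strict
   nearest-rank* 95th percentile: the percentile value is the
   `ceiling(q/100 * n)`-th smallest score and only strictly greater scores
   survive.  This convention is the one that reproduces the published
   behavior — 202 distinct depth-3 scores yield exactly 10 top-ranked
   paths — and it handles heavy ties gracefully (ties at the cut are all
   excluded).
4. **Summaries.** Distinct relationships across the selected paths are
   counted both as typed `(node, label, node)` triples and as unordered
   node pairs; published summaries mix the two conventions, so both are
   reported rather than guessing intent per query.

Numerical conventions: score comparisons in the test suite use absolute
tolerance `1e-9`; serialized reports round scores to 6 decimals, matching
the precision of published listings.  Ties in score order are broken by the
rendered path record so reports are byte-stable.

## Synthetic fixtures

`fixture_plan()` and its generators make every stage testable offline:

* **Graphs** with per-type entity counts, per-label random edge densities
  (fraction of all unordered pairs) and planted paths added verbatim.
* **Embeddings with planted cosines.**  A planted chain with per-step
  cosines `c_1..c_d` is completed to a full Gram matrix by the Markov rule
  `cos(n_i, n_j) = prod(c_(i+1)..c_j)` — always positive semidefinite for a
  chain — then eigen-factorized; eigenvalues below `-1e-9` are an
  infeasibility error, tiny negatives are clipped.  Planted pairs land
  within `1e-6` of their targets, and the construction (rather than
  iterative optimization) makes generation exact and deterministic.
  Unconstrained entities get seeded random unit vectors.
* **Documents** realizing a pair-to-count co-mention plan exactly, emitted
  through the same PubTator writer the package reads back.
* **Determinism.** Every generator draws from a private RNG stream seeded
  by the plan; the caller's random state is untouched and identical plans
  serialize byte-identically.

What the fixtures deliberately do *not* emulate: scale-free degree
distributions, realistic mention text, identifier noise, or the size of a
real literature corpus.  Passing tests therefore demonstrate correctness of
the algorithms (counting, conservation, ranking, recovery of planted
structure), not robustness to the statistical quirks of real annotation
pipelines.

Problem sizes used by the test suite are intentionally desk-scale: random
multigraphs of 6–14 nodes with up to 3 parallel edges per pair (where
exhaustive oracles are affordable — enumeration is cross-checked against a
brute-force oracle on over 200 graph/depth cases), corpora of a dozen
documents, and 100 random plans for planted-path recovery.  The planted
per-step cosine in those recovery plans is 0.97 against random unit vectors
in 12 dimensions, which separates the planted path's score from any
competitor by a wide margin with overwhelming probability.

## Known limitations

* Disambiguation is surface-string based; no embedding or context signal is
  used, and homonyms of the same type cannot be separated.
* Exact-depth enumeration is exponential in depth; it is intended for the
  published regime (depths 2–4, hundreds of paths), not for dense hubs at
  depth ≥ 5.
* Multi-word entities without a phrase vector are averaged from word
  tokens, which flattens compositional meaning ("weight loss").
* The GraphML export carries annotations (type, degree, label, weight) but
  no layout; rendering is out of scope.
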