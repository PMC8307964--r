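#' Entity-type and relation-label vocabularies
#'
#' The graph model is typed: every entity carries one of a closed set of
#' biological entity types (gene, disease, compound, ...) and every edge one
#' of a closed set of relation labels.  The relation vocabulary is the 27
#' curated chemogenomic relation types (COMPOUND_GENE, GENE_DISEASE, ...)
#' plus the literature-derived `co_occur` label, 28 labels in all.  Labels
#' are stored lowercase; matching is case-insensitive.
#'
#' @return `kg_entity_types()` and `kg_relation_labels()` return character
#'   vectors of admissible values; `ag_relation_labels()` returns the 27
#'   curated labels without `co_occur`.
#' @examples
#' length(ag_relation_labels())  # 27
#' "co_occur" %in% kg_relation_labels()
#' @export
kg_entity_types <- function() {
  c("compound", "phenotype", "gene", "biological_process", "enzyme_class",
    "go", "pathway", "organism", "tissue", "disease", "chemical", "species",
    "protein_mutation", "snp", "dna_mutation", "cell_line", "genus", "strain")
}

#' @rdname kg_entity_types
#' @export
ag_relation_labels <- function() {
  c("compound_gene", "gene_disease", "compound_adverse_effect", "gene_gene",
    "is_a_phenotype", "gene_biologicalprocess", "gene_cellularcomponent",
    "gene_molecularfunction", "gene_tissue", "pathway_gene",
    "compound_indication", "instance_of", "is_a_ec", "changes_with",
    "repurposed_indication", "pathway_compound", "pathway_cellularcomponent",
    "part_of", "gene_ec", "pathway_contains_pathway", "canonical_target",
    "positively_regulates", "negatively_regulates", "regulates", "has_part",
    "occurs_in", "gene_go")
}

#' @rdname kg_entity_types
#' @export
kg_relation_labels <- function() {
  c(ag_relation_labels(), "co_occur")
}

# Aliases seen in source files mapped onto the canonical type vocabulary.
.type_aliases <- c(
  "biological process"                     = "biological_process",
  "enzyme class"                           = "enzyme_class",
  "gene ontology (go)"                     = "go",
  "gene ontology"                          = "go",
  "protein mutation"                       = "protein_mutation",
  "proteinmutation"                        = "protein_mutation",
  "dna mutation"                           = "dna_mutation",
  "dnamutation"                            = "dna_mutation",
  "single nucleotide polymorphisms (snps)" = "snp",
  "snps"                                   = "snp",
  "cell line"                              = "cell_line",
  "cellline"                               = "cell_line",
  "mutation"                               = "dna_mutation")

#' Normalize an entity-type label
#'
#' Lowercases, resolves common aliases (e.g. PubTator's `CellLine`,
#' `ProteinMutation`) and validates against [kg_entity_types()].
#'
#' @param type character vector of raw type labels.
#' @param allow_unknown keep labels outside the vocabulary (lowercased)
#'   instead of raising an error.
#' @return character vector of canonical type labels.
#' @export
normalize_entity_type <- function(type, allow_unknown = FALSE) {
  t <- tolower(trimws(as.character(type)))
  hit <- t %in% names(.type_aliases)
  t[hit] <- .type_aliases[t[hit]]
  bad <- !(t %in% kg_entity_types())
  if (any(bad) && !allow_unknown) {
    kgpr_stop(sprintf("unknown entity type(s): %s",
                      paste(unique(t[bad]), collapse = ", ")),
              "kgpr_unknown_type")
  }
  t
}

#' Normalize a relation label
#'
#' Lowercases and validates against the 28-label vocabulary
#' ([kg_relation_labels()]).
#'
#' @param label character vector of raw relation labels.
#' @param allow_unknown keep labels outside the vocabulary instead of
#'   raising an error.
#' @return character vector of lowercase labels.
#' @export
normalize_relation_label <- function(label, allow_unknown = FALSE) {
  l <- tolower(trimws(as.character(label)))
  bad <- !(l %in% kg_relation_labels())
  if (any(bad) && !allow_unknown) {
    kgpr_stop(sprintf("unknown relation label(s): %s",
                      paste(unique(l[bad]), collapse = ", ")),
              "kgpr_unknown_label")
  }
  l
}
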