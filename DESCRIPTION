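Package: habmine
Title: Text Mining and Data Fusion of Microbial Habitat, Phenotype, and Use Relations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for building an ontology-indexed knowledge
    base of microbial habitats, phenotypes, and uses. Parses OBO-dialect
    ontologies and NCBI-taxdump-dialect taxonomies, extends the taxonomy with
    strain-catalog entries by rule-based name matching, recognizes taxon,
    habitat, phenotype, and use mentions in free text, normalizes candidate
    terms against ontology concepts by syntactic-head anchoring and Jaccard
    scoring, extracts lives_in, exhibits, and studied_for relations through
    trigger-word co-occurrence with microorganism anaphora resolution, ingests
    structured sequence and culture-collection records through declarative
    field mappings, and serves ontology-expanded boolean queries over the
    deduplicated knowledge base. Includes seeded generators for synthetic
    references and gold-annotated corpora used to evaluate the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
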