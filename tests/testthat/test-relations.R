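test_that("trigger detection is case-insensitive and multi-typed", {
  trig <- detect_triggers("X was isolated from Y")
  expect_equal(trig$type, "lives_in")
  expect_equal(trig$trigger, "isolated from")
  expect_equal(nrow(detect_triggers("X resembles Y")), 0)
  both <- detect_triggers("It was Isolated From soil and used for brining")
  expect_setequal(both$type, c("lives_in", "studied_for"))
  # copular exhibits rule needs a phenotype in the sentence
  expect_equal(nrow(detect_triggers("It was warm")), 0)
  cop <- detect_triggers("It was warm", has_phenotype = TRUE)
  expect_equal(cop$type, "exhibits")
})

test_that("anaphora resolve to the nearest preceding taxon in the window", {
  tax <- bacillus_taxonomy()
  lex <- build_taxon_lexicon(tax)
  docs <- doc_tbl(paste(
    "Bacillus subtilis was studied.",
    "This bacterium was isolated from milk."))
  ment <- match_taxa(docs, lex)
  links <- resolve_anaphora(docs, ment)
  expect_equal(nrow(links), 1)
  expect_equal(links$taxid, "T3")
  expect_equal(links$surface, "This bacterium")
  expect_equal(links$kind, "sortal")

  # no preceding taxon in the window: no link
  docs2 <- doc_tbl("This bacterium was isolated from milk.")
  expect_equal(nrow(resolve_anaphora(docs2, match_taxa(docs2, lex))), 0)

  # outside the window: no link
  docs3 <- doc_tbl(paste(
    "Bacillus subtilis was studied.", "Work continued. Samples arrived.",
    "It was isolated from milk."))
  expect_equal(nrow(resolve_anaphora(docs3, match_taxa(docs3, lex),
                                     window = 2)), 0)

  # singular anaphor with two candidates takes the nearest (rightmost)
  docs4 <- doc_tbl(paste(
    "Bacillus subtilis and Bacillus toyensis were studied.",
    "It was isolated from milk."))
  links4 <- resolve_anaphora(docs4, match_taxa(docs4, lex))
  expect_equal(links4$taxid, "T4")

  # plural anaphor gathers every taxon of the nearest taxon sentence
  links5 <- resolve_anaphora(docs4, match_taxa(docs4, lex))
  docs5 <- doc_tbl(paste(
    "Bacillus subtilis and Bacillus toyensis were studied.",
    "These bacteria were isolated from milk."))
  links5 <- resolve_anaphora(docs5, match_taxa(docs5, lex))
  expect_setequal(links5$taxid, c("T3", "T4"))
})

relation_fixture <- function(text) {
  tax <- bacillus_taxonomy()
  lex <- build_taxon_lexicon(tax)
  ont <- milk_ontology()
  docs <- doc_tbl(text)
  ment <- recognize_strain_mentions(docs, match_taxa(docs, lex), tax)
  idx <- build_head_index(ont)
  ents <- normalize_terms(extract_candidate_terms(docs, exclude = ment), idx)
  uses <- match_uses(docs, ont)
  links <- resolve_anaphora(docs, ment)
  list(docs = docs,
       rels = extract_relations(docs, ment, dplyr::bind_rows(ents, uses),
                                links = links))
}

test_that("one taxon, one habitat, one trigger give one lives_in", {
  f <- relation_fixture("Bacillus subtilis was isolated from cow milk.")
  expect_equal(nrow(f$rels), 1)
  expect_equal(f$rels$type, "lives_in")
  expect_equal(f$rels$taxid, "T3")
  expect_equal(f$rels$concept_id, "HAB:3")
  expect_equal(f$rels$trigger, "isolated from")
})

test_that("trigger without a branch-matching object yields nothing", {
  f <- relation_fixture("Bacillus subtilis was isolated from the archive.")
  expect_equal(nrow(f$rels), 0)
  # and no relation comes from a trigger-free sentence
  f2 <- relation_fixture("Bacillus subtilis appeared near cow milk.")
  expect_equal(nrow(f2$rels), 0)
})

test_that("anaphora bridge relations across sentences", {
  f <- relation_fixture(paste(
    "Bacillus subtilis was studied.",
    "This bacterium was isolated from cow milk."))
  expect_equal(nrow(f$rels), 1)
  expect_equal(f$rels$taxid, "T3")
  expect_equal(f$rels$concept_id, "HAB:3")
})

test_that("relations are a cross product with branch consistency", {
  refs <- make_toy_references(n_concepts = 40, n_taxa = 15, seed = 17)
  gold <- make_gold_corpus(refs, n_docs = 24, seed = 18)
  res <- run_pipeline(gold$documents, refs$ontology, refs$taxonomy)
  branches <- setNames(refs$ontology$concepts$branch, refs$ontology$concepts$id)
  type_branch <- c(lives_in = "habitat", exhibits = "phenotype",
                   studied_for = "use")
  expect_true(all(branches[res$relations$concept_id] ==
                    type_branch[res$relations$type]))
  # per sentence and type, counts equal |taxa| x |objects|
  ents <- dplyr::bind_rows(res$entities, res$use_mentions)
  per <- split(res$relations,
               paste(res$relations$doc_id, res$relations$sentence_start,
                     res$relations$type))
  for (g in per) {
    d <- g$doc_id[1]; s0 <- g$sentence_start[1]; ty <- g$type[1]
    ments <- res$taxon_mentions
    sid <- unique(ments$sid[ments$doc_id == d & ments$start >= s0])
    taxa_here <- unique(res$relations$taxid[res$relations$doc_id == d &
                                              res$relations$sentence_start == s0 &
                                              res$relations$type == ty])
    objs <- unique(g$concept_id)
    expect_equal(nrow(g), length(taxa_here) * length(objs))
  }
})

test_that("determinism holds for fixed inputs", {
  f1 <- relation_fixture("Bacillus subtilis was isolated from cow milk.")
  f2 <- relation_fixture("Bacillus subtilis was isolated from cow milk.")
  expect_identical(f1$rels, f2$rels)
})
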