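test_that("the head index files labels under their own heads", {
  idx <- build_head_index(milk_ontology(), branches = "habitat")
  milk_rows <- idx$labels[idx$labels$head_key == "milk", ]
  expect_setequal(milk_rows$label, c("milk", "cow milk"))
  expect_equal(idx$labels$head_key[idx$labels$label == "milk product"],
               "product")
  empty <- build_head_index(milk_ontology(), branches = character())
  expect_equal(nrow(empty$labels), 0)
})

test_that("jaccard is exact set arithmetic over normalized words", {
  expect_equal(jaccard(c("dairy", "cow", "milk"), c("cow", "milk")), 2 / 3)
  expect_equal(jaccard(c("cow", "milk"), c("cow", "milk")), 1)
  expect_equal(jaccard(c("fresh", "milk"), c("raw", "milk")), 1 / 3)
  # plural-s stripping and case folding apply on both sides
  expect_equal(jaccard(c("Cow", "milks"), c("cow", "milk")), 1)
  expect_error(jaccard(character(), "milk"), "empty")
})

test_that("the worked normalization example scores as stated", {
  idx <- build_head_index(milk_ontology(), branches = "habitat")
  term <- list(tokens = list(c("dairy", "cow", "milk")), head_key = "milk")
  r <- tomap_normalize(term, idx)
  expect_equal(r$concept_id, "HAB:3")   # "cow milk"
  expect_equal(r$score, 2 / 3)
  expect_equal(r$matched_label, "cow milk")
})

test_that("exact label matches score 1 and missing heads are ignored", {
  idx <- build_head_index(milk_ontology(), branches = "habitat")
  exact <- tomap_normalize(list(tokens = list(c("cow", "milk")),
                                head_key = "milk"), idx)
  expect_equal(exact$score, 1)
  expect_null(tomap_normalize(list(tokens = list(c("stainless", "steel")),
                                   head_key = "steel"), idx))
})

test_that("ties break to fewer label tokens then smaller concept id", {
  ont <- parse_obo(c(
    "[Term]", "id: HAB:0", "name: habitat", "",
    "[Term]", "id: HAB:1", "name: soil", "is_a: HAB:0", "",
    "[Term]", "id: HAB:2", "name: wet soil", "is_a: HAB:1", ""))
  idx <- build_head_index(ont, branches = "habitat")
  # "deep soil": jaccard 1/2 against "soil" and 1/3 against "wet soil"
  r <- tomap_normalize(list(tokens = list(c("deep", "soil")),
                            head_key = "soil"), idx)
  expect_equal(r$concept_id, "HAB:1")
  # equal-score tie on identical single-token labels: smaller id wins
  ont2 <- parse_obo(c(
    "[Term]", "id: HAB:0", "name: habitat", "",
    "[Term]", "id: HAB:1", "name: brine", "is_a: HAB:0", "",
    "[Term]", "id: HAB:2", "name: salt brine", "is_a: HAB:0", ""))
  idx2 <- build_head_index(ont2, branches = "habitat")
  r2 <- tomap_normalize(list(tokens = list(c("salt", "brine")),
                             head_key = "brine"), idx2)
  expect_equal(r2$concept_id, "HAB:2")  # exact 1.0 beats 1/2
})

test_that("tomap equals the brute-force scorer on seeded fixtures", {
  for (sd in 1:4) {
    refs <- make_toy_references(n_concepts = 50, n_taxa = 5, seed = sd)
    ont <- refs$ontology
    idx <- build_head_index(ont)
    labels <- branch_labels(ont)
    vocab <- unique(unlist(strsplit(labels$label, "[ ]+")))
    set.seed(sd * 100)
    for (k in 1:50) {
      n <- sample(1:3, 1)
      toks <- sample(vocab, n)
      term <- list(tokens = list(toks), head_key = norm_word_oracle(toks[n]))
      got <- tomap_normalize(term, idx)
      want <- bf_tomap(toks, term$head_key, labels)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$concept_id, want$concept_id)
        expect_equal(got$score, want$score)
        expect_true(got$score > 0 && got$score <= 1)
      }
    }
  }
})

test_that("normalization is deterministic and resolves sub-term overlaps", {
  idx <- build_head_index(milk_ontology(), branches = c("habitat", "phenotype"))
  docs <- doc_tbl("Samples were found in fresh raw cow milk.")
  terms <- extract_candidate_terms(docs)
  e1 <- normalize_terms(terms, idx)
  e2 <- normalize_terms(terms, idx)
  expect_identical(e1, e2)
  # only the best-scoring span survives per overlap group
  expect_equal(nrow(e1), 1)
  expect_equal(e1$id, "HAB:3")
  expect_equal(e1$surface, "cow milk")
  expect_equal(e1$score, 1)
})

test_that("heuristic rules drop and remap declaratively", {
  idx <- build_head_index(milk_ontology(), branches = "habitat")
  docs <- doc_tbl("Cells grew in cow milk. The cell culture thrived in milk.")
  ents <- normalize_terms(extract_candidate_terms(docs), idx)
  expect_identical(apply_heuristics(ents, NULL), ents)
  empty_rules <- tibble::tibble(field = character(), pattern = character(),
                                action = character(), target = character())
  expect_identical(apply_heuristics(ents, empty_rules), ents)
  dropped <- apply_heuristics(ents, tibble::tibble(
    field = "sentence", pattern = "cell culture", action = "drop",
    target = NA_character_), docs = docs)
  expect_true(nrow(dropped) < nrow(ents))
  remapped <- apply_heuristics(ents, tibble::tibble(
    field = "surface", pattern = "^cow milk$", action = "remap",
    target = "HAB:2"), ont = milk_ontology())
  expect_true("HAB:2" %in% remapped$id)
  expect_equal(remapped$score, ents$score)  # scores preserved
  expect_error(apply_heuristics(ents, tibble::tibble(
    field = "surface", pattern = "x", action = "remap", target = "NOPE"),
    ont = milk_ontology()), "unknown concept")
})
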