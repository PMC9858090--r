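test_that("the lexicon carries genus-initial variants", {
  lex <- build_taxon_lexicon(bacillus_taxonomy())
  expect_true("b subtilis" %in% lex$entries$key)   # covers B. and B forms
  expect_true("bacillus subtilis" %in% lex$entries$key)
  expect_true(all(lex$entries$is_variant[lex$entries$key == "b subtilis"]))
  # uninomials get no abbreviation
  expect_false(any(lex$entries$key == "b" & lex$entries$is_variant))
  # lexicon building is deterministic and idempotent
  lex2 <- build_taxon_lexicon(bacillus_taxonomy())
  expect_identical(lex$entries, lex2$entries)
})

test_that("trinomials abbreviate the genus token only", {
  nodes <- tibble::tibble(taxid = c("T1", "T2"), parent = c("T1", "T1"),
                          rank = c("no rank", "subspecies"))
  nms <- tibble::tibble(taxid = c("T1", "T2"),
                        name = c("root", "Lactococcus lactis cremoris"),
                        name_class = "scientific")
  lex <- build_taxon_lexicon(new_taxonomy(nodes, nms, "T1"))
  expect_true("l lactis cremoris" %in% lex$entries$key)
})

test_that("canonical, abbreviated, and variant mentions resolve alike", {
  tax <- bacillus_taxonomy()
  lex <- build_taxon_lexicon(tax)
  hits <- match_taxa(doc_tbl(
    "Bacillus subtilis grows. B. subtilis persists. B subtilis remains."), lex)
  expect_equal(nrow(hits), 3)
  expect_equal(unique(hits$id), "T3")
  # surfaces equal the document slices (span integrity)
  txt <- "Bacillus subtilis grows. B. subtilis persists. B subtilis remains."
  for (i in seq_len(nrow(hits))) {
    expect_equal(substr(txt, hits$start[i] + 1, hits$end[i]), hits$surface[i])
  }
})

test_that("the longest lexicon match wins", {
  nodes <- tibble::tibble(taxid = c("T1", "T2", "T3"),
                          parent = c("T1", "T1", "T2"),
                          rank = c("no rank", "species", "subspecies"))
  nms <- tibble::tibble(
    taxid = c("T1", "T2", "T3"),
    name = c("root", "Lactococcus lactis", "Lactococcus lactis ssp. lactis"),
    name_class = "scientific")
  lex <- build_taxon_lexicon(new_taxonomy(nodes, nms, "T1"))
  hits <- match_taxa(doc_tbl("Lactococcus lactis ssp. lactis acidifies."), lex)
  expect_equal(hits$id, "T3")
  expect_equal(hits$surface, "Lactococcus lactis ssp. lactis")
})

test_that("genus-initial case is respected and ambiguity drops the key", {
  tax <- bacillus_taxonomy()
  lex <- build_taxon_lexicon(tax)
  expect_equal(nrow(match_taxa(doc_tbl("bacillus subtilis lowercase."), lex)), 0)
  # one key, two taxids at the same name class: dropped
  tax2 <- tax
  tax2$names <- dplyr::bind_rows(tax2$names, tibble::tibble(
    taxid = "T6", name = "Twin name", name_class = "synonym"),
    tibble::tibble(taxid = "T2", name = "Twin name", name_class = "synonym"))
  lex2 <- build_taxon_lexicon(tax2)
  expect_equal(nrow(match_taxa(doc_tbl("Twin name appears."), lex2)), 0)
  # scientific beats synonym on a shared key
  tax3 <- tax
  tax3$names <- dplyr::bind_rows(tax3$names, tibble::tibble(
    taxid = "T6", name = "Bacillus subtilis", name_class = "synonym"))
  lex3 <- build_taxon_lexicon(tax3)
  expect_equal(match_taxa(doc_tbl("Bacillus subtilis here."), lex3)$id, "T3")
})

test_that("match_taxa equals a brute-force maximal scan on fixture docs", {
  refs <- make_toy_references(n_concepts = 12, n_taxa = 25, seed = 13)
  gold <- make_gold_corpus(refs, n_docs = 30, seed = 14,
                           templates = c("lives_in", "abbrev", "distractor"))
  lex <- build_taxon_lexicon(refs$taxonomy)
  got <- match_taxa(gold$documents, lex)
  # oracle: try every key at every token position, keep leftmost-longest
  bf <- list()
  for (d in seq_len(nrow(gold$documents))) {
    txt <- gold$documents$text[d]
    sents <- split_sentences(txt)
    for (s in seq_len(nrow(sents))) {
      toks <- tokenize(substr(txt, sents$start[s] + 1, sents$end[s]),
                       offset = sents$start[s])
      i <- 1L
      while (i <= nrow(toks)) {
        found <- 0L
        for (len in rev(seq_len(nrow(toks) - i + 1L))) {
          key <- paste(toks$norm[i:(i + len - 1L)], collapse = " ")
          rows <- which(lex$entries$key == key)
          if (!length(rows)) next
          surf <- substr(txt, toks$start[i] + 1, toks$end[i + len - 1L])
          ok <- rows[!lex$entries$case_sensitive[rows] |
                       substr(surf, 1, 1) == lex$entries$first_char[rows]]
          if (!length(ok)) next
          if (length(unique(lex$entries$taxid[ok])) == 1) {
            bf[[length(bf) + 1L]] <- tibble::tibble(
              doc_id = gold$documents$doc_id[d],
              start = toks$start[i], end = toks$end[i + len - 1L],
              id = unique(lex$entries$taxid[ok]))
          }
          found <- len
          break
        }
        i <- i + max(found, 1L)
      }
    }
  }
  bf <- dplyr::bind_rows(bf)
  expect_setequal(paste(got$doc_id, got$start, got$end, got$id),
                  paste(bf$doc_id, bf$start, bf$end, bf$id))
})

test_that("strain designators attach and resolve through variant keys", {
  tax <- bacillus_taxonomy()
  lex <- build_taxon_lexicon(tax)
  docs <- doc_tbl("Bacillus subtilis DSM 10 was sampled.")
  hits <- recognize_strain_mentions(docs, match_taxa(docs, lex), tax)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$id, "T5")
  expect_equal(hits$surface, "Bacillus subtilis DSM 10")
  # variant form through the comparison key
  docs2 <- doc_tbl("Bacillus subtilis strain DSM10 was sampled.")
  hits2 <- recognize_strain_mentions(docs2, match_taxa(docs2, lex), tax)
  expect_equal(hits2$id, "T5")
  # unresolvable designator falls back to the species
  docs3 <- doc_tbl("Bacillus subtilis XYZ-99 was sampled.")
  hits3 <- recognize_strain_mentions(docs3, match_taxa(docs3, lex), tax)
  expect_equal(hits3$id, "T3")
  expect_equal(hits3$surface, "Bacillus subtilis XYZ-99")
})

test_that("a detached 'strain <id>' resolves against the sentence species", {
  tax <- bacillus_taxonomy()
  lex <- build_taxon_lexicon(tax)
  docs <- doc_tbl("Bacillus subtilis was grown as strain DSM10 overnight.")
  hits <- recognize_strain_mentions(docs, match_taxa(docs, lex), tax)
  expect_true("T5" %in% hits$id)
  strain_hit <- hits[hits$id == "T5", ]
  expect_equal(strain_hit$surface, "DSM10")
})

test_that("use matching is exact-only with longest-match overlap handling", {
  ont <- milk_ontology()
  hits <- match_uses(doc_tbl("Known for acidification of milk."), ont)
  expect_equal(hits$id, "USE:1")
  expect_equal(hits$surface, "acidification")
  expect_equal(nrow(match_uses(doc_tbl("Known for acidifications."), ont)), 0)
  # longest of two overlapping labels wins
  ont2 <- parse_obo(c(
    "[Term]", "id: USE:0", "name: use", "",
    "[Term]", "id: USE:1", "name: milk acidification", "is_a: USE:0", "",
    "[Term]", "id: USE:2", "name: acidification", "is_a: USE:0", "",
    "[Term]", "id: HAB:0", "name: habitat", "",
    "[Term]", "id: PHE:0", "name: phenotype"))
  hits2 <- match_uses(doc_tbl("Applied in milk acidification today."), ont2)
  expect_equal(hits2$id, "USE:1")
})
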