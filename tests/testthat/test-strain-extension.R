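test_that("strain name variants close over the stated rewrites", {
  v <- strain_name_variants("DSM 20174")
  expect_true(all(c("DSM 20174", "DSM20174", "DSM-20174") %in% v))
  # symmetry through the comparison key
  expect_equal(strain_key("LMG2003"), strain_key("LMG 2003"))
  expect_equal(strain_key("LMG-2003"), strain_key("lmg 2003"))
  expect_true(all(strain_key(strain_name_variants("LMG 2003")) ==
                    strain_key("LMG2003")))
  expect_equal(strain_name_variants("X"), "X")
  expect_equal(strain_name_variants(""), character())
  # quote and superscript markers are stripped
  expect_equal(strain_key('"DSM 20174ᵀ"'), strain_key("DSM 20174"))
})

strain_catalog_row <- function(entry_id, species, desig = character(),
                               culture = character()) {
  tibble::tibble(entry_id = entry_id, species_name = species,
                 strain_designations = list(desig),
                 culture_numbers = list(culture))
}

test_that("the three match outcomes fire on their forced cases", {
  tax <- bacillus_taxonomy()
  # (i) variant key equals an existing strain name
  m1 <- match_catalog_entry(tax, strain_catalog_row("e1", "Bacillus subtilis",
                                                    "DSM10"))
  expect_equal(m1$outcome, "synonyms_added")
  expect_equal(m1$target_taxid, "T5")
  expect_length(m1$added_names, 0)  # same comparison key, nothing new
  m1b <- match_catalog_entry(tax, strain_catalog_row("e1b", "Bacillus subtilis",
                                                     c("DSM 10", "ATCC 99")))
  expect_equal(m1b$outcome, "synonyms_added")
  expect_equal(m1b$added_names, "ATCC 99")
  # (ii) species anchors a new node
  m2 <- match_catalog_entry(tax, strain_catalog_row("e2", "Bacillus toyensis",
                                                    "XYZ 1"))
  expect_equal(m2$outcome, "node_added")
  expect_equal(m2$target_taxid, "T4")
  # (ii) genus token fallback
  m2g <- match_catalog_entry(tax, strain_catalog_row("e2g", "Bacillus novel",
                                                     "XYZ 2"))
  expect_equal(m2g$outcome, "node_added")
  expect_equal(m2g$target_taxid, "T2")
  # (iii) nothing matches
  m3 <- match_catalog_entry(tax, strain_catalog_row("e3", "Nulla missing",
                                                    "QQQ 7"))
  expect_equal(m3$outcome, "left_out")
  expect_true(is.na(m3$target_taxid))
})

test_that("an entry hitting two distinct strain nodes is ambiguous", {
  tax <- bacillus_taxonomy()
  tax$nodes <- dplyr::bind_rows(tax$nodes, tibble::tibble(
    taxid = "T7", parent = "T4", rank = "strain"))
  tax$names <- dplyr::bind_rows(tax$names, tibble::tibble(
    taxid = "T7", name = c("Bacillus toyensis CC 5", "CC 5"),
    name_class = c("scientific", "catalog")))
  m <- match_catalog_entry(tax, strain_catalog_row(
    "amb", "Bacillus subtilis", c("DSM 10", "CC 5")))
  expect_equal(m$outcome, "left_out")
  expect_true(m$ambiguous)
})

test_that("extend_taxonomy merges sequentially with consistent reports", {
  tax <- bacillus_taxonomy()
  # empty catalog: identity
  r0 <- extend_taxonomy(tax, strain_catalog_row("x", "y")[0, ])
  expect_equal(r0$taxonomy$nodes, tax$nodes)
  expect_equal(unname(sum(r0$report$counts)), 0)

  entries <- dplyr::bind_rows(
    strain_catalog_row("b1", "Bacillus subtilis", "DSM 10"),
    strain_catalog_row("b2", "Bacillus toyensis", "AAA 1"),
    strain_catalog_row("b3", "Bacillus novel", "BBB 2"),
    strain_catalog_row("b4", "Ghostia phantom", "CCC 3"))
  r <- extend_taxonomy(tax, entries)
  expect_equal(unname(r$report$counts),
               c(1, 2, 1))
  expect_equal(nrow(r$taxonomy$nodes), nrow(tax$nodes) + 2)
  expect_true(all(grepl("^EXT\\d{6}$", setdiff(r$taxonomy$nodes$taxid,
                                               tax$nodes$taxid))))
  # every added node has rank strain under a species or genus
  added <- setdiff(r$taxonomy$nodes$taxid, tax$nodes$taxid)
  for (a in added) {
    expect_equal(taxon_rank(r$taxonomy, a), "strain")
    parent <- r$taxonomy$nodes$parent[r$taxonomy$nodes$taxid == a]
    expect_true(taxon_rank(r$taxonomy, parent) %in% c("species", "genus"))
  }
  # equivalence covers exactly the non-left-out entries
  expect_setequal(r$equivalence$entry_id, c("b1", "b2", "b3"))
  # the tree is still valid
  expect_silent(validate_taxonomy(r$taxonomy))
})

test_that("the same strain listed twice merges instead of duplicating", {
  tax <- bacillus_taxonomy()
  entries <- dplyr::bind_rows(
    strain_catalog_row("c1", "Bacillus toyensis", "NEW 77"),
    strain_catalog_row("c2", "Bacillus toyensis", "NEW77"))
  r <- extend_taxonomy(tax, entries)
  expect_equal(unname(r$report$counts), c(1, 1, 0))
  expect_equal(r$equivalence$taxid[1], r$equivalence$taxid[2])
})

test_that("re-extending with the same entries adds no nodes", {
  tax <- bacillus_taxonomy()
  entries <- dplyr::bind_rows(
    strain_catalog_row("d1", "Bacillus toyensis", "QQ 1"),
    strain_catalog_row("d2", "Bacillus subtilis", "RR 2"))
  r1 <- extend_taxonomy(tax, entries)
  r2 <- extend_taxonomy(r1$taxonomy, entries)
  expect_equal(nrow(r2$taxonomy$nodes), nrow(r1$taxonomy$nodes))
  expect_equal(unname(r2$report$counts[["node_added"]]), 0)
})

test_that("report counts equal independent sequential re-classification", {
  refs <- make_toy_references(n_concepts = 12, n_taxa = 10, seed = 21)
  tax <- refs$taxonomy
  entries <- dplyr::bind_rows(
    refs$catalog,
    strain_catalog_row("gx1", paste(refs$species$name[2]), "ZZA 11"),
    strain_catalog_row("gx2", "Unknownia nowhere", "ZZB 12"))
  r <- extend_taxonomy(tax, entries)
  cur <- tax
  expected <- character(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    m <- match_catalog_entry(cur, entries[i, ])
    expected[i] <- m$outcome
    step <- extend_taxonomy(cur, entries[i, ])
    cur <- step$taxonomy
  }
  expect_equal(tidy(r$report)$outcome, expected)
  expect_error(extend_taxonomy(tax, dplyr::bind_rows(
    strain_catalog_row("dup", "A b", "X 1"),
    strain_catalog_row("dup", "A b", "X 2"))), "duplicate entry_id")
})
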