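# Shared fixture builders and independent brute-force oracles.

# milk-chain ontology used across normalization tests
milk_ontology <- function() {
  parse_obo(c(
    "[Term]", "id: HAB:0", "name: habitat", "",
    "[Term]", "id: HAB:1", "name: food", "is_a: HAB:0", "",
    "[Term]", "id: HAB:2", "name: milk", "is_a: HAB:1", "",
    "[Term]", "id: HAB:3", "name: cow milk", "is_a: HAB:2", "",
    "[Term]", "id: HAB:4", "name: milk product", "is_a: HAB:1", "",
    "[Term]", "id: PHE:0", "name: phenotype", "",
    "[Term]", "id: PHE:1", "name: mesophile", 'synonym: "mesophilic" EXACT []',
    "is_a: PHE:0", "",
    "[Term]", "id: USE:0", "name: use", "",
    "[Term]", "id: USE:1", "name: acidification", "is_a: USE:0", ""))
}

# small taxonomy with genus/species/subspecies/strain and catalog names
bacillus_taxonomy <- function() {
  nodes <- tibble::tibble(
    taxid  = c("T1", "T2", "T3", "T4", "T5", "T6"),
    parent = c("T1", "T1", "T2", "T2", "T3", "T1"),
    rank   = c("no rank", "genus", "species", "species", "strain", "genus"))
  nms <- tibble::tibble(
    taxid = c("T1", "T2", "T3", "T3", "T4", "T5", "T5", "T6"),
    name = c("Biota", "Bacillus", "Bacillus subtilis", "hay bacillus",
             "Bacillus toyensis", "Bacillus subtilis DSM 10", "DSM 10",
             "Examplella"),
    name_class = c("scientific", "scientific", "scientific", "vernacular",
                   "scientific", "scientific", "catalog", "scientific"))
  validate_taxonomy(new_taxonomy(nodes, nms, root = "T1"))
}

doc_tbl <- function(text, doc_id = "d1", source = "pubmed") {
  tibble::tibble(doc_id = doc_id, source = source, text = text)
}

# reachability by exhaustive edge relaxation, independent of the package's
# BFS helpers
bf_descendants <- function(ids, parent_sets, id) {
  desc <- character()
  repeat {
    new <- ids[vapply(parent_sets, function(p)
      any(p %in% c(id, desc)), logical(1))]
    new <- setdiff(new, c(desc, id))
    if (!length(new)) break
    desc <- c(desc, new)
  }
  sort(desc)
}

bf_descendants_ontology <- function(ont, id) {
  bf_descendants(ont$concepts$id, ont$concepts$parents, id)
}

bf_descendants_taxonomy <- function(tax, id) {
  non_root <- tax$nodes$taxid != tax$nodes$parent
  bf_descendants(tax$nodes$taxid[non_root],
                 as.list(tax$nodes$parent[non_root]), id)
}

# all root paths by exhaustive recursion over parent list-columns
bf_paths <- function(ont, id) {
  pmap <- setNames(ont$concepts$parents, ont$concepts$id)
  recur <- function(x) {
    ps <- pmap[[x]]
    if (!length(ps)) return(list(x))
    out <- list()
    for (p in ps) for (pp in recur(p)) out <- c(out, list(c(pp, x)))
    out
  }
  recur(id)
}

# brute-force ToMap: score every label/synonym of the branch, keep those
# sharing the head, pick max score with the declared tie rules
bf_tomap <- function(term_tokens, head_key, labels_tbl) {
  best <- NULL
  for (i in seq_len(nrow(labels_tbl))) {
    lab_head <- head_word(labels_tbl$label[i])
    if (is.na(lab_head) || lab_head != head_key) next
    lt <- labels_tbl$label_tokens[[i]]
    a <- unique(norm_word_oracle(term_tokens))
    sc <- length(intersect(a, lt)) / length(union(a, lt))
    cand <- list(concept_id = labels_tbl$concept_id[i], score = sc,
                 n_tokens = labels_tbl$n_tokens[i])
    if (is.null(best) ||
        sc > best$score ||
        (sc == best$score && cand$n_tokens < best$n_tokens) ||
        (sc == best$score && cand$n_tokens == best$n_tokens &&
         cand$concept_id < best$concept_id)) {
      best <- cand
    }
  }
  best
}

# independent restatement of the declared word normalization
norm_word_oracle <- function(w) {
  w <- tolower(sub("\\.$", "", w))
  long <- nchar(w) > 3
  drop <- long & grepl("s$", w) & !grepl("(ss|us)$", w)
  ifelse(drop, substr(w, 1, nchar(w) - 1), w)
}

# flat label table for bf_tomap, built straight off the concept tibble
branch_labels <- function(ont, branches = c("habitat", "phenotype")) {
  co <- ont$concepts[ont$concepts$branch %in% branches, ]
  rows <- list()
  for (i in seq_len(nrow(co))) {
    for (lab in c(co$label[i], co$synonyms[[i]])) {
      toks <- strsplit(gsub("-", " ", lab), " +")[[1]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        concept_id = co$id[i], label = lab,
        label_tokens = list(unique(norm_word_oracle(
          unlist(strsplit(lab, "[ ]+"))))),
        n_tokens = length(unlist(strsplit(lab, "[ ]+"))))
    }
  }
  dplyr::bind_rows(rows)
}

# brute-force boolean query evaluation by full scans with an independent
# ancestor walk over the raw parent columns
bf_query <- function(q, store) {
  ont <- store$ontology; tax <- store$taxonomy
  canc <- function(id) {  # concept + its ancestors, by recursion
    pmap <- setNames(ont$concepts$parents, ont$concepts$id)
    seen <- character(); todo <- id
    while (length(todo)) {
      x <- todo[[1]]; todo <- todo[-1]
      if (x %in% seen) next
      seen <- c(seen, x); todo <- c(todo, pmap[[x]])
    }
    seen
  }
  tanc <- function(id) {
    pmap <- setNames(tax$nodes$parent, tax$nodes$taxid)
    seen <- id
    while (pmap[[id]] != id) { id <- pmap[[id]]; seen <- c(seen, id) }
    seen
  }
  rec <- store$records
  leaf_taxa <- function(leaf) {
    if (leaf$kind == "qps") return(intersect(unique(rec$taxid), store$qps))
    if (leaf$kind == "source") return(unique(rec$taxid[rec$source == leaf$value]))
    if (leaf$kind == "taxon") {
      hit <- vapply(rec$taxid, function(t) leaf$value %in% tanc(t), logical(1))
      return(unique(rec$taxid[hit]))
    }
    type <- c(habitat = "lives_in", phenotype = "exhibits",
              use = "studied_for")[[leaf$kind]]
    hit <- rec$type == type &
      vapply(rec$concept_id, function(cc) leaf$value %in% canc(cc), logical(1))
    unique(rec$taxid[hit])
  }
  walk <- function(node) {
    if (!is.null(node$kind)) return(leaf_taxa(node))
    op <- intersect(names(node), c("and", "or"))
    parts <- lapply(node[[op]], walk)
    if (op == "and") Reduce(intersect, parts) else Reduce(union, parts)
  }
  sort(unique(walk(q)))
}

# random boolean query tree over the store's references
random_query <- function(store, depth = 3) {
  ont <- store$ontology; tax <- store$taxonomy
  leaf <- function() {
    kind <- sample(c("taxon", "habitat", "phenotype", "use", "qps", "source"), 1)
    switch(kind,
      qps = list(kind = "qps"),
      source = list(kind = "source",
                    value = sample(unique(c(store$records$source, "pubmed")), 1)),
      taxon = list(kind = "taxon", value = sample(tax$nodes$taxid, 1)),
      {
        ids <- ont$concepts$id[ont$concepts$branch == kind]
        list(kind = kind, value = sample(ids, 1))
      })
  }
  build <- function(d) {
    if (d <= 0 || stats::runif(1) < 0.4) return(leaf())
    op <- sample(c("and", "or"), 1)
    n <- sample(2:3, 1)
    setNames(list(lapply(seq_len(n), function(i) build(d - 1L))), op)
  }
  build(depth)
}

# GenBank flat-file fixture writer
genbank_record_lines <- function(accession, length, product = "16S ribosomal RNA",
                                 organism = "Bacillus subtilis",
                                 isolation_source = "soil", strain = NULL,
                                 feature = "rRNA") {
  c(sprintf("LOCUS       %s %19d bp    DNA     linear   BCT 01-JAN-2024",
            accession, length),
    sprintf("DEFINITION  %s partial sequence.", organism),
    sprintf("ACCESSION   %s", accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", length),
    sprintf('                     /organism="%s"', organism),
    if (!is.null(strain)) sprintf('                     /strain="%s"', strain),
    if (!is.null(isolation_source))
      sprintf('                     /isolation_source="%s"', isolation_source),
    sprintf("     %-15s 1..%d", feature, length),
    if (!is.null(product)) sprintf('                     /product="%s"', product),
    "ORIGIN",
    "        1 acgtacgtac",
    "//")
}
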