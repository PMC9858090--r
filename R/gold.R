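## Gold-annotated synthetic corpora. Documents are assembled from segment
## lists so every gold span is recorded at generation time; the templates
## realize the constructions the text-mining rules target: trigger
## sentences, genus abbreviations, strain designators, enumerations with
## cross-product readings, anaphora, and trigger-free distractors.

build_doc <- function(doc_id, source, segs) {
  text <- ""
  rows <- list()
  for (sg in segs) {
    start <- nchar(text)
    text <- paste0(text, sg$text)
    if (!is.null(sg$kind)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        doc_id = doc_id, start = start, end = start + nchar(sg$text),
        surface = sg$text, kind = sg$kind, id = sg$id)
    }
  }
  list(doc = tibble::tibble(doc_id = doc_id, source = source, text = text),
       mentions = dplyr::bind_rows(rows))
}

seg <- function(text, kind = NULL, id = NULL) list(text = text, kind = kind, id = id)

#' Names of the built-in gold templates
#' @return Character vector of template names accepted by
#'   [make_gold_corpus()].
#' @export
gold_templates <- function() {
  c("lives_in", "abbrev", "strain", "distractor", "anaphora", "pronoun",
    "coordination", "use", "exhibits")
}

# slot helpers ---------------------------------------------------------

pick_species <- function(refs, n = 1) {
  idx <- sample.int(nrow(refs$species), n)
  refs$species[idx, ]
}

pick_habitat <- function(refs, modifier_pool) {
  co <- refs$ontology$concepts
  hab <- co[co$branch == "habitat" & co$id != refs$ontology$roots[["habitat"]], ]
  i <- sample.int(nrow(hab), 1)
  syns <- hab$synonyms[[i]]
  surface <- if (length(syns) && stats::runif(1) < 0.3) syns[[1]] else hab$label[[i]]
  n_mod <- sample(0:2, 1, prob = c(0.5, 0.3, 0.2))
  mods <- if (n_mod) paste0(paste(sample(modifier_pool, n_mod), collapse = " "), " ") else ""
  list(prefix = mods, surface = surface, id = hab$id[[i]])
}

pick_phenotype <- function(refs, n = 1) {
  co <- refs$ontology$concepts
  ph <- co[co$branch == "phenotype" & co$id != refs$ontology$roots[["phenotype"]], ]
  idx <- sample.int(nrow(ph), n)
  list(adj = vapply(ph$synonyms[idx], `[[`, character(1), 1), id = ph$id[idx])
}

pick_use <- function(refs) {
  co <- refs$ontology$concepts
  us <- co[co$branch == "use" & co$id != refs$ontology$roots[["use"]], ]
  i <- sample.int(nrow(us), 1)
  list(surface = us$label[[i]], id = us$id[[i]])
}

habitat_segs <- function(h) {
  out <- list()
  if (nzchar(h$prefix)) out <- list(seg(h$prefix))
  c(out, list(seg(h$surface, "habitat", h$id)))
}

# template realizations ------------------------------------------------

gold_template <- function(name, refs, modifier_pool) {
  switch(
    name,
    lives_in = {
      sp <- pick_species(refs)
      h <- pick_habitat(refs, modifier_pool)
      list(segs = c(list(seg(sp$name, "taxon", sp$taxid),
                         seg(" was isolated from ")),
                    habitat_segs(h), list(seg("."))),
           rels = tibble::tibble(type = "lives_in", taxid = sp$taxid,
                                 concept_id = h$id))
    },
    abbrev = {
      sp <- pick_species(refs)
      h <- pick_habitat(refs, modifier_pool)
      abbrev <- sub("^(\\S)\\S*", "\\1.", sp$name)
      list(segs = c(list(seg(abbrev, "taxon", sp$taxid),
                         seg(" was isolated from ")),
                    habitat_segs(h), list(seg("."))),
           rels = tibble::tibble(type = "lives_in", taxid = sp$taxid,
                                 concept_id = h$id))
    },
    strain = {
      st <- refs$strains[sample.int(nrow(refs$strains), 1), ]
      h <- pick_habitat(refs, modifier_pool)
      list(segs = c(list(seg(paste(st$species, st$catalog_name),
                             "taxon", st$taxid),
                         seg(" was isolated from ")),
                    habitat_segs(h), list(seg("."))),
           rels = tibble::tibble(type = "lives_in", taxid = st$taxid,
                                 concept_id = h$id))
    },
    distractor = {
      sp <- pick_species(refs)
      h <- pick_habitat(refs, modifier_pool)
      list(segs = c(list(seg(sp$name, "taxon", sp$taxid),
                         seg(" was examined near ")),
                    habitat_segs(h), list(seg("."))),
           rels = empty_gold_rels())
    },
    anaphora = {
      sp <- pick_species(refs)
      h <- pick_habitat(refs, modifier_pool)
      list(segs = c(list(seg(sp$name, "taxon", sp$taxid),
                         seg(" was studied. This bacterium was isolated from ")),
                    habitat_segs(h), list(seg("."))),
           rels = tibble::tibble(type = "lives_in", taxid = sp$taxid,
                                 concept_id = h$id))
    },
    pronoun = {
      sp <- pick_species(refs)
      h <- pick_habitat(refs, modifier_pool)
      list(segs = c(list(seg(sp$name, "taxon", sp$taxid),
                         seg(" was studied. It was isolated from ")),
                    habitat_segs(h), list(seg("."))),
           rels = tibble::tibble(type = "lives_in", taxid = sp$taxid,
                                 concept_id = h$id))
    },
    coordination = {
      sp <- pick_species(refs, 3)
      ph <- pick_phenotype(refs, 2)
      list(segs = list(
        seg("A "),
        seg(ph$adj[1], "phenotype", ph$id[1]), seg("-"),
        seg(ph$adj[2], "phenotype", ph$id[2]),
        seg(" mixed culture of "),
        seg(sp$name[1], "taxon", sp$taxid[1]), seg(", "),
        seg(sp$name[2], "taxon", sp$taxid[2]), seg(" and "),
        seg(sp$name[3], "taxon", sp$taxid[3]),
        seg(" was also used.")),
        rels = tidyr::expand_grid(taxid = sp$taxid, concept_id = ph$id) |>
          dplyr::mutate(type = "exhibits", .before = 1))
    },
    use = {
      sp <- pick_species(refs)
      u <- pick_use(refs)
      list(segs = list(seg(sp$name, "taxon", sp$taxid),
                       seg(" is used as "),
                       seg(u$surface, "use", u$id), seg(".")),
           rels = tibble::tibble(type = "studied_for", taxid = sp$taxid,
                                 concept_id = u$id))
    },
    exhibits = {
      sp <- pick_species(refs)
      ph <- pick_phenotype(refs, 1)
      list(segs = list(seg(sp$name, "taxon", sp$taxid),
                       seg(" is "),
                       seg(ph$adj[1], "phenotype", ph$id[1]), seg(".")),
           rels = tibble::tibble(type = "exhibits", taxid = sp$taxid,
                                 concept_id = ph$id[1]))
    },
    stop("unknown gold template: ", name, call. = FALSE)
  )
}

empty_gold_rels <- function() {
  tibble::tibble(type = character(), taxid = character(),
                 concept_id = character())
}

#' Generate a gold-annotated synthetic corpus
#'
#' Assembles `n_docs` documents by cycling over the requested templates with
#' randomized slot fills (taxon canonical/abbreviated/strain form, habitat
#' label or synonym with 0-2 out-of-vocabulary modifier words, trigger or
#' distractor phrasing, anaphoric second sentence, 3-taxon coordination).
#' Every annotation is recorded at generation time; regeneration with the
#' same seed is byte-identical.
#'
#' @param refs References from [make_toy_references()].
#' @param n_docs Number of documents.
#' @param templates Template names (subset of [gold_templates()]).
#' @param seed Integer seed.
#' @param source Source label stamped on the documents.
#' @return A `GoldCorpus` list: `documents`, `mentions` (gold spans with
#'   ids), `relations` (gold doc-level relations), `seed`, `templates`.
#' @export
make_gold_corpus <- function(refs, n_docs = 50,
                             templates = gold_templates(), seed = 1,
                             source = "pubmed") {
  bad <- setdiff(templates, gold_templates())
  if (length(bad)) stop("unknown template(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  with_seed(seed, {
    taken <- tolower(unlist(c(
      strsplit(refs$ontology$concepts$label, "[ -]"),
      strsplit(unlist(refs$ontology$concepts$synonyms), "[ -]"),
      strsplit(refs$taxonomy$names$name, "[ -]"))))
    modifier_pool <- nonce_words(12, taken = taken)
    docs <- list(); ments <- list(); rels <- list()
    for (i in seq_len(n_docs)) {
      tmpl <- templates[((i - 1L) %% length(templates)) + 1L]
      doc_id <- sprintf("gold%05d", i)
      g <- gold_template(tmpl, refs, modifier_pool)
      b <- build_doc(doc_id, source, g$segs)
      docs[[i]] <- b$doc
      ments[[i]] <- b$mentions
      if (nrow(g$rels)) {
        rels[[length(rels) + 1L]] <- dplyr::mutate(
          g$rels, doc_id = doc_id, source = source, .before = 1)
      }
    }
    list(documents = dplyr::bind_rows(docs),
         mentions = dplyr::bind_rows(ments),
         relations = if (length(rels)) dplyr::bind_rows(rels) else
           tibble::tibble(doc_id = character(), source = character(),
                          type = character(), taxid = character(),
                          concept_id = character()),
         seed = seed, templates = templates)
  })
}
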