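## Seeded synthetic references: ontology, taxonomy, strain catalog, QPS set.
## All generated words are pronounceable CV-syllable nonce words, drawn
## without replacement and screened against the chunker's closed-class and
## suffix heuristics, so fixture vocabularies never collide with template
## filler or with each other.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

SYLLABLES <- as.vector(outer(
  c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z"),
  c("a", "e", "i", "o", "u"), paste0))

reserved_words <- function() {
  unique(c(
    DETERMINERS, CLOSED_CLASS, "of", "strain", "strains", "culture",
    "cultures", "mixed", "bacterium", "bacteria", "species", "organism",
    "microorganism", "yeast", "fungus", "microbe", "isolate", "examined",
    "near", "isolated", "found", "detected", "present", "recovered",
    "inhabit", "application", "capable", "milk"))
}

# n unique nonce words; never reserved, never matching the adjective
# suffix heuristics
nonce_words <- function(n, taken = character()) {
  reserved <- reserved_words()
  out <- character()
  while (length(out) < n) {
    w <- paste(sample(SYLLABLES, sample(2:3, 1), replace = TRUE), collapse = "")
    if (w %in% taken || w %in% out || w %in% reserved ||
        grepl(ADJ_SUFFIX_RE, w)) next
    out <- c(out, w)
  }
  out
}

capitalize <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Generate synthetic reference vocabularies
#'
#' Builds a three-branch ontology (habitat concepts as modifier chains over
#' shared head nouns, phenotypes with noun labels and adjectival synonyms,
#' uses with flat labels), a taxonomy with ranks down to strain (catalog
#' names attached to strain nodes), and a QPS subset of species. All names
#' are unique pronounceable nonce words; output is deterministic under
#' `seed`.
#'
#' @param n_concepts Total ontology size including the 3 branch roots
#'   (>= 6). Split roughly 70/20/10 across habitat/phenotype/use,
#'   mirroring the heavy habitat skew of real microbial vocabularies.
#' @param n_taxa Number of species (>= 2); genera, strains, and the root are
#'   added on top.
#' @param seed Integer seed.
#' @param habitat_depth Maximum modifier-chain depth below a habitat head
#'   concept (default 3: head, modifier head, modifier modifier head).
#' @return List `ontology`, `taxonomy`, `qps` (taxid vector), `catalog`
#'   (strain-catalog tibble usable for taxonomy extension), `seed`.
#' @export
make_toy_references <- function(n_concepts = 60, n_taxa = 20, seed = 1,
                                habitat_depth = 3) {
  if (n_concepts < 3) stop("n_concepts must be at least 3 (one root per branch)",
                           call. = FALSE)
  if (n_taxa < 2) stop("n_taxa must be at least 2", call. = FALSE)
  with_seed(seed, {
    n_free <- n_concepts - 3L
    n_use <- if (n_free >= 3) max(1L, round(n_free * 0.1)) else 0L
    n_phen <- if (n_free >= 3) max(1L, round(n_free * 0.2)) else 0L
    n_hab <- n_free - n_use - n_phen

    words <- nonce_words(3 * n_concepts + 6 * n_taxa + 40)
    w_i <- 0L
    take <- function(n) {
      out <- words[(w_i + 1L):(w_i + n)]
      w_i <<- w_i + n
      out
    }

    concepts <- tibble::tibble(
      id = c("HAB:0000", "PHE:0000", "USE:0000"),
      label = c("habitat", "phenotype", "use"),
      synonyms = list(character(), character(), character()),
      parents = list(character(), character(), character()),
      branch = c("habitat", "phenotype", "use"))

    # habitat: chains "<head>", "<mod> <head>", "<mod2> <mod> <head>"
    hab <- list()
    hid <- 0L
    while (length(hab) < n_hab) {
      head_w <- take(1)
      chain_len <- min(sample(seq_len(habitat_depth), 1), n_hab - length(hab))
      label <- head_w
      parent <- "HAB:0000"
      for (lv in seq_len(chain_len)) {
        hid <- hid + 1L
        id <- sprintf("HAB:%04d", hid)
        syn <- if (stats::runif(1) < 0.3) paste(take(1), head_w) else character()
        hab[[length(hab) + 1L]] <- tibble::tibble(
          id = id, label = label, synonyms = list(syn),
          parents = list(parent), branch = "habitat")
        parent <- id
        label <- paste(take(1), label)
      }
    }

    # phenotype: noun label + adjectival synonym
    phen <- lapply(seq_len(n_phen), function(i) {
      stem <- take(1)
      tibble::tibble(id = sprintf("PHE:%04d", i),
                     label = paste0(stem, "phile"),
                     synonyms = list(paste0(stem, "philic")),
                     parents = list("PHE:0000"), branch = "phenotype")
    })

    use <- lapply(seq_len(n_use), function(i) {
      lab <- if (stats::runif(1) < 0.4) paste(take(2), collapse = " ") else take(1)
      tibble::tibble(id = sprintf("USE:%04d", i), label = lab,
                     synonyms = list(character()),
                     parents = list("USE:0000"), branch = "use")
    })

    ont <- assign_branches(
      dplyr::bind_rows(c(list(concepts), hab, phen, use)),
      branch_roots = c(habitat = "HAB:0000", phenotype = "PHE:0000",
                       use = "USE:0000"))

    # taxonomy: root -> genera -> species -> strains
    n_genus <- max(2L, ceiling(n_taxa / 4))
    genus_w <- capitalize(take(n_genus))
    nodes <- tibble::tibble(taxid = "T0001", parent = "T0001", rank = "no rank")
    names_tbl <- tibble::tibble(taxid = "T0001", name = "Biota",
                                name_class = "scientific")
    tid <- 1L
    new_id <- function() {
      tid <<- tid + 1L
      sprintf("T%04d", tid)
    }
    genus_ids <- character(n_genus)
    for (g in seq_len(n_genus)) {
      genus_ids[g] <- new_id()
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        taxid = genus_ids[g], parent = "T0001", rank = "genus"))
      names_tbl <- dplyr::bind_rows(names_tbl, tibble::tibble(
        taxid = genus_ids[g], name = genus_w[g], name_class = "scientific"))
    }
    species <- tibble::tibble(taxid = character(), name = character(),
                              genus = character())
    for (s in seq_len(n_taxa)) {
      g <- ((s - 1L) %% n_genus) + 1L
      id <- new_id()
      nm <- paste(genus_w[g], take(1))
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        taxid = id, parent = genus_ids[g], rank = "species"))
      names_tbl <- dplyr::bind_rows(names_tbl, tibble::tibble(
        taxid = id, name = nm, name_class = "scientific"))
      if (stats::runif(1) < 0.3) {
        names_tbl <- dplyr::bind_rows(names_tbl, tibble::tibble(
          taxid = id, name = paste(capitalize(take(1)), take(1)),
          name_class = "synonym"))
      }
      species <- dplyr::bind_rows(species, tibble::tibble(
        taxid = id, name = nm, genus = genus_w[g]))
    }
    # strains with culture-collection catalog names for ~half the species
    strains <- tibble::tibble(taxid = character(), species = character(),
                              catalog_name = character())
    for (s in seq_len(nrow(species))) {
      if (s %% 2 == 0) next
      id <- new_id()
      code <- paste(sample(LETTERS, 3, replace = TRUE), collapse = "")
      num <- sample.int(999, 1)
      cat_nm <- paste(code, num)
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        taxid = id, parent = species$taxid[s], rank = "strain"))
      names_tbl <- dplyr::bind_rows(names_tbl, tibble::tibble(
        taxid = id,
        name = c(paste(species$name[s], cat_nm), cat_nm),
        name_class = c("scientific", "catalog")))
      strains <- dplyr::bind_rows(strains, tibble::tibble(
        taxid = id, species = species$name[s], catalog_name = cat_nm))
    }
    tax <- validate_taxonomy(new_taxonomy(nodes, names_tbl, root = "T0001"))

    qps <- sort(sample(species$taxid, max(1L, floor(n_taxa / 3))))

    catalog <- tibble::tibble(
      entry_id = sprintf("BD%04d", seq_len(nrow(strains))),
      species_name = strains$species,
      strain_designations = lapply(strsplit(strains$catalog_name, " "),
                                   function(p) paste(p, collapse = " ")),
      culture_numbers = rep(list(character()), nrow(strains)))

    list(ontology = ont, taxonomy = tax, qps = qps, catalog = catalog,
         species = species, strains = strains, seed = seed)
  })
}

#' Generate a random relation multiset over fixture references
#'
#' Draws relations with branch-consistent objects, several sources, and
#' duplicated (taxon, object, source) triples so that per-source merging has
#' work to do. Used to seed stores for query testing.
#'
#' @param refs Result of [make_toy_references()].
#' @param n Number of relation rows.
#' @param seed Integer seed.
#' @param sources Source labels to draw from.
#' @return Relation tibble.
#' @export
make_random_relations <- function(refs, n = 200, seed = 1,
                                  sources = c("pubmed", "genbank", "bacdive")) {
  ont <- refs$ontology
  tax <- refs$taxonomy
  with_seed(seed, {
    taxa <- tax$nodes$taxid[tax$nodes$rank %in% c("species", "strain")]
    pool <- list(
      lives_in = ont$concepts$id[ont$concepts$branch == "habitat" &
                                   ont$concepts$id != "HAB:0000"],
      exhibits = ont$concepts$id[ont$concepts$branch == "phenotype" &
                                   ont$concepts$id != "PHE:0000"],
      studied_for = ont$concepts$id[ont$concepts$branch == "use" &
                                      ont$concepts$id != "USE:0000"])
    type <- sample(names(pool), n, replace = TRUE,
                   prob = c(0.6, 0.25, 0.15))
    tibble::tibble(
      doc_id = sprintf("doc%05d", sample.int(max(2L, n %/% 2), n, replace = TRUE)),
      type = type,
      taxid = sample(taxa, n, replace = TRUE),
      concept_id = vapply(type, function(t) sample(pool[[t]], 1), character(1)),
      sentence_start = 0L, sentence_end = 0L,
      trigger = NA_character_,
      source = sample(sources, n, replace = TRUE))
  })
}
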