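#' Field mapping for a structured source
#'
#' Declares how the fields of a fielded source (culture-collection catalog,
#' sequence database) route into the knowledge-base slots. Mappings are
#' data, not code: shipping a new source means shipping a new mapping.
#'
#' @param source Source name.
#' @param mapping Named character vector: field name -> slot, slot one of
#'   `taxon_text`, `strain_text`, `habitat_text`, `ignore`.
#' @return An `hm_field_mapping`.
#' @export
field_mapping <- function(source, mapping) {
  slots <- c("taxon_text", "strain_text", "habitat_text", "ignore")
  bad <- setdiff(unique(mapping), slots)
  if (length(bad)) stop("unknown slot(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!any(mapping == "taxon_text") || !any(mapping == "habitat_text")) {
    stop("mapping must route at least one field to taxon_text and one to habitat_text",
         call. = FALSE)
  }
  structure(list(source = source, mapping = mapping),
            class = "hm_field_mapping")
}

#' Read a field mapping from YAML
#'
#' Expected shape: `source: <name>` and `fields: {<field>: <slot>, ...}`.
#'
#' @param path YAML path.
#' @return An [field_mapping()] object.
#' @export
read_field_mapping <- function(path) {
  cfg <- yaml::read_yaml(path)
  field_mapping(cfg$source, unlist(cfg$fields))
}

#' Route one fielded record through a mapping
#'
#' @param rec Named list or one-row data frame of field values.
#' @param fm An [field_mapping()].
#' @return List with `taxon_text`, `strain_text`, `habitat_text` character
#'   vectors (empty values dropped).
#' @export
align_record <- function(rec, fm) {
  if (is.data.frame(rec)) rec <- as.list(rec[1, ])
  absent <- setdiff(names(fm$mapping), names(rec))
  if (length(absent)) {
    stop("mapping for source '", fm$source, "' references absent field(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  pick <- function(slot) {
    v <- unlist(rec[names(fm$mapping)[fm$mapping == slot]], use.names = FALSE)
    v <- trimws(as.character(v %||% character()))
    v[!is.na(v) & nzchar(v)]
  }
  list(taxon_text = pick("taxon_text"), strain_text = pick("strain_text"),
       habitat_text = pick("habitat_text"))
}

#' Relations from one structured record
#'
#' Structured sources already pair their taxon and habitat fields, so
#' relation extraction is skipped: the taxon is resolved by lexicon lookup
#' (the most specific resolved node wins, strain designators over species
#' names), each habitat text is term-extracted and normalized, and one
#' lives_in relation is emitted per (taxon, normalized habitat concept).
#' Structured sources feed habitats only; no exhibits/studied_for relations
#' are produced here.
#'
#' @param taxon_texts,strain_texts,habitat_texts Character vectors from
#'   [align_record()].
#' @param tax Taxonomy (for strain-designator resolution).
#' @param idx Head index over the habitat branch.
#' @param lex Taxon lexicon.
#' @param source Source label.
#' @param record_id Identifier recorded as the relation's document id.
#' @return Relation tibble ([extract_relations()] shape, trigger `NA`);
#'   zero rows when the taxon or all habitats fail to resolve.
#' @export
structured_to_relations <- function(taxon_texts, strain_texts, habitat_texts,
                                    tax, idx, lex, source = "db",
                                    record_id = NA_character_) {
  taxid <- NA_character_
  # strain designators first: catalog-key lookup, most specific node
  strain_nodes <- tax$nodes$taxid[tax$nodes$rank == "strain"]
  snames <- tax$names[tax$names$taxid %in% strain_nodes, ]
  skeys <- strain_key(snames$name)
  for (st in strain_texts) {
    keys <- unique(strain_key(strain_name_variants(st)))
    hit <- unique(snames$taxid[skeys %in% keys])
    if (length(hit) == 1) { taxid <- hit; break }
  }
  if (is.na(taxid)) {
    for (tt in c(taxon_texts, strain_texts)) {
      taxid <- resolve_taxon_text(tt, lex)
      if (!is.na(taxid)) break
    }
  }
  if (is.na(taxid) || !length(habitat_texts)) return(empty_relations())
  concepts <- character()
  for (ht in habitat_texts) {
    doc <- tibble::tibble(doc_id = "field", source = source, text = ht)
    ents <- normalize_terms(extract_candidate_terms(doc), idx)
    concepts <- c(concepts, ents$id[ents$kind == "habitat"])
  }
  if (!length(concepts)) return(empty_relations())
  tibble::tibble(
    doc_id = record_id, type = "lives_in", taxid = taxid,
    concept_id = sort(unique(concepts)), sentence_start = NA_integer_,
    sentence_end = NA_integer_, trigger = NA_character_, source = source)
}

#' Ingest a table of fielded records
#'
#' Applies [align_record()] and [structured_to_relations()] to each row of a
#' fielded table.
#'
#' @param records Data frame of source records (one row each, `record_id`
#'   column or row number used as identifier).
#' @param fm Field mapping.
#' @param tax Taxonomy.
#' @param idx Head index.
#' @param lex Taxon lexicon.
#' @return List: `relations` (bound tibble) and `report` (per-record tibble
#'   with `record_id`, `status` in kept/no_taxon/no_habitat).
#' @export
ingest_structured <- function(records, fm, tax, idx, lex) {
  rel <- list(); rep <- list()
  ids <- if ("record_id" %in% names(records)) records$record_id else
    as.character(seq_len(nrow(records)))
  for (i in seq_len(nrow(records))) {
    slots <- align_record(records[i, ], fm)
    r <- structured_to_relations(slots$taxon_text, slots$strain_text,
                                 slots$habitat_text, tax, idx, lex,
                                 source = fm$source, record_id = ids[i])
    status <- if (nrow(r)) "kept" else if (
      all(is.na(resolve_taxon_text(paste(slots$taxon_text, collapse = " "), lex))) &&
      !length(slots$strain_text)) "no_taxon" else "no_habitat"
    rel[[i]] <- r
    rep[[i]] <- tibble::tibble(record_id = ids[i], status = status,
                               n_relations = nrow(r))
  }
  list(relations = dplyr::bind_rows(rel), report = dplyr::bind_rows(rep))
}

#' Load and resolve a QPS species list
#'
#' One species name per line; names are resolved through the taxon lexicon.
#' Names that resolve only at genus level (or not at all) are excluded and
#' reported.
#'
#' @param x Path or character vector of names.
#' @param lex Taxon lexicon.
#' @param tax Taxonomy (rank check).
#' @return Tibble `name`, `taxid`, `status` (resolved / genus_level /
#'   unresolved); [qps_taxids()] extracts the resolved set.
#' @export
load_qps_list <- function(x, lex, tax) {
  names <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE) else x
  names <- trimws(names)
  names <- names[nzchar(names)]
  if (!length(names)) {
    return(tibble::tibble(name = character(), taxid = character(),
                          status = character()))
  }
  taxid <- vapply(names, resolve_taxon_text, character(1), lex = lex,
                  USE.NAMES = FALSE)
  rank <- taxon_rank(tax, taxid)
  status <- dplyr::case_when(
    is.na(taxid) ~ "unresolved",
    rank %in% c("species", "subspecies", "strain") ~ "resolved",
    TRUE ~ "genus_level")
  tibble::tibble(name = names,
                 taxid = ifelse(status == "resolved", taxid, NA_character_),
                 status = status)
}

#' @rdname load_qps_list
#' @param qps Tibble returned by [load_qps_list()].
#' @return Character vector of resolved taxids.
#' @export
qps_taxids <- function(qps) sort(unique(stats::na.omit(qps$taxid)))
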