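#' Common variations of a strain name
#'
#' Culture-collection identifiers are typeset inconsistently ("DSM 20174",
#' "DSM20174", "DSM-20174", superscript type-strain markers, quotes). This
#' returns the closed set of surface variants used when matching catalog
#' entries against taxonomy names; [strain_key()] gives the case-folded
#' comparison key shared by all variants of the same identifier.
#'
#' @param name A strain designation or culture-collection number.
#' @return Character vector of variants (empty for an empty name).
#' @export
strain_name_variants <- function(name) {
  name <- strip_strain_markers(name)
  if (!nzchar(name)) return(character())
  collapsed <- stringr::str_squish(name)
  out <- unique(c(name, collapsed))
  # collection code + number: join/split forms
  m <- stringr::str_match(collapsed, "^([A-Za-z]+)[ -]?(\\d[\\w.-]*)$")
  if (!is.na(m[1, 1])) {
    code <- m[1, 2]; num <- m[1, 3]
    out <- unique(c(out, paste0(code, " ", num), paste0(code, num),
                    paste0(code, "-", num)))
  }
  out
}

# superscript type-strain markers and quote decorations
strip_strain_markers <- function(x) {
  x <- gsub("[\"'‘’“”]", "", x)
  x <- gsub("[ᵀ⁰-₟]", "", x)  # unicode superscripts (e.g. ᵀ)
  trimws(x)
}

#' Comparison key for strain-name matching
#'
#' Case-folded, with all non-alphanumeric characters removed, so every
#' variant produced by [strain_name_variants()] maps to the same key.
#'
#' @param name Character vector of names.
#' @return Character vector of keys.
#' @export
strain_key <- function(name) {
  tolower(gsub("[^A-Za-z0-9]+", "", strip_strain_markers(name)))
}

#' Read a strain catalog table
#'
#' Expects a TSV/CSV with header columns `entry_id`, `species_name`,
#' `strain_designations`, `culture_numbers`; the two list columns are
#' `;`-separated.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Tibble with list columns `strain_designations`, `culture_numbers`.
#' @export
read_strain_catalog <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character")
  split_col <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                  function(v) trimws(v[nzchar(trimws(v))]))
  tibble::tibble(
    entry_id = df$entry_id,
    species_name = trimws(df$species_name),
    strain_designations = split_col(df$strain_designations),
    culture_numbers = split_col(df$culture_numbers)
  )
}

#' Match one catalog entry against the taxonomy
#'
#' Applies the three-outcome rule used to merge culture-collection entries
#' into the taxonomic reference:
#' (i) if any variant of an entry name equals (by [strain_key()]) a name of a
#' strain-rank node, new synonyms are added to that strain;
#' (ii) otherwise, if the species name (or its genus token) identifies a
#' species or genus node, a new strain node is created under it;
#' (iii) otherwise the entry is left out of the reference.
#' An entry whose names hit two distinct strain nodes is ambiguous and left
#' out.
#'
#' @param tax A validated taxonomy.
#' @param entry One row of a [read_strain_catalog()] tibble (as a list or
#'   one-row data frame).
#' @return A list with `entry_id`, `outcome` (one of `"synonyms_added"`,
#'   `"node_added"`, `"left_out"`), `target_taxid` (NA for `left_out`),
#'   `added_names`, and `ambiguous` flag.
#' @export
match_catalog_entry <- function(tax, entry) {
  if (is.data.frame(entry)) entry <- as.list(entry[1, ])
  entry$strain_designations <- unlist(entry$strain_designations) %||% character()
  entry$culture_numbers <- unlist(entry$culture_numbers) %||% character()
  # strain designations take precedence over culture numbers
  entry_names <- c(entry$strain_designations, entry$culture_numbers)
  entry_names <- entry_names[nzchar(entry_names)]

  strain_nodes <- tax$nodes$taxid[tax$nodes$rank == "strain"]
  snames <- tax$names[tax$names$taxid %in% strain_nodes, ]
  skeys <- strain_key(snames$name)

  hit_nodes <- character()
  for (nm in entry_names) {
    keys <- unique(strain_key(strain_name_variants(nm)))
    hit_nodes <- unique(c(hit_nodes, snames$taxid[skeys %in% keys]))
  }
  res <- function(outcome, target = NA_character_, added = character(),
                  ambiguous = FALSE) {
    list(entry_id = entry$entry_id, outcome = outcome, target_taxid = target,
         added_names = added, ambiguous = ambiguous)
  }
  if (length(hit_nodes) > 1) return(res("left_out", ambiguous = TRUE))
  if (length(hit_nodes) == 1) {
    present <- strain_key(snames$name[snames$taxid == hit_nodes])
    added <- entry_names[!strain_key(entry_names) %in% present]
    return(res("synonyms_added", target = hit_nodes, added = unique(added)))
  }
  # (ii): anchor on species name, then its genus token
  name_key <- function(x) tolower(stringr::str_squish(x))
  anchor <- NA_character_
  if (nzchar(entry$species_name %||% "")) {
    sp_nodes <- tax$nodes$taxid[tax$nodes$rank %in% c("species", "subspecies")]
    cand <- tax$names[tax$names$taxid %in% sp_nodes, ]
    hit <- cand$taxid[name_key(cand$name) == name_key(entry$species_name)]
    if (length(hit)) anchor <- hit[[1]]
    if (is.na(anchor)) {
      genus_tok <- strsplit(stringr::str_squish(entry$species_name), " ")[[1]][1]
      g_nodes <- tax$nodes$taxid[tax$nodes$rank == "genus"]
      gcand <- tax$names[tax$names$taxid %in% g_nodes, ]
      ghit <- gcand$taxid[name_key(gcand$name) == name_key(genus_tok)]
      if (length(ghit)) anchor <- ghit[[1]]
    }
  }
  if (is.na(anchor) || !length(entry_names)) return(res("left_out"))
  res("node_added", target = anchor, added = unique(entry_names))
}

#' Extend the taxonomy with a strain catalog
#'
#' Applies [match_catalog_entry()] sequentially (earlier entries are visible
#' to later ones, so the same strain listed twice merges instead of
#' duplicating). New nodes get fresh taxids `EXT000001`, `EXT000002`, ... in
#' a namespace disjoint from the input ids.
#'
#' @param tax A validated taxonomy.
#' @param entries Strain catalog tibble ([read_strain_catalog()] shape).
#' @return A list with `taxonomy` (extended, still a valid tree), `report`
#'   (class `hm_merge_report`: per-outcome counts plus per-entry outcomes),
#'   and `equivalence` (tibble `entry_id`, `taxid` for non-left-out entries).
#' @export
extend_taxonomy <- function(tax, entries) {
  if (anyDuplicated(entries$entry_id)) {
    stop("duplicate entry_id(s): ",
         paste(unique(entries$entry_id[duplicated(entries$entry_id)]),
               collapse = ", "), call. = FALSE)
  }
  existing_ext <- grep("^EXT\\d+$", tax$nodes$taxid, value = TRUE)
  counter <- if (length(existing_ext))
    max(as.integer(sub("^EXT", "", existing_ext))) else 0L

  outcomes <- vector("list", nrow(entries))
  equiv <- list()
  for (i in seq_len(nrow(entries))) {
    entry <- as.list(entries[i, ])
    m <- match_catalog_entry(tax, entry)
    if (m$outcome == "synonyms_added" && length(m$added_names)) {
      tax$names <- dplyr::bind_rows(
        tax$names,
        tibble::tibble(taxid = m$target_taxid, name = m$added_names,
                       name_class = "catalog"))
    } else if (m$outcome == "node_added") {
      counter <- counter + 1L
      new_id <- sprintf("EXT%06d", counter)
      sci <- stringr::str_squish(paste(entry$species_name, m$added_names[[1]]))
      tax$nodes <- dplyr::bind_rows(
        tax$nodes,
        tibble::tibble(taxid = new_id, parent = m$target_taxid, rank = "strain"))
      tax$names <- dplyr::bind_rows(
        tax$names,
        tibble::tibble(taxid = new_id, name = sci, name_class = "scientific"),
        tibble::tibble(taxid = new_id, name = m$added_names,
                       name_class = "catalog"))
      m$target_taxid <- new_id
    }
    outcomes[[i]] <- m
    if (m$outcome != "left_out") {
      equiv[[length(equiv) + 1L]] <- tibble::tibble(
        entry_id = m$entry_id, taxid = m$target_taxid)
    }
  }
  validate_taxonomy(tax)
  per_entry <- tibble::tibble(
    entry_id = vapply(outcomes, `[[`, character(1), "entry_id"),
    outcome = vapply(outcomes, `[[`, character(1), "outcome"),
    target_taxid = vapply(outcomes, `[[`, character(1), "target_taxid"),
    n_added_names = vapply(outcomes, function(m) length(m$added_names), integer(1)),
    ambiguous = vapply(outcomes, `[[`, logical(1), "ambiguous")
  )
  report <- structure(list(
    counts = c(
      synonyms_added = sum(per_entry$outcome == "synonyms_added"),
      node_added = sum(per_entry$outcome == "node_added"),
      left_out = sum(per_entry$outcome == "left_out")),
    nodes_added = sum(per_entry$outcome == "node_added"),
    synonyms_added = sum(per_entry$n_added_names[per_entry$outcome == "synonyms_added"]),
    per_entry = per_entry
  ), class = "hm_merge_report")
  list(taxonomy = tax,
       report = report,
       equivalence = if (length(equiv)) dplyr::bind_rows(equiv) else
         tibble::tibble(entry_id = character(), taxid = character()))
}

#' @export
print.hm_merge_report <- function(x, ...) {
  cat("<hm_merge_report> entries:", sum(x$counts),
      "| synonyms_added:", x$counts[["synonyms_added"]],
      "| node_added:", x$counts[["node_added"]],
      "| left_out:", x$counts[["left_out"]],
      "| new synonyms:", x$synonyms_added, "\n")
  invisible(x)
}
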