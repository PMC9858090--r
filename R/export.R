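#' Export query results as CSV
#'
#' RFC-4180-quoted CSV of the records supporting a query result, with a
#' selectable column set and deterministic row order.
#'
#' @param results Result of [evaluate_query()] (its `support` attribute is
#'   used), or a knowledge-record tibble.
#' @param store The store queried (labels and ranks).
#' @param columns Columns to include, from: taxid, taxon_name, rank, type,
#'   object_id, object_label, source, evidence, count.
#' @param path Optional output path; when `NULL` the CSV lines are returned.
#' @return Character vector of CSV lines (invisibly when written).
#' @export
export_csv <- function(results, store,
                       columns = c("taxid", "taxon_name", "rank", "type",
                                   "object_id", "object_label", "source",
                                   "evidence", "count"),
                       path = NULL) {
  known <- c("taxid", "taxon_name", "rank", "type", "object_id",
             "object_label", "source", "evidence", "count")
  bad <- setdiff(columns, known)
  if (length(bad)) stop("unknown column(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  rec <- if (is.data.frame(results) && !is.null(attr(results, "support"))) {
    sup <- attr(results, "support")
    all <- dplyr::distinct(dplyr::bind_rows(sup))
    all[all$taxid %in% results$taxid, ]
  } else {
    results
  }
  tab <- tibble::tibble(
    taxid = rec$taxid,
    taxon_name = scientific_name(store$taxonomy, rec$taxid),
    rank = taxon_rank(store$taxonomy, rec$taxid),
    type = rec$type,
    object_id = rec$concept_id,
    object_label = concept_label(store$ontology, rec$concept_id),
    source = rec$source,
    evidence = vapply(rec$evidence, paste, character(1), collapse = ";"),
    count = rec$count
  )[, columns, drop = FALSE]
  tab <- dplyr::arrange(tab, dplyr::across(dplyr::everything()))
  quote_field <- function(x) {
    x <- as.character(x)
    need <- grepl('[",\n]', x)
    x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
    x
  }
  lines <- c(paste(quote_field(columns), collapse = ","),
             apply(as.data.frame(lapply(tab, quote_field)), 1,
                   paste, collapse = ","))
  lines <- unname(lines)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

RANK_BANDS <- list(
  strain = c("strain", "isolate"),
  species_and_subspecies = c("species", "subspecies", "varietas", "morph",
                             "forma"),
  genus_and_subgenus = c("genus", "subgenus", "section", "series"),
  family_and_subfamily = c("family", "subfamily", "tribe")
)

rank_band <- function(rank) {
  out <- rep("higher", length(rank))
  for (b in names(RANK_BANDS)) out[rank %in% RANK_BANDS[[b]]] <- b
  out
}

#' Summary tables over a knowledge store
#'
#' Computes the descriptive aggregations used to profile the knowledge
#' base: per-source relation-type counts; the rank-band distribution of
#' subjects of lives_in records (strain / species+subspecies /
#' genus+subgenus / family+subfamily / higher); counts per top-level
#' habitat (descendant-expanded); habitat frequency versus distinct-taxa
#' diversity; and the phenotype co-occurrence matrix (Jaccard index between
#' the taxa sets of each phenotype pair).
#'
#' @param store An `hm_store`.
#' @return List of tibbles: `per_source_type`, `rank_bands`,
#'   `top_habitats`, `habitat_diversity`, `phenotype_cooccurrence`.
#' @export
summarize_store <- function(store) {
  rec <- store$records
  per_source_type <- rec |>
    dplyr::count(.data$source, .data$type, wt = .data$count, name = "n") |>
    dplyr::arrange(.data$source, .data$type)

  li <- rec[rec$type == "lives_in", ]
  rank_bands <- li |>
    dplyr::mutate(band = rank_band(taxon_rank(store$taxonomy, .data$taxid))) |>
    dplyr::count(.data$band, wt = .data$count, name = "n") |>
    dplyr::arrange(.data$band)

  hab_root <- store$ontology$roots[["habitat"]]
  top <- store$ontology$concepts$id[
    vapply(store$ontology$concepts$parents, function(p) hab_root %in% p,
           logical(1))]
  top_habitats <- dplyr::bind_rows(lapply(sort(top), function(h) {
    sub <- records_at_concept(store, h)
    sub <- sub[sub$type == "lives_in", ]
    tibble::tibble(habitat = h, label = concept_label(store$ontology, h),
                   n_relations = sum(sub$count),
                   n_taxa = length(unique(sub$taxid)))
  }))

  habitat_diversity <- li |>
    dplyr::group_by(concept_id = .data$concept_id) |>
    dplyr::summarise(n_relations = sum(.data$count),
                     n_taxa = dplyr::n_distinct(.data$taxid),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_relations), .data$concept_id)

  ex <- rec[rec$type == "exhibits", ]
  phen <- sort(unique(ex$concept_id))
  pairs <- tidyr::expand_grid(a = phen, b = phen)
  phenotype_cooccurrence <- if (nrow(pairs)) {
    sets <- lapply(phen, function(p) unique(ex$taxid[ex$concept_id == p]))
    names(sets) <- phen
    pairs$jaccard <- purrr::map2_dbl(pairs$a, pairs$b, function(a, b) {
      length(intersect(sets[[a]], sets[[b]])) /
        length(union(sets[[a]], sets[[b]]))
    })
    pairs
  } else {
    tibble::tibble(a = character(), b = character(), jaccard = double())
  }

  list(per_source_type = per_source_type, rank_bands = rank_bands,
       top_habitats = top_habitats, habitat_diversity = habitat_diversity,
       phenotype_cooccurrence = phenotype_cooccurrence)
}

#' Deterministic text dump of a store
#'
#' Fixed-format serialization of the records (evidence flattened), used to
#' check byte-identical reproducibility of pipeline runs.
#'
#' @param store An `hm_store`.
#' @return Character vector of lines.
#' @export
store_dump <- function(store) {
  rec <- store$records
  c(paste0("# records=", nrow(rec), " qps=", length(store$qps)),
    paste(rec$type, rec$taxid, rec$concept_id, rec$source,
          vapply(rec$evidence, paste, character(1), collapse = ";"),
          rec$count, sep = "\t"))
}
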