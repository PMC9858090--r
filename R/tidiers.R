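#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a knowledge store into its record table
#'
#' @param x An `hm_store`.
#' @param ... Unused.
#' @return Tibble of records with evidence flattened to a `;`-separated
#'   string plus resolved taxon/concept labels.
#' @method tidy hm_store
#' @export
tidy.hm_store <- function(x, ...) {
  rec <- x$records
  tibble::tibble(
    type = rec$type, taxid = rec$taxid,
    taxon_name = scientific_name(x$taxonomy, rec$taxid),
    rank = taxon_rank(x$taxonomy, rec$taxid),
    concept_id = rec$concept_id,
    concept_label = concept_label(x$ontology, rec$concept_id),
    source = rec$source,
    evidence = vapply(rec$evidence, paste, character(1), collapse = ";"),
    count = rec$count)
}

#' One-row summary of a knowledge store
#'
#' @param x An `hm_store`.
#' @param ... Unused.
#' @return Tibble with record, taxon, concept, source, and QPS tallies.
#' @method glance hm_store
#' @export
glance.hm_store <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$records),
    n_evidence = sum(x$records$count),
    n_taxa = length(unique(x$records$taxid)),
    n_concepts = length(unique(x$records$concept_id)),
    n_sources = length(unique(x$records$source)),
    n_qps = length(x$qps))
}

#' Per-entry outcomes of a taxonomy merge
#'
#' @param x An `hm_merge_report`.
#' @param ... Unused.
#' @return The per-entry outcome tibble.
#' @method tidy hm_merge_report
#' @export
tidy.hm_merge_report <- function(x, ...) x$per_entry

#' One-row summary of a taxonomy merge
#'
#' @param x An `hm_merge_report`.
#' @param ... Unused.
#' @return Tibble with outcome counts and totals.
#' @method glance hm_merge_report
#' @export
glance.hm_merge_report <- function(x, ...) {
  tibble::tibble(
    n_entries = sum(x$counts),
    synonyms_added = x$counts[["synonyms_added"]],
    node_added = x$counts[["node_added"]],
    left_out = x$counts[["left_out"]],
    n_new_nodes = x$nodes_added,
    n_new_synonyms = x$synonyms_added)
}

#' Per-stage counts of a pipeline run
#'
#' @param x An `hm_pipeline`.
#' @param ... Unused.
#' @return The per-stage count tibble (with evaluation rows when present).
#' @method tidy hm_pipeline
#' @export
tidy.hm_pipeline <- function(x, ...) {
  if (is.null(x$evaluation)) return(x$counts)
  dplyr::bind_rows(
    dplyr::mutate(x$counts, layer = NA_character_),
    dplyr::mutate(x$evaluation, stage = "evaluation", n = NA_integer_))
}

#' One-row summary of a pipeline run
#'
#' @param x An `hm_pipeline`.
#' @param ... Unused.
#' @return Tibble of stage tallies (wide), plus macro-averaged F1 when the
#'   run was evaluated.
#' @method glance hm_pipeline
#' @export
glance.hm_pipeline <- function(x, ...) {
  out <- tidyr::pivot_wider(x$counts, names_from = "stage", values_from = "n")
  if (!is.null(x$evaluation)) out$macro_f1 <- mean(x$evaluation$f1)
  out
}

#' Plot per-source relation-type volumes of a store
#'
#' @param object An `hm_store`.
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @method autoplot hm_store
#' @export
autoplot.hm_store <- function(object, ...) {
  tab <- summarize_store(object)$per_source_type
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$source, y = .data$n,
                                    fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "source", y = "relations (with duplicates merged)",
                  fill = "relation") +
    ggplot2::theme_minimal()
}

#' Plot per-stage volumes of a pipeline run
#'
#' @param object An `hm_pipeline`.
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @method autoplot hm_pipeline
#' @export
autoplot.hm_pipeline <- function(object, ...) {
  counts <- dplyr::mutate(object$counts,
                          stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "items") +
    ggplot2::theme_minimal()
}

#' Phenotype co-occurrence heat map
#'
#' Tiles the Jaccard index between the taxa sets of each phenotype pair, the
#' store-consistency view used to check that incompatible phenotypes are
#' rarely predicted for the same organism.
#'
#' @param store An `hm_store`.
#' @return A ggplot tile chart.
#' @export
plot_phenotype_cooccurrence <- function(store) {
  tab <- summarize_store(store)$phenotype_cooccurrence
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$a, y = .data$b,
                                    fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
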