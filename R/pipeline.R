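#' Run the full mining pipeline
#'
#' Executes the end-to-end flow: build the taxon lexicon, recognize taxon
#' mentions (with strain attachment), extract candidate terms, normalize
#' them against the habitat and phenotype branches, match use mentions,
#' resolve anaphora, extract relations, ingest structured sources, then
#' deduplicate per source and build the indexed store. When gold
#' annotations are supplied, precision/recall/F1 are reported per layer.
#'
#' @param docs Document tibble (may have zero rows).
#' @param ont Ontology.
#' @param tax Taxonomy (extended reference).
#' @param qps QPS taxid vector.
#' @param triggers Trigger lexicon.
#' @param heuristics Optional heuristic rules for [apply_heuristics()].
#' @param structured Optional list of `list(records =, mapping =)` pairs for
#'   [ingest_structured()].
#' @param anaphora_window Sentence window for [resolve_anaphora()].
#' @param gold Optional gold corpus ([make_gold_corpus()] shape).
#' @return List: `store`, `mentions` (all layers combined), `taxon_mentions`,
#'   `entities`, `use_mentions`, `relations`, `counts` (per-stage tallies),
#'   and `evaluation` when gold was given.
#' @export
run_pipeline <- function(docs, ont, tax, qps = character(),
                         triggers = default_triggers(), heuristics = NULL,
                         structured = NULL, anaphora_window = 2L,
                         gold = NULL) {
  lex <- build_taxon_lexicon(tax)
  taxa <- match_taxa(docs, lex)
  taxa <- recognize_strain_mentions(docs, taxa, tax)
  terms <- extract_candidate_terms(docs, exclude = taxa)
  idx <- build_head_index(ont, branches = c("habitat", "phenotype"))
  ents <- normalize_terms(terms, idx)
  if (!is.null(heuristics)) {
    ents <- apply_heuristics(ents, heuristics, docs = docs, ont = ont)
  }
  uses <- match_uses(docs, ont)
  links <- resolve_anaphora(docs, taxa, window = anaphora_window)
  rels <- extract_relations(docs, taxa, dplyr::bind_rows(ents, uses),
                            links = links, lex = triggers)
  if (!is.null(structured)) {
    for (src in structured) {
      ing <- ingest_structured(src$records, src$mapping, tax, idx, lex)
      rels <- dplyr::bind_rows(rels, ing$relations)
    }
  }
  records <- deduplicate(rels)
  store <- build_store(records, ont, tax, qps = qps)
  mentions <- dplyr::bind_rows(
    taxa[, c("doc_id", "start", "end", "surface", "kind", "id")],
    ents[, c("doc_id", "start", "end", "surface", "kind", "id")],
    uses[, c("doc_id", "start", "end", "surface", "kind", "id")])
  counts <- tibble::tibble(
    stage = c("documents", "taxon_mentions", "candidate_terms",
              "normalized_entities", "use_mentions", "anaphora_links",
              "relations", "records"),
    n = c(nrow(docs), nrow(taxa), nrow(terms), nrow(ents), nrow(uses),
          nrow(links), nrow(rels), nrow(records)))
  out <- list(store = store, mentions = mentions, taxon_mentions = taxa,
              entities = ents, use_mentions = uses, relations = rels,
              counts = counts)
  if (!is.null(gold)) {
    out$evaluation <- evaluate_extraction(mentions, rels, gold)
  }
  structure(out, class = "hm_pipeline")
}

#' @export
print.hm_pipeline <- function(x, ...) {
  cat("<hm_pipeline>\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-20s %d\n", x$counts$stage[i], x$counts$n[i]))
  }
  if (!is.null(x$evaluation)) {
    cat("  evaluation:\n")
    e <- x$evaluation
    for (i in seq_len(nrow(e))) {
      cat(sprintf("    %-22s P=%.3f R=%.3f F1=%.3f\n",
                  e$layer[i], e$precision[i], e$recall[i], e$f1[i]))
    }
  }
  invisible(x)
}

set_metrics <- function(pred, gold) {
  tp <- length(intersect(pred, gold))
  fp <- length(setdiff(pred, gold))
  fn <- length(setdiff(gold, pred))
  p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  r <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
}

#' Score pipeline output against gold annotations
#'
#' Layers: `mentions` (span + kind), `normalizations` (span + kind +
#' assigned id), and each relation type (doc-level (taxon, object) pairs).
#' Empty layers score as vacuously perfect precision.
#'
#' @param mentions Combined mention tibble (pipeline output).
#' @param relations Relation tibble (pipeline output).
#' @param gold Gold corpus.
#' @return Tibble with one row per layer: `layer`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
evaluate_extraction <- function(mentions, relations, gold) {
  mkey <- function(m) paste(m$doc_id, m$start, m$end, m$kind)
  nkey <- function(m) paste(m$doc_id, m$start, m$end, m$kind, m$id)
  rkey <- function(r) paste(r$doc_id, r$taxid, r$concept_id)
  out <- list(
    dplyr::mutate(set_metrics(unique(mkey(mentions)), unique(mkey(gold$mentions))),
                  layer = "mentions", .before = 1),
    dplyr::mutate(set_metrics(unique(nkey(mentions)), unique(nkey(gold$mentions))),
                  layer = "normalizations", .before = 1))
  for (type in c("lives_in", "exhibits", "studied_for")) {
    pr <- relations[relations$type == type, ]
    gr <- gold$relations[gold$relations$type == type, ]
    out[[length(out) + 1L]] <- dplyr::mutate(
      set_metrics(unique(rkey(pr)), unique(rkey(gr))),
      layer = paste0("relations_", type), .before = 1)
  }
  dplyr::bind_rows(out)
}
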