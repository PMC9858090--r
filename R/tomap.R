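#' Build the head index over ontology labels
#'
#' First stage of head-anchored term-to-concept mapping: every label and
#' synonym of every concept in the requested branches is indexed under the
#' comparison key of its own syntactic head ([head_word()]).
#'
#' @param ont An ontology.
#' @param branches Branch names to index (default habitat + phenotype).
#' @return An `hm_head_index`: label tibble (`head_key`, `concept_id`,
#'   `label`, `label_tokens`, `n_tokens`, `branch`) plus a lookup table.
#' @export
build_head_index <- function(ont, branches = c("habitat", "phenotype")) {
  co <- ont$concepts[ont$concepts$branch %in% branches, ]
  rows <- list()
  for (i in seq_len(nrow(co))) {
    for (lab in c(co$label[i], co$synonyms[[i]])) {
      toks <- tokenize(lab)
      if (!nrow(toks)) next
      cls <- classify_token(toks$norm)
      hk <- norm_word(toks$token[head_position(cls)])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        head_key = hk, concept_id = co$id[i], label = lab,
        label_tokens = list(unique(norm_word(toks$token))),
        n_tokens = nrow(toks), branch = co$branch[i])
    }
  }
  labels <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(head_key = character(), concept_id = character(),
                   label = character(), label_tokens = list(),
                   n_tokens = integer(), branch = character())
  structure(list(labels = labels,
                 by_head = split(seq_len(nrow(labels)), labels$head_key)),
            class = "hm_head_index")
}

#' @export
print.hm_head_index <- function(x, ...) {
  cat("<hm_head_index> ", nrow(x$labels), " labels under ",
      length(x$by_head), " head keys\n", sep = "")
  invisible(x)
}

#' Jaccard index of two word sets
#'
#' `|intersection| / |union|` over word-comparison keys ([norm_word()]
#' form: case-folded, plural-s stripped).
#'
#' @param term_tokens,label_tokens Character vectors of words.
#' @return Score in (0, 1]; 1 iff the sets are equal.
#' @export
jaccard <- function(term_tokens, label_tokens) {
  a <- unique(norm_word(term_tokens))
  b <- unique(norm_word(label_tokens))
  if (!length(a) || !length(b)) stop("jaccard over an empty word set", call. = FALSE)
  length(intersect(a, b)) / length(union(a, b))
}

#' Map one candidate term to an ontology concept
#'
#' Head-anchored concept mapping: candidate concepts are those with a label
#' or synonym sharing the term's syntactic head; each candidate is scored by
#' the Jaccard index of the word sets (a concept scores as its best label),
#' and the highest-scoring concept wins. A term whose head matches no label
#' head is ignored (`NULL`). Ties break toward the candidate with fewer
#' label tokens (the more specific fit), then the smallest concept id.
#'
#' @param term One row of [extract_candidate_terms()] (or a list with
#'   `tokens` and `head_key`).
#' @param idx An [build_head_index()] index.
#' @return `NULL`, or a list with `concept_id`, `score`, `matched_label`,
#'   `branch`.
#' @export
tomap_normalize <- function(term, idx) {
  if (is.data.frame(term)) term <- as.list(term[1, ])
  tokens <- unlist(term$tokens)
  rows <- idx$by_head[[term$head_key]]
  if (is.null(rows)) return(NULL)
  cand <- idx$labels[rows, ]
  scores <- vapply(cand$label_tokens, function(lt) jaccard(tokens, lt), double(1))
  ord <- order(-scores, cand$n_tokens, cand$concept_id)
  best <- ord[[1]]
  list(concept_id = cand$concept_id[[best]], score = scores[[best]],
       matched_label = cand$label[[best]], branch = cand$branch[[best]])
}

#' Normalize all candidate terms of a document set
#'
#' Applies [tomap_normalize()] to every candidate term and resolves
#' same-branch overlaps (sub-terms compete with their enclosing term): the
#' higher score wins, then the longer span, then the leftmost start, then
#' the smaller concept id.
#'
#' @param terms Candidate-term tibble.
#' @param idx Head index.
#' @param resolve_overlaps Drop lower-priority overlapping entities
#'   (default `TRUE`).
#' @return Normalized-entity tibble: `doc_id`, `start`, `end`, `surface`,
#'   `kind` (branch of the winning concept), `id`, `score`,
#'   `matched_label`, `sid`.
#' @export
normalize_terms <- function(terms, idx, resolve_overlaps = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(terms))) {
    r <- tomap_normalize(terms[i, ], idx)
    if (is.null(r)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      doc_id = terms$doc_id[i], start = terms$start[i], end = terms$end[i],
      surface = terms$surface[i], kind = r$branch, id = r$concept_id,
      score = r$score, matched_label = r$matched_label, sid = terms$sid[i])
  }
  if (!length(rows)) return(use_empty())
  ents <- dplyr::bind_rows(rows)
  if (resolve_overlaps) ents <- drop_overlapping(ents)
  dplyr::arrange(ents, .data$doc_id, .data$start, .data$end)
}

# same-branch overlap resolution: score desc, span length desc, start asc,
# concept id asc
drop_overlapping <- function(ents) {
  ord <- order(-ents$score, -(ents$end - ents$start), ents$start, ents$id)
  keep <- logical(nrow(ents))
  taken <- ents[0, ]
  for (i in ord) {
    clash <- taken$doc_id == ents$doc_id[i] & taken$kind == ents$kind[i] &
      taken$start < ents$end[i] & ents$start[i] < taken$end
    if (!any(clash)) {
      keep[i] <- TRUE
      taken <- dplyr::bind_rows(taken, ents[i, ])
    }
  }
  ents[keep, ]
}

#' Apply declarative post-normalization heuristics
#'
#' Hand-designed rules for recurring ambiguities, applied in file order.
#' Each rule has `field` (`"surface"` or `"sentence"`), `pattern` (regex,
#' case-insensitive), `action` (`"drop"` or `"remap"`), and for remaps a
#' `target` concept id.
#'
#' @param entities Normalized-entity tibble.
#' @param rules Rule tibble/data frame, or path to a YAML list of rules.
#' @param docs Document tibble (needed for `field = "sentence"` rules).
#' @param ont Ontology (target validation for remaps).
#' @return Filtered/remapped copy of `entities`; identity for empty rules.
#' @export
apply_heuristics <- function(entities, rules, docs = NULL, ont = NULL) {
  if (is.character(rules)) {
    rules <- dplyr::bind_rows(lapply(yaml::read_yaml(rules), tibble::as_tibble))
  }
  if (is.null(rules) || !nrow(rules)) return(entities)
  rules <- tibble::as_tibble(rules)
  if (!"target" %in% names(rules)) rules$target <- NA_character_
  if (!is.null(ont)) {
    bad <- setdiff(stats::na.omit(rules$target[rules$action == "remap"]),
                   ont$concepts$id)
    if (length(bad)) stop("heuristic rule remaps to unknown concept id(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  for (r in seq_len(nrow(rules))) {
    field <- rules$field[r]
    hit <- if (field == "surface") {
      grepl(rules$pattern[r], entities$surface, ignore.case = TRUE)
    } else {
      vapply(seq_len(nrow(entities)), function(i) {
        txt <- docs$text[docs$doc_id == entities$doc_id[i]][1]
        sents <- split_sentences(txt)
        s <- entities$sid[i]
        grepl(rules$pattern[r], slice(txt, sents$start[s], sents$end[s]),
              ignore.case = TRUE)
      }, logical(1))
    }
    if (rules$action[r] == "drop") {
      entities <- entities[!hit, ]
    } else if (rules$action[r] == "remap") {
      entities$id[hit] <- rules$target[r]
      if (!is.null(ont)) {
        entities$kind[hit] <- ont$concepts$branch[match(rules$target[r],
                                                        ont$concepts$id)]
      }
    }
  }
  entities
}
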