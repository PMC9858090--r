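#' Default trigger lexicon
#'
#' Trigger expressions whose presence in a sentence licenses relation
#' extraction between the co-occurring entities. "isolated from" is the
#' canonical lives_in trigger; the exhibits copular rule (is/are/was/were
#' plus a phenotype term in the sentence) is handled by
#' [detect_triggers()] itself.
#'
#' @return Named list of character vectors, one per relation type.
#' @export
default_triggers <- function() {
  list(
    lives_in = c("isolated from", "found in", "detected in", "present in",
                 "recovered from", "inhabit", "inhabits", "inhabiting"),
    exhibits = c("exhibit", "exhibits", "exhibited", "show", "shows",
                 "showed"),
    studied_for = c("used for", "used in", "used as", "application",
                    "applications", "capable of")
  )
}

#' Read a trigger lexicon / relation settings YAML
#'
#' @param path YAML file with keys `triggers` (type -> expressions) and
#'   optionally `anaphora_window`.
#' @return List with `triggers` and `anaphora_window`.
#' @export
read_relation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(triggers = lapply(cfg$triggers, unlist),
       anaphora_window = cfg$anaphora_window %||% 2L)
}

COPULAR <- c("is", "are", "was", "were")

#' Detect relation triggers in a sentence
#'
#' Case-insensitive multi-word matching at token boundaries; every relation
#' type with a firing trigger is returned. The exhibits type additionally
#' fires on a copular verb when the sentence contains a phenotype entity,
#' and when a phenotype term modifies a culture/strain noun phrase
#' (adjectival-modifier rule).
#'
#' @param sentence Sentence text.
#' @param lex Trigger lexicon ([default_triggers()] shape).
#' @param has_phenotype Does the sentence contain a phenotype entity?
#' @param offset 0-based offset of the sentence in its document.
#' @return Tibble `type`, `start`, `end`, `trigger`.
#' @export
detect_triggers <- function(sentence, lex = default_triggers(),
                            has_phenotype = FALSE, offset = 0L) {
  toks <- tokenize(sentence, offset = offset)
  out <- list()
  for (type in names(lex)) {
    for (trig in lex[[type]]) {
      tt <- tokenize(trig)$norm
      k <- length(tt)
      if (!k || nrow(toks) < k) next
      for (i in seq_len(nrow(toks) - k + 1L)) {
        if (all(toks$norm[i:(i + k - 1L)] == tt)) {
          out[[length(out) + 1L]] <- tibble::tibble(
            type = type, start = toks$start[i], end = toks$end[i + k - 1L],
            trigger = paste(toks$token[i:(i + k - 1L)], collapse = " "))
        }
      }
    }
  }
  if (has_phenotype) {
    cop <- which(toks$norm %in% COPULAR)
    if (length(cop)) {
      i <- cop[[1]]
      out[[length(out) + 1L]] <- tibble::tibble(
        type = "exhibits", start = toks$start[i], end = toks$end[i],
        trigger = toks$token[i])
    }
    np <- which(toks$norm %in% c("culture", "cultures", "strain", "strains",
                                 "isolate", "isolates"))
    if (length(np)) {
      i <- np[[1]]
      out[[length(out) + 1L]] <- tibble::tibble(
        type = "exhibits", start = toks$start[i], end = toks$end[i],
        trigger = toks$token[i])
    }
  }
  if (!length(out)) {
    return(tibble::tibble(type = character(), start = integer(),
                          end = integer(), trigger = character()))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

PRONOUN_ANAPHORS <- c(it = "singular", they = "plural")
SORTAL_NOUNS <- c(
  bacterium = "singular", bacteria = "plural", strain = "singular",
  strains = "plural", species = "singular", organism = "singular",
  organisms = "plural", microorganism = "singular",
  microorganisms = "plural", microbe = "singular", microbes = "plural",
  yeast = "singular", yeasts = "plural", fungus = "singular",
  fungi = "plural", isolate = "singular", isolates = "plural")
DEMONSTRATIVES <- c("this", "these", "that", "those", "the")

#' Resolve microorganism anaphora
#'
#' Links pronouns ("it", "they") and sortal phrases ("this bacterium") back
#' to the nearest preceding taxon mention within a sentence window. A
#' plural anaphor gathers every taxon of the nearest preceding sentence that
#' contains taxa; a singular anaphor takes the nearest (rightmost) single
#' mention. Unresolvable anaphors are dropped.
#'
#' @param docs Document tibble.
#' @param taxon_mentions Taxon mention tibble.
#' @param window Number of preceding sentences searched (default 2).
#' @return Tibble `doc_id`, `anaphor_start`, `anaphor_end`, `surface`,
#'   `kind` (`pronoun`/`sortal`), `sid`, `taxid` (one row per antecedent).
#' @export
resolve_anaphora <- function(docs, taxon_mentions, window = 2L) {
  out <- list()
  for (d in seq_len(nrow(docs))) {
    text <- docs$text[d]
    ment <- taxon_mentions[taxon_mentions$doc_id == docs$doc_id[d], ]
    sents <- split_sentences(text)
    for (s in seq_len(nrow(sents))) {
      toks <- tokenize(slice(text, sents$start[s], sents$end[s]),
                       offset = sents$start[s])
      cands <- list()
      pron <- which(toks$norm %in% names(PRONOUN_ANAPHORS))
      for (i in pron) {
        cands[[length(cands) + 1L]] <- list(
          i = i, j = i, kind = "pronoun",
          number = PRONOUN_ANAPHORS[[toks$norm[i]]])
      }
      if (nrow(toks) >= 2) {
        for (i in seq_len(nrow(toks) - 1L)) {
          if (toks$norm[i] %in% DEMONSTRATIVES &&
              toks$norm[i + 1L] %in% names(SORTAL_NOUNS)) {
            cands[[length(cands) + 1L]] <- list(
              i = i, j = i + 1L, kind = "sortal",
              number = SORTAL_NOUNS[[toks$norm[i + 1L]]])
          }
        }
      }
      for (cd in cands) {
        a_start <- toks$start[cd$i]; a_end <- toks$end[cd$j]
        prior <- ment[ment$sid >= s - window & ment$sid <= s &
                        ment$end <= a_start, ]
        if (!nrow(prior)) next
        ante <- if (cd$number == "plural") {
          last_sid <- max(prior$sid)
          unique(prior$id[prior$sid == last_sid])
        } else {
          prior$id[which.max(prior$end)]
        }
        out[[length(out) + 1L]] <- tibble::tibble(
          doc_id = docs$doc_id[d], anaphor_start = a_start,
          anaphor_end = a_end,
          surface = slice(text, a_start, a_end),
          kind = cd$kind, sid = s, taxid = ante)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(doc_id = character(), anaphor_start = integer(),
                          anaphor_end = integer(), surface = character(),
                          kind = character(), sid = integer(),
                          taxid = character()))
  }
  dplyr::bind_rows(out)
}

RELATION_OBJECT_BRANCH <- c(lives_in = "habitat", exhibits = "phenotype",
                            studied_for = "use")

#' Extract relations from a document set
#'
#' For every sentence where a trigger of type T fires, emits one relation of
#' type T for each pair of (taxon in scope, object entity of the branch
#' matching T) in the sentence — a cross product with no syntactic
#' attachment. Taxa in scope are the sentence's taxon mentions plus taxa
#' bridged into it by anaphora.
#'
#' @param docs Document tibble.
#' @param taxon_mentions Taxon mention tibble.
#' @param entities Normalized habitat/phenotype/use entity tibble.
#' @param links Anaphora links from [resolve_anaphora()] (optional).
#' @param lex Trigger lexicon.
#' @return Relation tibble: `doc_id`, `type`, `taxid`, `concept_id`,
#'   `sentence_start`, `sentence_end`, `trigger`, `source`.
#' @export
extract_relations <- function(docs, taxon_mentions, entities, links = NULL,
                              lex = default_triggers()) {
  out <- list()
  for (d in seq_len(nrow(docs))) {
    text <- docs$text[d]
    doc_id <- docs$doc_id[d]
    src <- if ("source" %in% names(docs)) docs$source[d] else "text"
    ment <- taxon_mentions[taxon_mentions$doc_id == doc_id, ]
    ents <- entities[entities$doc_id == doc_id, ]
    lk <- if (is.null(links)) NULL else links[links$doc_id == doc_id, ]
    sents <- split_sentences(text)
    for (s in seq_len(nrow(sents))) {
      sent_ents <- ents[ents$sid == s, ]
      trig <- detect_triggers(slice(text, sents$start[s], sents$end[s]), lex,
                              has_phenotype = any(sent_ents$kind == "phenotype"),
                              offset = sents$start[s])
      if (!nrow(trig)) next
      taxa <- unique(c(ment$id[ment$sid == s],
                       if (!is.null(lk)) lk$taxid[lk$sid == s]))
      if (!length(taxa)) next
      for (type in unique(trig$type)) {
        objs <- sent_ents[sent_ents$kind == RELATION_OBJECT_BRANCH[[type]], ]
        if (!nrow(objs)) next
        tr <- trig[trig$type == type, ][1, ]
        grid <- tidyr::expand_grid(taxid = sort(taxa),
                                   concept_id = sort(unique(objs$id)))
        out[[length(out) + 1L]] <- tibble::tibble(
          doc_id = doc_id, type = type, taxid = grid$taxid,
          concept_id = grid$concept_id,
          sentence_start = sents$start[s], sentence_end = sents$end[s],
          trigger = tr$trigger, source = src)
      }
    }
  }
  if (!length(out)) return(empty_relations())
  dplyr::bind_rows(out)
}

empty_relations <- function() {
  tibble::tibble(doc_id = character(), type = character(), taxid = character(),
                 concept_id = character(), sentence_start = integer(),
                 sentence_end = integer(), trigger = character(),
                 source = character())
}
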