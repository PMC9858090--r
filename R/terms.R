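#' Extract candidate noun/adjectival terms
#'
#' A self-contained chunker standing in for a full term extractor: maximal
#' runs of adjectives and nouns (determiners excluded, internal hyphens
#' kept), one optional "of" attachment joining two adjacent chunks, with the
#' syntactic head at the rightmost noun before the "of". For every maximal
#' chunk the suffix sub-chunks (which share its head) are also emitted, and
#' single adjectives — including the components of hyphenated compounds —
#' are emitted as their own candidates so that adjectival phenotype terms
#' ("mesophilic") surface.
#'
#' @param docs Document tibble.
#' @param exclude Optional mention tibble; candidate terms overlapping these
#'   spans (typically taxon mentions) are dropped.
#' @return Tibble of candidate terms: `doc_id`, `start`, `end`, `surface`,
#'   `tokens` (list), `head_index` (1-based into `tokens`), `head_key`,
#'   `sid`.
#' @export
extract_candidate_terms <- function(docs, exclude = NULL) {
  out <- list()
  for (d in seq_len(nrow(docs))) {
    text <- docs$text[d]
    sents <- split_sentences(text)
    for (s in seq_len(nrow(sents))) {
      toks <- tokenize(slice(text, sents$start[s], sents$end[s]),
                       offset = sents$start[s])
      if (!nrow(toks)) next
      toks$class <- classify_token(toks$norm)
      chunks <- chunk_runs(toks$class)
      emitted <- list()
      ci <- 1L
      while (ci <= length(chunks)) {
        ch <- chunks[[ci]]
        # of-attachment: chunk, "of" token, chunk — contiguous
        joined <- FALSE
        if (ci < length(chunks)) {
          nxt <- chunks[[ci + 1L]]
          gap <- min(nxt) - max(ch)
          if (gap == 2L && toks$class[max(ch) + 1L] == "of") {
            span <- seq(min(ch), max(nxt))
            emitted <- c(emitted, list(list(idx = span,
                                            head = head_position(toks$class[span]))))
            joined <- TRUE
          }
        }
        if (!joined) {
          emitted <- c(emitted, list(list(idx = ch,
                                          head = head_position(toks$class[ch]))))
        }
        # suffix sub-chunks of the base chunk share its head
        if (length(ch) > 1L) {
          for (k in seq(2L, length(ch))) {
            sub <- ch[k:length(ch)]
            emitted <- c(emitted, list(list(idx = sub,
                                            head = head_position(toks$class[sub]))))
          }
        }
        if (joined) {
          nxt <- chunks[[ci + 1L]]
          for (k in seq_len(length(nxt))) {
            sub <- nxt[k:length(nxt)]
            if (length(sub) == length(nxt) || length(sub) >= 1L) {
              emitted <- c(emitted, list(list(idx = sub,
                                              head = head_position(toks$class[sub]))))
            }
          }
          ci <- ci + 2L
        } else {
          ci <- ci + 1L
        }
      }
      rows <- lapply(emitted, function(e) {
        idx <- e$idx
        tibble::tibble(
          doc_id = docs$doc_id[d],
          start = toks$start[idx[1]], end = toks$end[idx[length(idx)]],
          surface = slice(text, toks$start[idx[1]], toks$end[idx[length(idx)]]),
          tokens = list(toks$token[idx]), head_index = e$head,
          head_key = norm_word(toks$token[idx[e$head]]), sid = s)
      })
      # hyphenated adjective components as standalone candidates
      hyph <- which(grepl("-", toks$token) & toks$class %in% c("adj", "noun"))
      for (h in hyph) {
        parts <- strsplit(toks$token[h], "-", fixed = TRUE)[[1]]
        off <- toks$start[h]
        for (p in parts) {
          if (grepl("^[[:alpha:]]+$", p)) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              doc_id = docs$doc_id[d], start = off, end = off + nchar(p),
              surface = p, tokens = list(p), head_index = 1L,
              head_key = norm_word(p), sid = s)
          }
          off <- off + nchar(p) + 1L
        }
      }
      out <- c(out, rows)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(doc_id = character(), start = integer(),
                          end = integer(), surface = character(),
                          tokens = list(), head_index = integer(),
                          head_key = character(), sid = integer()))
  }
  terms <- dplyr::distinct(dplyr::bind_rows(out),
                           .data$doc_id, .data$start, .data$end,
                           .keep_all = TRUE)
  if (!is.null(exclude) && nrow(exclude)) {
    keep <- !purrr::map_lgl(seq_len(nrow(terms)), function(i) {
      any(exclude$doc_id == terms$doc_id[i] &
            exclude$start < terms$end[i] & terms$start[i] < exclude$end)
    })
    terms <- terms[keep, ]
  }
  dplyr::arrange(terms, .data$doc_id, .data$start, .data$end)
}

# indices of maximal adj/noun runs
chunk_runs <- function(classes) {
  in_chunk <- classes %in% c("adj", "noun")
  if (!any(in_chunk)) return(list())
  r <- rle(in_chunk)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map2(starts[r$values], ends[r$values], seq)
}
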