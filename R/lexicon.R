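#' Read documents from a TSV or plain-text files
#'
#' @param x Path to a 3-column TSV (`doc_id`, `source`, `text`, with header),
#'   or a character vector of plain-text file paths (one document per file,
#'   `doc_id` = file name).
#' @param source Source label used for plain-text files.
#' @return Tibble with columns `doc_id`, `source`, `text`.
#' @export
read_documents <- function(x, source = "text") {
  if (length(x) == 1 && grepl("\\.tsv$", x)) {
    df <- utils::read.delim(x, sep = "\t", stringsAsFactors = FALSE,
                            colClasses = "character")
    return(tibble::as_tibble(df[, c("doc_id", "source", "text")]))
  }
  tibble::tibble(
    doc_id = basename(x),
    source = source,
    text = vapply(x, function(p) paste(readLines(p, warn = FALSE),
                                       collapse = " "), character(1))
  )
}

#' Build the taxon lexicon from a taxonomy
#'
#' Indexes every name of every node under a token-normalized key and adds
#' genus-initial variants for multinomial scientific names: "Bacillus
#' subtilis" also matches as "B. subtilis" and "B subtilis" (both normalize
#' to the same key). Only the genus token is abbreviated, so trinomials keep
#' their epithets ("L. lactis cremoris").
#'
#' @param tax A validated taxonomy.
#' @return An `hm_taxon_lexicon`: entry tibble plus a key lookup table.
#' @export
build_taxon_lexicon <- function(tax) {
  nm <- tax$names
  rows <- vector("list", nrow(nm))
  for (i in seq_len(nrow(nm))) {
    toks <- tokenize(nm$name[i])
    if (!nrow(toks)) next
    key <- paste(toks$norm, collapse = " ")
    first <- substr(nm$name[i], 1, 1)
    case_sensitive <- nm$name_class[i] == "scientific" && grepl("^[A-Z]", first)
    ent <- tibble::tibble(
      key = key, n_tokens = nrow(toks), taxid = nm$taxid[i],
      name = nm$name[i], name_class = nm$name_class[i],
      is_variant = FALSE, first_char = first, case_sensitive = case_sensitive)
    # genus-initial variants for capitalized multinomial scientific names
    if (nm$name_class[i] == "scientific" && nrow(toks) >= 2 &&
        grepl("^[A-Z][a-z]+$", toks$token[1])) {
      vkey <- paste(c(substr(toks$norm[1], 1, 1), toks$norm[-1]), collapse = " ")
      ent <- dplyr::bind_rows(ent, tibble::tibble(
        key = vkey, n_tokens = nrow(toks),
        taxid = nm$taxid[i],
        name = paste(c(paste0(substr(toks$token[1], 1, 1), "."),
                       toks$token[-1]), collapse = " "),
        name_class = "scientific", is_variant = TRUE,
        first_char = first, case_sensitive = TRUE))
    }
    rows[[i]] <- ent
  }
  entries <- dplyr::distinct(dplyr::bind_rows(rows),
                             key, taxid, name_class, is_variant, .keep_all = TRUE)
  structure(list(entries = entries,
                 by_key = split(seq_len(nrow(entries)), entries$key),
                 max_len = max(entries$n_tokens)),
            class = "hm_taxon_lexicon")
}

#' @export
print.hm_taxon_lexicon <- function(x, ...) {
  cat("<hm_taxon_lexicon> ", nrow(x$entries), " entries (",
      sum(x$entries$is_variant), " generated variants)\n", sep = "")
  invisible(x)
}

NAME_CLASS_PRIORITY <- c(scientific = 1, synonym = 2, vernacular = 3, catalog = 4)

# resolve one key hit: case filter, then name-class priority, then unique
# taxid; NA when ambiguous
resolve_key_hit <- function(entries, rows, surface) {
  hits <- entries[rows, ]
  ok <- !hits$case_sensitive | substr(surface, 1, 1) == hits$first_char
  hits <- hits[ok, ]
  if (!nrow(hits)) return(NULL)
  best <- min(NAME_CLASS_PRIORITY[hits$name_class])
  hits <- hits[NAME_CLASS_PRIORITY[hits$name_class] == best, ]
  if (length(unique(hits$taxid)) > 1) {
    return(list(ambiguous = TRUE))
  }
  list(ambiguous = FALSE, taxid = hits$taxid[[1]], name = hits$name[[1]],
       name_class = hits$name_class[[1]])
}

#' Match taxon mentions in documents
#'
#' Longest-match-first scan over token boundaries within each sentence.
#' Recognition and normalization are combined: each mention carries the
#' taxid it resolved to. Keys resolving to several taxa are disambiguated by
#' name class (scientific over synonym over vernacular over catalog);
#' remaining ties are dropped.
#'
#' @param docs Document tibble ([read_documents()] shape).
#' @param lex An [build_taxon_lexicon()] lexicon.
#' @return Tibble of mentions: `doc_id`, `start`, `end`, `surface`,
#'   `kind = "taxon"`, `id` (taxid), `matched_label`, `sid` (sentence index).
#' @export
match_taxa <- function(docs, lex) {
  out <- list()
  for (d in seq_len(nrow(docs))) {
    text <- docs$text[d]
    sents <- split_sentences(text)
    for (s in seq_len(nrow(sents))) {
      toks <- tokenize(slice(text, sents$start[s], sents$end[s]),
                       offset = sents$start[s])
      n <- nrow(toks)
      i <- 1L
      while (i <= n) {
        matched <- FALSE
        for (len in seq(min(lex$max_len, n - i + 1L), 1L)) {
          key <- paste(toks$norm[i:(i + len - 1L)], collapse = " ")
          rows <- lex$by_key[[key]]
          if (is.null(rows)) next
          sp_start <- toks$start[i]; sp_end <- toks$end[i + len - 1L]
          surface <- slice(text, sp_start, sp_end)
          r <- resolve_key_hit(lex$entries, rows, surface)
          if (is.null(r)) next
          if (!r$ambiguous) {
            out[[length(out) + 1L]] <- tibble::tibble(
              doc_id = docs$doc_id[d], start = sp_start, end = sp_end,
              surface = surface, kind = "taxon", id = r$taxid,
              matched_label = r$name, sid = s)
          }
          i <- i + len
          matched <- TRUE
          break
        }
        if (!matched) i <- i + 1L
      }
    }
  }
  bind_mentions(out)
}

bind_mentions <- function(out) {
  if (!length(out)) {
    return(tibble::tibble(doc_id = character(), start = integer(),
                          end = integer(), surface = character(),
                          kind = character(), id = character(),
                          matched_label = character(), sid = integer()))
  }
  dplyr::bind_rows(out)
}

# strain designator patterns: "DSM 20174" (code + number) or a single
# letters-and-digits token ("XYZ-99", "DSM20174")
is_desig_code <- function(tok) grepl("^[A-Za-z]{2,10}$", tok) & grepl("[A-Z]", tok)
is_desig_num <- function(tok) grepl("^\\d[\\w.-]*$", tok, perl = TRUE)
is_desig_single <- function(tok) grepl("^[A-Za-z][\\w.-]*\\d[\\w.-]*$", tok, perl = TRUE) &
  grepl("[A-Za-z]", tok)

# designator token run starting at index i; returns last index or 0
desig_span <- function(toks, i) {
  n <- nrow(toks)
  if (i > n) return(0L)
  if (is_desig_single(toks$token[i])) return(i)
  if (i < n && is_desig_code(toks$token[i]) && is_desig_num(toks$token[i + 1L])) {
    return(i + 1L)
  }
  0L
}

#' Attach strain designators to species mentions
#'
#' Recognizes strain names next to recognized taxon mentions: the pattern
#' `<species mention> [strain] <designator>` (and `strain <designator>` with
#' the species earlier in the sentence). Designators are resolved against
#' catalog names of strain nodes below the species via [strain_key()];
#' unresolvable designators keep the mention linked to the species node.
#'
#' @param docs Document tibble.
#' @param mentions Taxon mentions from [match_taxa()].
#' @param tax The taxonomy the lexicon was built from.
#' @return Updated mention tibble (extended spans replace their species
#'   mention).
#' @export
recognize_strain_mentions <- function(docs, mentions, tax) {
  if (!nrow(mentions)) return(mentions)
  rank <- taxon_rank(tax, mentions$id)
  strain_names <- tax$names[tax$names$taxid %in%
                              tax$nodes$taxid[tax$nodes$rank == "strain"], ]
  strain_names$key <- strain_key(strain_names$name)
  drop <- logical(nrow(mentions))
  out <- list()
  for (d in seq_len(nrow(docs))) {
    text <- docs$text[d]
    midx <- which(mentions$doc_id == docs$doc_id[d])
    if (!length(midx)) next
    sents <- split_sentences(text)
    for (s in seq_len(nrow(sents))) {
      toks <- tokenize(slice(text, sents$start[s], sents$end[s]),
                       offset = sents$start[s])
      sidx <- midx[mentions$sid[midx] == s & rank[midx] %in%
                     c("species", "subspecies")]
      consumed <- rep(FALSE, nrow(toks))
      for (mi in sidx) {
        after <- which(toks$start >= mentions$end[mi])
        if (!length(after)) next
        i <- min(after)
        if (i <= nrow(toks) && norm_token(toks$token[i]) %in% c("strain", "str")) {
          i <- i + 1L
        }
        j <- desig_span(toks, i)
        if (!j) next
        desig <- slice(text, toks$start[i], toks$end[j])
        hit <- resolve_designator(desig, mentions$id[mi], strain_names, tax)
        out[[length(out) + 1L]] <- tibble::tibble(
          doc_id = docs$doc_id[d], start = mentions$start[mi],
          end = toks$end[j],
          surface = slice(text, mentions$start[mi], toks$end[j]),
          kind = "taxon", id = hit %||% mentions$id[mi],
          matched_label = desig, sid = s)
        drop[mi] <- TRUE
        consumed[i:j] <- TRUE
      }
      # "strain <designator>" with the species mentioned earlier in the
      # sentence but not adjacent
      st <- which(toks$norm == "strain" | toks$norm == "str")
      for (i in st) {
        j <- desig_span(toks, i + 1L)
        if (!j || any(consumed[(i + 1L):j])) next
        prior <- midx[mentions$sid[midx] == s &
                        mentions$end[midx] <= toks$start[i] &
                        rank[midx] %in% c("species", "subspecies")]
        if (!length(prior)) next
        sp <- prior[which.max(mentions$end[prior])]
        desig <- slice(text, toks$start[i + 1L], toks$end[j])
        hit <- resolve_designator(desig, mentions$id[sp], strain_names, tax)
        out[[length(out) + 1L]] <- tibble::tibble(
          doc_id = docs$doc_id[d], start = toks$start[i + 1L],
          end = toks$end[j], surface = desig, kind = "taxon",
          id = hit %||% mentions$id[sp], matched_label = desig, sid = s)
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(mentions[!drop, ], bind_mentions(out)),
                 .data$doc_id, .data$start)
}

# strain node below `species` whose catalog/any name shares the designator's
# comparison key; NULL when unresolved
resolve_designator <- function(desig, species, strain_names, tax) {
  keys <- unique(strain_key(strain_name_variants(desig)))
  cand <- strain_names[strain_names$key %in% keys, ]
  if (!nrow(cand)) return(NULL)
  below <- c(species, descendants(tax, species))
  cand <- cand[cand$taxid %in% below, ]
  if (!nrow(cand)) return(NULL)
  sort(unique(cand$taxid))[[1]]
}

#' Match use mentions against the use branch
#'
#' Exact (case-insensitive, whitespace-normalized) matches of use-branch
#' labels and synonyms only; no fuzzy mapping. Longest match wins on
#' overlap.
#'
#' @param docs Document tibble.
#' @param ont Ontology with a use branch.
#' @return Mention tibble with `kind = "use"`, `id` (concept), `score = 1`.
#' @export
match_uses <- function(docs, ont) {
  use <- ont$concepts[ont$concepts$branch == "use", ]
  lexicon <- list()
  for (i in seq_len(nrow(use))) {
    for (lab in c(use$label[i], use$synonyms[[i]])) {
      toks <- tokenize(lab)
      if (!nrow(toks)) next
      key <- paste(toks$norm, collapse = " ")
      lexicon[[length(lexicon) + 1L]] <- tibble::tibble(
        key = key, n_tokens = nrow(toks), id = use$id[i], label = lab)
    }
  }
  if (!length(lexicon)) return(use_empty())
  entries <- dplyr::bind_rows(lexicon)
  entries <- entries[order(entries$id), ]
  by_key <- split(seq_len(nrow(entries)), entries$key)
  max_len <- max(entries$n_tokens)

  out <- list()
  for (d in seq_len(nrow(docs))) {
    text <- docs$text[d]
    sents <- split_sentences(text)
    for (s in seq_len(nrow(sents))) {
      toks <- tokenize(slice(text, sents$start[s], sents$end[s]),
                       offset = sents$start[s])
      n <- nrow(toks); i <- 1L
      while (i <= n) {
        matched <- FALSE
        for (len in seq(min(max_len, n - i + 1L), 1L)) {
          key <- paste(toks$norm[i:(i + len - 1L)], collapse = " ")
          rows <- by_key[[key]]
          if (is.null(rows)) next
          hit <- entries[rows[[1]], ]  # deterministic: smallest concept id
          out[[length(out) + 1L]] <- tibble::tibble(
            doc_id = docs$doc_id[d], start = toks$start[i],
            end = toks$end[i + len - 1L],
            surface = slice(text, toks$start[i], toks$end[i + len - 1L]),
            kind = "use", id = hit$id, matched_label = hit$label,
            score = 1, sid = s)
          i <- i + len; matched <- TRUE
          break
        }
        if (!matched) i <- i + 1L
      }
    }
  }
  if (!length(out)) return(use_empty())
  dplyr::bind_rows(out)
}

use_empty <- function() {
  tibble::tibble(doc_id = character(), start = integer(), end = integer(),
                 surface = character(), kind = character(), id = character(),
                 matched_label = character(), score = double(), sid = integer())
}
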