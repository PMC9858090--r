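#' @keywords internal
#' @importFrom rlang .data
#' @importFrom stats setNames
"_PACKAGE"

## Character offsets throughout the package are 0-based, half-open
## [start, end): surface == substr(text, start + 1, end).

slice <- function(text, start, end) substr(text, start + 1L, end)

# abbreviations that never terminate a sentence even before a capital/digit
SENT_ABBREV <- c("no", "ca", "cf", "vs", "fig", "figs", "al", "e.g", "i.e",
                 "approx", "etc")

#' Split text into sentence spans
#'
#' Sentences end at `.`, `?` or `!` followed by whitespace and an uppercase
#' letter or digit. An abbreviation guard keeps genus-initial abbreviations
#' ("B. subtilis") and common shorthands ("no.", "et al.") attached to their
#' sentence.
#'
#' @param text A single string.
#' @return Tibble with 0-based half-open columns `start`, `end`, one row per
#'   sentence, ordered and non-overlapping.
#' @export
split_sentences <- function(text) {
  empty <- tibble::tibble(start = integer(), end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  n <- nchar(text)
  m <- gregexpr("[.?!](?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  cuts <- integer()
  if (m[1] != -1) {
    for (pos in as.integer(m)) {
      before <- substr(text, 1, pos - 1L)
      word <- stringr::str_extract(before, "[A-Za-z.]+$")
      word <- tolower(word %||% "")
      guard <- !is.na(word) && nzchar(word) && word %in% SENT_ABBREV
      # single-capital guard applies when the next word is lowercase (genus
      # abbreviation); the terminator regex already requires a capital/digit,
      # so it only suppresses splits for shorthand in SENT_ABBREV here
      if (!guard) cuts <- c(cuts, pos)
    }
  }
  bounds <- c(0L, cuts, n)
  spans <- purrr::map(seq_len(length(bounds) - 1L), function(i) {
    s <- bounds[i]; e <- bounds[i + 1L]
    seg <- slice(text, s, e)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    c(start = s + lead, end = e - trail)
  })
  out <- tibble::as_tibble(do.call(rbind, spans))
  out[out$end > out$start, ]
}

# period-keeping token alternation: taxonomic abbreviations, genus initials,
# then general alphanumeric words with internal hyphens/apostrophes
TOKEN_RE <- "(?:ssp|subsp|spp|sp|var|str|cf)\\.|[A-Z]\\.|[[:alnum:]]+(?:['’-][[:alnum:]]+)*"

#' Tokenize a text span
#'
#' Splits on whitespace and punctuation, keeping internal hyphens
#' ("mesophilic-thermophilic") and periods of recognized abbreviations
#' ("B.", "ssp.").
#'
#' @param text String to tokenize.
#' @param offset 0-based offset of `text` within its document.
#' @return Tibble with columns `token`, `start`, `end` (0-based, half-open,
#'   document coordinates) and `norm` (comparison form).
#' @export
tokenize <- function(text, offset = 0L) {
  m <- gregexpr(TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer(), norm = character()))
  }
  start <- as.integer(m) - 1L + offset
  len <- attr(m, "match.length")
  tok <- regmatches(text, list(m))[[1]]
  tibble::tibble(token = tok, start = start, end = start + len,
                 norm = norm_token(tok))
}

# comparison form of one token: case-folded, trailing abbreviation period
# stripped
norm_token <- function(tok) tolower(sub("\\.$", "", tok))

# word-comparison key used inside Jaccard: case-folding plus plural-s
# stripping (no stemming)
norm_word <- function(tok) {
  w <- norm_token(tok)
  ifelse(nchar(w) > 3 & grepl("[^su]s$", w), sub("s$", "", w), w)
}

DETERMINERS <- c("the", "a", "an", "this", "that", "these", "those", "its",
                 "their", "our", "such", "each", "every", "all", "some",
                 "any", "no", "both", "other", "another")

CLOSED_CLASS <- c(
  "is", "are", "was", "were", "be", "been", "being", "am",
  "has", "have", "had", "having", "do", "does", "did", "done",
  "can", "could", "may", "might", "will", "would", "shall", "should", "must",
  "and", "or", "but", "nor", "so", "yet", "also", "not", "only", "very",
  "too", "then", "thus", "however", "moreover", "both", "either", "neither",
  "it", "they", "we", "he", "she", "you", "i", "them", "him", "her", "us",
  "there", "here", "what", "which", "who", "whom", "whose", "when", "where",
  "while", "because", "if", "although", "though", "than",
  "from", "in", "on", "at", "by", "with", "to", "into", "onto", "for", "as",
  "about", "against", "between", "among", "through", "during", "before",
  "after", "above", "below", "under", "over", "up", "down", "out", "off",
  "grows", "grow", "grew", "grown", "growing", "studied", "study", "studies",
  "used", "use", "uses", "using", "obtained", "described", "reported",
  "observed", "performed", "sampled", "collected", "tested", "analyzed",
  "sequenced", "identified", "characterized", "acidified", "acidify")

ADJ_SUFFIX_RE <- "(ic|ical|ous|ive|ary|al|ile|ed|ing|like|philic|phobic)$"

# token classes for the noun-phrase chunker
classify_token <- function(norm) {
  dplyr::case_when(
    norm %in% DETERMINERS ~ "det",
    norm == "of" ~ "of",
    norm %in% CLOSED_CLASS ~ "stop",
    grepl("\\d", norm) ~ "num",
    grepl(ADJ_SUFFIX_RE, norm) ~ "adj",
    grepl("-", norm) ~ "adj",
    TRUE ~ "noun"
  )
}

# rightmost noun of a token-class sequence (before any "of"), falling back
# to the last token; returns an index into the sequence
head_position <- function(classes) {
  upto <- which(classes == "of")
  upto <- if (length(upto)) min(upto) - 1L else length(classes)
  nouns <- which(classes[seq_len(upto)] == "noun")
  if (length(nouns)) max(nouns) else upto
}

#' Syntactic head of a term string
#'
#' The head is the main word of a noun phrase: the rightmost noun before any
#' "of" attachment (English compounds are right-headed), e.g. "milk" in
#' "dairy cow milk". Used to anchor term-to-concept matching.
#'
#' @param term A term string (label, synonym, or extracted phrase).
#' @return The head word's comparison key ([norm_word()] form).
#' @export
head_word <- function(term) {
  toks <- tokenize(term)
  if (!nrow(toks)) return(NA_character_)
  cls <- classify_token(toks$norm)
  norm_word(toks$token[head_position(cls)])
}
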