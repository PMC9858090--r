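#' Parse a GenBank-dialect flat file (subset)
#'
#' Reads the subset of the GenBank flat-file format needed for sequence
#' ingestion: the LOCUS line (length in bp), ACCESSION, the source feature
#' qualifiers `/organism`, `/strain`, `/isolation_source`, and feature
#' descriptors (feature keys plus `/product` and `/gene` values). A record
#' must open with LOCUS and close with `//` after ORIGIN.
#'
#' @param x File path or character vector of lines.
#' @return Tibble of sequence records: `accession`, `organism`, `strain`,
#'   `isolation_source` (NA when absent), `descriptors` (list of feature
#'   keys/product/gene strings), `length` (bp).
#' @export
parse_genbank <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) readLines(x, warn = FALSE) else
    unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- lines[!is.na(lines)]
  recs <- list()
  cur <- character()
  for (ln in lines) {
    if (trimws(ln) == "//") {
      if (length(cur)) recs[[length(recs) + 1L]] <- cur
      cur <- character()
    } else {
      cur <- c(cur, ln)
    }
  }
  if (length(cur) && any(nzchar(trimws(cur)))) {
    acc <- qualifier_value(cur, "ACCESSION") %||% "<unknown>"
    stop("record ", acc, " lacks the `//` terminator", call. = FALSE)
  }
  rows <- lapply(recs, parse_genbank_record)
  if (!length(rows)) {
    return(tibble::tibble(accession = character(), organism = character(),
                          strain = character(), isolation_source = character(),
                          descriptors = list(), length = integer()))
  }
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$accession)) {
    stop("duplicate accession(s): ",
         paste(unique(out$accession[duplicated(out$accession)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

qualifier_value <- function(lines, field) {
  hit <- grep(paste0("^", field, "\\s"), lines, value = TRUE)
  if (!length(hit)) return(NULL)
  trimws(sub(paste0("^", field, "\\s+"), "", hit[[1]]))
}

parse_genbank_record <- function(lines) {
  locus <- grep("^LOCUS\\s", lines, value = TRUE)
  acc <- qualifier_value(lines, "ACCESSION")
  if (!length(locus)) {
    stop("record ", acc %||% "<unknown>", " lacks a LOCUS line", call. = FALSE)
  }
  if (!any(grepl("^ORIGIN", lines))) {
    stop("record ", acc %||% "<unknown>", " lacks an ORIGIN section", call. = FALSE)
  }
  len <- stringr::str_match(locus[[1]], "\\s(\\d+)\\s+bp\\b")[, 2]
  if (is.na(len)) stop("record ", acc %||% "<unknown>",
                       ": LOCUS line has no `<n> bp` length", call. = FALSE)
  quals <- stringr::str_match(lines, '^\\s+/([A-Za-z_]+)="?([^"]*)"?\\s*$')
  qname <- quals[, 2]; qval <- quals[, 3]
  feat_keys <- stringr::str_match(lines, "^ {5}([A-Za-z_'-]+)\\s+\\S")[ , 2]
  descriptors <- c(stats::na.omit(feat_keys),
                   qval[!is.na(qname) & qname %in% c("product", "gene")])
  get1 <- function(nm) {
    v <- qval[!is.na(qname) & qname == nm]
    if (length(v)) v[[1]] else NA_character_
  }
  tibble::tibble(
    accession = acc %||% NA_character_,
    organism = get1("organism"),
    strain = get1("strain"),
    isolation_source = get1("isolation_source"),
    descriptors = list(unname(descriptors)),
    length = as.integer(len))
}

RRNA_16S_RE <- "16S (ribosomal RNA|rRNA)"

#' Sequence-record ingestion filter
#'
#' A record is kept iff (a) a feature descriptor names the 16S rRNA gene
#' ("16S ribosomal RNA" or "16S rRNA", case-insensitive, matched on either
#' gene or product), (b) its sequence length is at least 800 bp (inclusive
#' threshold), (c) it carries a non-empty isolation_source, and (d) its
#' organism resolves to a taxon of the selected microbial subtree.
#'
#' @param rec One record (one row of [parse_genbank()] output, or a list).
#' @param lex Taxon lexicon built from the selected microbial subtree.
#' @return `TRUE`/`FALSE`.
#' @export
filter_sequence_record <- function(rec, lex) {
  if (is.data.frame(rec)) rec <- as.list(rec[1, ])
  desc <- unlist(rec$descriptors)
  has_16s <- any(grepl(RRNA_16S_RE, desc, ignore.case = TRUE))
  long_enough <- isTRUE(rec$length >= 800L)
  has_source <- !is.na(rec$isolation_source) && nzchar(trimws(rec$isolation_source))
  in_subtree <- !is.na(resolve_taxon_text(rec$organism, lex))
  has_16s && long_enough && has_source && in_subtree
}

#' Filter a batch of sequence records
#'
#' @param recs Record tibble from [parse_genbank()].
#' @param lex Taxon lexicon of the selected microbial subtree.
#' @return Logical vector, one element per record.
#' @export
filter_sequence_records <- function(recs, lex) {
  vapply(seq_len(nrow(recs)), function(i) filter_sequence_record(recs[i, ], lex),
         logical(1))
}

#' Resolve a free-text name to a taxid
#'
#' Whole-string lexicon lookup (after tokenization), used for structured
#' fields; returns `NA` when the text is not a known taxon name or is
#' ambiguous.
#'
#' @param text Name string.
#' @param lex A taxon lexicon.
#' @return A taxid or `NA`.
#' @export
resolve_taxon_text <- function(text, lex) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NA_character_)
  toks <- tokenize(text)
  if (!nrow(toks)) return(NA_character_)
  key <- paste(toks$norm, collapse = " ")
  rows <- lex$by_key[[key]]
  if (is.null(rows)) return(NA_character_)
  r <- resolve_key_hit(lex$entries, rows, trimws(text))
  if (is.null(r) || r$ambiguous) return(NA_character_)
  r$taxid
}
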