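#' Merge duplicate relations per source
#'
#' Groups relations on (type, subject, object, source) — merging happens
#' within a source, never across sources — concatenating the evidence
#' (document/record ids) in input order.
#'
#' @param relations Relation tibble ([extract_relations()] shape).
#' @return Knowledge-record tibble: `type`, `taxid`, `concept_id`,
#'   `source`, `evidence` (list of doc ids), `count`; sorted
#'   deterministically.
#' @export
deduplicate <- function(relations) {
  if (!nrow(relations)) {
    return(tibble::tibble(type = character(), taxid = character(),
                          concept_id = character(), source = character(),
                          evidence = list(), count = integer()))
  }
  relations |>
    dplyr::group_by(.data$type, .data$taxid, .data$concept_id, .data$source) |>
    dplyr::summarise(evidence = list(.data$doc_id), .groups = "drop") |>
    dplyr::mutate(count = lengths(.data$evidence)) |>
    dplyr::arrange(.data$type, .data$taxid, .data$concept_id, .data$source)
}

#' Build the knowledge store with hierarchical-path index
#'
#' Materializes the (entity, ancestor) closure pairs of both reference
#' vocabularies, so that every record is retrievable by its specific class
#' and all more general classes.
#'
#' @param records Knowledge-record tibble ([deduplicate()] output).
#' @param ont Ontology.
#' @param tax Taxonomy.
#' @param qps Character vector of QPS taxids (optional).
#' @return An `hm_store`.
#' @export
build_store <- function(records, ont, tax, qps = character()) {
  bad_c <- setdiff(records$concept_id, ont$concepts$id)
  if (length(bad_c)) stop("record(s) reference unknown concept id(s): ",
                          paste(utils::head(bad_c, 5), collapse = ", "),
                          call. = FALSE)
  bad_t <- setdiff(records$taxid, tax$nodes$taxid)
  if (length(bad_t)) stop("record(s) reference unknown taxid(s): ",
                          paste(utils::head(bad_t, 5), collapse = ", "),
                          call. = FALSE)
  structure(list(
    records = records,
    concept_closure = concept_closure(ont),
    taxon_closure = taxon_closure(tax),
    ontology = ont, taxonomy = tax, qps = sort(unique(qps))
  ), class = "hm_store")
}

#' @export
print.hm_store <- function(x, ...) {
  cat("<hm_store> ", nrow(x$records), " records, ",
      length(unique(x$records$taxid)), " taxa, ",
      length(unique(x$records$source)), " source(s), ",
      length(x$qps), " QPS taxa\n", sep = "")
  invisible(x)
}

# (id, ancestor) pairs, self included
concept_closure <- function(ont) {
  ids <- ont$concepts$id
  dplyr::bind_rows(lapply(ids, function(i)
    tibble::tibble(id = i, ancestor = c(i, ancestors(ont, i)))))
}

taxon_closure <- function(tax) {
  ids <- tax$nodes$taxid
  dplyr::bind_rows(lapply(ids, function(i)
    tibble::tibble(id = i, ancestor = c(i, ancestors(tax, i)))))
}

#' Records retrievable at a concept (with descendant expansion)
#'
#' @param store An `hm_store`.
#' @param concept_id Concept id.
#' @return Record tibble subset whose object is the concept or any
#'   descendant.
#' @export
records_at_concept <- function(store, concept_id) {
  if (!concept_id %in% store$ontology$concepts$id) {
    stop("unknown concept id: ", concept_id, call. = FALSE)
  }
  under <- store$concept_closure$id[store$concept_closure$ancestor == concept_id]
  store$records[store$records$concept_id %in% under, ]
}

#' Records retrievable at a taxon (with descendant expansion)
#'
#' @param store An `hm_store`.
#' @param taxid Taxid.
#' @return Record tibble subset whose subject is the taxon or any
#'   descendant.
#' @export
records_at_taxon <- function(store, taxid) {
  if (!taxid %in% store$taxonomy$nodes$taxid) {
    stop("unknown taxid: ", taxid, call. = FALSE)
  }
  under <- store$taxon_closure$id[store$taxon_closure$ancestor == taxid]
  store$records[store$records$taxid %in% under, ]
}

LEAF_RECORD_TYPE <- c(habitat = "lives_in", phenotype = "exhibits",
                      use = "studied_for")

#' Evaluate a boolean query over the store
#'
#' Leaf semantics: a habitat/phenotype/use leaf selects the subject taxa
#' having a record of the corresponding relation type whose object is the
#' leaf concept or any descendant; a taxon leaf selects subjects that are
#' the leaf taxon or any descendant; a qps leaf selects subjects in the QPS
#' set; a source leaf selects subjects with any record from that source.
#' `and`/`or` nodes intersect/unite. Each result taxon carries the records
#' that justified the leaves it satisfied.
#'
#' @param q A query: nested list (`list(and = list(...))`,
#'   `list(or = list(...))`, or a leaf `list(kind =, value =)`), a query
#'   string for [parse_query()], or a YAML file path.
#' @param store An `hm_store`.
#' @return Tibble `taxid` (sorted); attribute `support` holds the
#'   justifying records per leaf.
#' @export
evaluate_query <- function(q, store) {
  if (is.character(q) && length(q) == 1) {
    q <- if (file.exists(q) && grepl("\\.ya?ml$", q)) query_from_yaml(q) else
      parse_query(q)
  }
  support <- list()
  eval_node <- function(node) {
    if (!is.null(node$kind)) {
      res <- eval_leaf(node, store)
      key <- paste0(node$kind, ":", node$value %||% "")
      support[[key]] <<- res$records
      return(res$taxa)
    }
    op <- intersect(names(node), c("and", "or"))
    if (!length(op)) stop("malformed query node", call. = FALSE)
    parts <- lapply(node[[op]], eval_node)
    if (op == "and") Reduce(intersect, parts) else Reduce(union, parts)
  }
  taxa <- sort(unique(eval_node(q)))
  out <- tibble::tibble(taxid = taxa)
  attr(out, "support") <- support
  out
}

eval_leaf <- function(leaf, store) {
  kind <- leaf$kind
  rec <- store$records
  if (kind %in% names(LEAF_RECORD_TYPE)) {
    sub <- records_at_concept(store, leaf$value)
    sub <- sub[sub$type == LEAF_RECORD_TYPE[[kind]], ]
    return(list(taxa = unique(sub$taxid), records = sub))
  }
  if (kind == "taxon") {
    sub <- records_at_taxon(store, leaf$value)
    return(list(taxa = unique(sub$taxid), records = sub))
  }
  if (kind == "qps") {
    sub <- rec[rec$taxid %in% store$qps, ]
    return(list(taxa = intersect(unique(rec$taxid), store$qps), records = sub))
  }
  if (kind == "source") {
    sub <- rec[rec$source == leaf$value, ]
    return(list(taxa = unique(sub$taxid), records = sub))
  }
  stop("unknown query leaf kind: ", kind, call. = FALSE)
}

#' Parse the text query syntax
#'
#' Grammar: `kind:value` leaves (kinds taxon, habitat, phenotype, use,
#' source; bare `qps` for the safety flag) combined with `and` / `or` and
#' parentheses; `and` binds tighter than `or`.
#'
#' @param s Query string, e.g.
#'   `"(phenotype:P1 or phenotype:P2) and habitat:H3 and qps"`.
#' @return A query tree for [evaluate_query()].
#' @export
parse_query <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()[:space:]]+", s))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_leaf <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of query", call. = FALSE)
    if (t == "(") {
      node <- parse_or()
      if (!identical(take(), ")")) stop("expected `)`", call. = FALSE)
      return(node)
    }
    if (tolower(t) == "qps") return(list(kind = "qps"))
    m <- stringr::str_match(t, "^([a-z_]+):(.+)$")
    if (is.na(m[1, 1])) stop("malformed query leaf: ", t, call. = FALSE)
    list(kind = m[1, 2], value = m[1, 3])
  }
  parse_and <- function() {
    parts <- list(parse_leaf())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      parts <- c(parts, list(parse_leaf()))
    }
    if (length(parts) == 1) parts[[1]] else list(and = parts)
  }
  parse_or <- function() {
    parts <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      parts <- c(parts, list(parse_and()))
    }
    if (length(parts) == 1) parts[[1]] else list(or = parts)
  }
  out <- parse_or()
  if (!is.na(peek())) stop("trailing tokens in query: ", peek(), call. = FALSE)
  out
}

#' Read a query from its YAML tree form
#'
#' The YAML mirrors the query tree: mappings with a single `and:`/`or:` key
#' holding a sequence of sub-queries, and leaves `{kind: ..., value: ...}`.
#'
#' @param path YAML file.
#' @return A query tree.
#' @export
query_from_yaml <- function(path) yaml::read_yaml(path)

#' Validate a query tree against the store's references
#'
#' @param q Query tree.
#' @param store An `hm_store`.
#' @return `TRUE` invisibly; errors on an unknown leaf id.
#' @export
validate_query <- function(q, store) {
  walk <- function(node) {
    if (!is.null(node$kind)) {
      if (node$kind %in% names(LEAF_RECORD_TYPE) &&
          !node$value %in% store$ontology$concepts$id) {
        stop("query leaf references unknown concept: ", node$value, call. = FALSE)
      }
      if (node$kind == "taxon" && !node$value %in% store$taxonomy$nodes$taxid) {
        stop("query leaf references unknown taxid: ", node$value, call. = FALSE)
      }
      return(invisible(NULL))
    }
    lapply(node[[intersect(names(node), c("and", "or"))]], walk)
    invisible(NULL)
  }
  walk(q)
  invisible(TRUE)
}
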