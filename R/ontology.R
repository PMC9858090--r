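#' Ontology container
#'
#' An `hm_ontology` wraps a tibble of concepts (one row per class of the
#' habitat/phenotype/use vocabulary) together with the identifiers of its
#' branch roots. The concept graph is a DAG: a concept may declare several
#' `is_a` parents, but branches are disjoint — a concept reachable from two
#' different branch roots is a validation error.
#'
#' @param concepts Tibble with columns `id`, `label`, `synonyms` (list of
#'   character vectors), `parents` (list of character vectors), `branch`.
#' @param roots Named character vector mapping branch name to root concept id.
#' @return An object of class `hm_ontology` with fields `concepts` and `roots`.
#' @export
new_ontology <- function(concepts, roots) {
  stopifnot(is.data.frame(concepts),
            all(c("id", "label", "synonyms", "parents", "branch") %in% names(concepts)))
  structure(list(concepts = tibble::as_tibble(concepts), roots = roots),
            class = "hm_ontology")
}

#' @export
print.hm_ontology <- function(x, ...) {
  cat("<hm_ontology> ", nrow(x$concepts), " concepts, branches: ",
      paste0(names(x$roots), " (", x$roots, ")", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Parse an OBO flat file into an ontology
#'
#' Reads the `[Term]` stanzas of an OBO 1.2 flat file, keeping the tags `id`,
#' `name`, `synonym` and `is_a`; other tags are ignored. Synonym strings are
#' stripped of their OBO decorations (quotes, scope keyword, xref list).
#' Each concept is assigned to the branch of the single branch root it
#' reaches through `is_a` links.
#'
#' @param x Path to an OBO file, or a character vector of lines.
#' @param branch_roots Optional named character vector (branch name -> root
#'   concept id). When `NULL`, parentless terms are taken as roots and their
#'   lower-cased labels as branch names.
#' @return An [new_ontology()] object.
#' @export
parse_obo <- function(x, branch_roots = NULL) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) readLines(x, warn = FALSE) else
    unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- sub("\\s+$", "", lines)

  # stanza boundaries: lines equal to "[Term]"; other stanza types ignored
  stanza_starts <- which(lines == "[Term]")
  any_stanza <- grepl("^\\[[A-Za-z-]+\\]$", lines)
  terms <- vector("list", length(stanza_starts))
  for (i in seq_along(stanza_starts)) {
    from <- stanza_starts[i] + 1L
    nxt <- which(any_stanza & seq_along(lines) >= from)
    to <- if (length(nxt)) min(nxt) - 1L else length(lines)
    body <- lines[seq(from, length.out = max(0L, to - from + 1L))]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    tag <- sub("^([A-Za-z_]+):.*$", "\\1", body)
    val <- sub("^[A-Za-z_]+:\\s*", "", body)
    val <- sub("\\s*!.*$", "", val)  # trailing comments
    id <- val[tag == "id"]
    name <- val[tag == "name"]
    if (length(id) != 1 || length(name) != 1 || !nzchar(id) || !nzchar(name)) {
      stop("malformed [Term] stanza #", i, ": missing id or name", call. = FALSE)
    }
    syn_raw <- val[tag == "synonym"]
    syn <- stringr::str_match(syn_raw, '^"([^"]*)"')[, 2]
    syn <- syn[!is.na(syn) & nzchar(syn)]
    parents <- val[tag == "is_a"]
    parents <- unique(parents[nzchar(parents)])
    terms[[i]] <- list(id = id, label = name, synonyms = syn, parents = parents)
  }
  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate concept id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  concepts <- tibble::tibble(
    id = ids,
    label = vapply(terms, `[[`, character(1), "label"),
    synonyms = lapply(terms, `[[`, "synonyms"),
    parents = lapply(terms, `[[`, "parents")
  )
  missing <- setdiff(unique(unlist(concepts$parents)), concepts$id)
  if (length(missing)) {
    stop("dangling is_a target(s): ", paste(sort(missing), collapse = ", "),
         call. = FALSE)
  }
  assign_branches(concepts, branch_roots)
}

# Branch assignment + acyclicity validation shared by parse_obo and the
# fixture generator.
assign_branches <- function(concepts, branch_roots = NULL) {
  cyc <- find_cycle(concepts$id, concepts$parents)
  if (!is.null(cyc)) {
    stop("is_a cycle detected: ", paste(cyc, collapse = " -> "), call. = FALSE)
  }
  is_root <- lengths(concepts$parents) == 0L
  root_ids <- concepts$id[is_root]
  if (is.null(branch_roots)) {
    branch_roots <- stats::setNames(root_ids, tolower(concepts$label[is_root]))
  } else {
    bad <- setdiff(branch_roots, concepts$id)
    if (length(bad)) stop("declared branch root(s) not in ontology: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    extra <- setdiff(root_ids, branch_roots)
    if (length(extra)) stop("parentless concept(s) outside declared roots: ",
                            paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!length(branch_roots)) stop("ontology has no branch root", call. = FALSE)

  kids <- children_map(concepts$id, concepts$parents)
  branch <- stats::setNames(rep(NA_character_, nrow(concepts)), concepts$id)
  for (b in names(branch_roots)) {
    reach <- reachable(branch_roots[[b]], kids)
    clash <- reach[!is.na(branch[reach])]
    if (length(clash)) {
      stop("concept(s) reachable from two branch roots: ",
           paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
    }
    branch[reach] <- b
  }
  if (anyNA(branch)) {
    stop("concept(s) not reachable from any branch root: ",
         paste(utils::head(names(branch)[is.na(branch)], 5), collapse = ", "),
         call. = FALSE)
  }
  concepts$branch <- unname(branch[concepts$id])
  new_ontology(concepts, branch_roots)
}

# adjacency: named list id -> character vector of child ids
children_map <- function(ids, parents) {
  edges <- tibble::tibble(child = rep(ids, lengths(parents)),
                          parent = unlist(parents) %||% character())
  kids <- split(edges$child, factor(edges$parent, levels = ids))
  stats::setNames(kids, ids)
}

# ids reachable from start (inclusive) over adjacency list
reachable <- function(start, adj) {
  seen <- character()
  frontier <- start
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
  }
  seen
}

# Kahn's algorithm over child->parent edges; returns one cycle or NULL
find_cycle <- function(ids, parents) {
  deg <- stats::setNames(lengths(parents), ids)  # out-degree towards parents
  kids <- children_map(ids, parents)
  queue <- names(deg)[deg == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (k in kids[[n]]) {
      deg[[k]] <- deg[[k]] - 1L
      if (deg[[k]] == 0L) queue <- c(queue, k)
    }
  }
  if (seen == length(ids)) return(NULL)
  # walk parent links among remaining nodes to exhibit one cycle
  rem <- names(deg)[deg > 0L]
  pmap <- stats::setNames(parents, ids)
  cur <- rem[[1]]; path <- character()
  while (!(cur %in% path)) {
    path <- c(path, cur)
    cur <- intersect(pmap[[cur]], rem)[[1]]
  }
  c(path[which(path == cur):length(path)], cur)
}

#' Serialize an ontology to OBO flat-file lines
#'
#' @param ont An [new_ontology()] object.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when writing to `path`).
#' @export
write_obo <- function(ont, path = NULL) {
  co <- ont$concepts
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(co))) {
    out <- c(out, "[Term]",
             paste0("id: ", co$id[i]),
             paste0("name: ", co$label[i]),
             sprintf('synonym: "%s" EXACT []', co$synonyms[[i]]),
             paste0("is_a: ", co$parents[[i]]),
             "")
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Descendants of a concept or taxon
#'
#' Transitive closure of children, excluding the node itself. For ontologies
#' the closure runs over the `is_a` DAG; for taxonomies over the tree.
#'
#' @param x An `hm_ontology` or `hm_taxonomy`.
#' @param id Identifier present in `x`.
#' @return Character vector of descendant ids (unordered set).
#' @export
descendants <- function(x, id) UseMethod("descendants")

#' @export
descendants.hm_ontology <- function(x, id) {
  if (!id %in% x$concepts$id) stop("unknown concept id: ", id, call. = FALSE)
  kids <- children_map(x$concepts$id, x$concepts$parents)
  setdiff(reachable(id, kids), id)
}

#' Ancestors of a concept
#'
#' Transitive closure of `is_a` parents, excluding the concept itself.
#'
#' @inheritParams descendants
#' @return Character vector of ancestor ids.
#' @export
ancestors <- function(x, id) UseMethod("ancestors")

#' @export
ancestors.hm_ontology <- function(x, id) {
  if (!id %in% x$concepts$id) stop("unknown concept id: ", id, call. = FALSE)
  pmap <- stats::setNames(x$concepts$parents, x$concepts$id)
  seen <- character(); frontier <- pmap[[id]]
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(pmap[frontier], use.names = FALSE)), seen)
  }
  unique(seen)
}

#' Root-to-concept hierarchical paths
#'
#' Enumerates every distinct route from a branch root down to `concept_id`,
#' the index paths under which a record attached to the concept is
#' retrievable. On a tree every concept has exactly one path; multiple
#' inheritance yields one path per route. Paths are sorted lexicographically
#' on their collapsed id string for determinism.
#'
#' @param ont An [new_ontology()] object.
#' @param concept_id Concept identifier.
#' @return List of character vectors, each starting at a branch root and
#'   ending at `concept_id`.
#' @export
hierarchical_paths <- function(ont, concept_id) {
  co <- ont$concepts
  if (!concept_id %in% co$id) stop("unknown concept id: ", concept_id, call. = FALSE)
  pmap <- stats::setNames(co$parents, co$id)
  walk <- function(id) {
    ps <- pmap[[id]]
    if (!length(ps)) return(list(id))
    unlist(lapply(sort(ps), function(p) lapply(walk(p), function(pp) c(pp, id))),
           recursive = FALSE)
  }
  paths <- walk(concept_id)
  paths[order(vapply(paths, paste, character(1), collapse = "\r"))]
}

#' Look up a concept label
#' @param ont An ontology.
#' @param id Concept id(s).
#' @return Character vector of labels.
#' @export
concept_label <- function(ont, id) {
  x <- x_at(ont$concepts$label, ont$concepts$id, id)
  x
}

x_at <- function(values, keys, q) values[match(q, keys)]

`%||%` <- function(a, b) if (is.null(a)) b else a
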