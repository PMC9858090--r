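#' Taxonomy container
#'
#' An `hm_taxonomy` holds a strict tree of taxa: a `nodes` tibble
#' (`taxid`, `parent`, `rank`) and a `names` tibble
#' (`taxid`, `name`, `name_class`). The root is its own parent. Every node
#' carries exactly one scientific name; further names are synonyms,
#' vernacular names, or catalog names of strains.
#'
#' @param nodes Tibble with columns `taxid`, `parent`, `rank`.
#' @param names Tibble with columns `taxid`, `name`, `name_class`.
#' @param root Taxid of the root node.
#' @return An object of class `hm_taxonomy`.
#' @export
new_taxonomy <- function(nodes, names, root) {
  structure(list(nodes = tibble::as_tibble(nodes),
                 names = tibble::as_tibble(names),
                 root = root),
            class = "hm_taxonomy")
}

#' @export
print.hm_taxonomy <- function(x, ...) {
  cat("<hm_taxonomy> ", nrow(x$nodes), " nodes, ", nrow(x$names),
      " names, root: ", x$root, "\n", sep = "")
  invisible(x)
}

NAME_CLASSES <- c("scientific", "synonym", "vernacular", "catalog")

# normalize taxdump name classes to the internal four
canon_name_class <- function(x) {
  x <- tolower(trimws(x))
  dplyr::case_when(
    x %in% c("scientific", "scientific name") ~ "scientific",
    x %in% c("vernacular", "common name", "genbank common name") ~ "vernacular",
    x %in% c("catalog", "type material", "culture collection") ~ "catalog",
    TRUE ~ "synonym"
  )
}

#' Parse NCBI-taxdump-dialect tables into a taxonomy
#'
#' Accepts the `names.dmp` / `nodes.dmp` column order with the
#' `"\t|\t"` separator (and trailing `"\t|"`), or plain tab-separated
#' three-column tables. Name classes are folded to
#' scientific/synonym/vernacular/catalog.
#'
#' @param names_x Path or character lines of the names table
#'   (taxid, name, \[unique name,\] name class).
#' @param nodes_x Path or character lines of the nodes table
#'   (taxid, parent taxid, rank).
#' @return An [new_taxonomy()] object.
#' @export
parse_taxdump <- function(names_x, nodes_x) {
  nm <- read_dmp(names_x)
  nd <- read_dmp(nodes_x)
  if (ncol(nd) < 3) stop("nodes table needs 3 columns (taxid, parent, rank)", call. = FALSE)
  nodes <- tibble::tibble(taxid = nd[[1]], parent = nd[[2]], rank = nd[[3]])
  # names.dmp proper has 4 columns (with "unique name" third); tolerate 3
  cls <- if (ncol(nm) >= 4) nm[[4]] else nm[[3]]
  names <- tibble::tibble(taxid = nm[[1]], name = nm[[2]],
                          name_class = canon_name_class(cls))
  validate_taxonomy(new_taxonomy(nodes, names, root = find_root(nodes)))
}

read_dmp <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) readLines(x, warn = FALSE) else
    unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- lines[nzchar(lines)]
  lines <- sub("\t\\|$", "", lines)
  parts <- strsplit(lines, "\t|\t", fixed = TRUE)
  # plain TSV fallback when the taxdump separator is absent
  if (all(lengths(parts) == 1)) parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- max(lengths(parts))
  cols <- lapply(seq_len(n), function(i)
    trimws(vapply(parts, function(p) if (length(p) >= i) p[[i]] else "", character(1))))
  tibble::as_tibble(stats::setNames(cols, paste0("V", seq_len(n))))
}

find_root <- function(nodes) {
  r <- nodes$taxid[nodes$taxid == nodes$parent | !nzchar(nodes$parent)]
  if (length(r) != 1) stop("taxonomy must have exactly one root, found ",
                           length(r), call. = FALSE)
  r
}

#' Validate taxonomy invariants
#'
#' Checks: unique taxids; parents resolve; single root reached from every
#' node (no cycles); exactly one scientific name per node; no names for
#' unknown taxids.
#'
#' @param tax An [new_taxonomy()] object.
#' @return `tax`, invisibly unchanged, on success.
#' @export
validate_taxonomy <- function(tax) {
  nd <- tax$nodes
  if (anyDuplicated(nd$taxid)) {
    stop("duplicate taxid(s): ",
         paste(unique(nd$taxid[duplicated(nd$taxid)]), collapse = ", "), call. = FALSE)
  }
  orphan_parents <- setdiff(nd$parent, nd$taxid)
  if (length(orphan_parents)) {
    stop("parent taxid(s) missing from nodes: ",
         paste(orphan_parents, collapse = ", "), call. = FALSE)
  }
  orphan_names <- setdiff(tax$names$taxid, nd$taxid)
  if (length(orphan_names)) {
    stop("name row(s) for unknown taxid(s): ",
         paste(orphan_names, collapse = ", "), call. = FALSE)
  }
  sci <- tax$names$taxid[tax$names$name_class == "scientific"]
  tab <- table(factor(sci, levels = nd$taxid))
  bad <- names(tab)[tab != 1L]
  if (length(bad)) {
    stop("node(s) without exactly one scientific name: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  # cycle check: every node must reach the root by parent hops
  pmap <- stats::setNames(nd$parent, nd$taxid)
  depth <- ancestor_depths(pmap, tax$root)
  if (anyNA(depth)) {
    stop("parent links do not form a tree rooted at ", tax$root,
         " (cycle or disconnected node: ",
         paste(utils::head(names(depth)[is.na(depth)], 5), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(tax)
}

# depth of each node above root; NA when root is unreachable
ancestor_depths <- function(pmap, root) {
  depth <- stats::setNames(rep(NA_real_, length(pmap)), names(pmap))
  depth[[root]] <- 0
  for (id in names(pmap)) {
    chain <- character()
    cur <- id
    while (is.na(depth[[cur]]) && !(cur %in% chain)) {
      chain <- c(chain, cur)
      cur <- pmap[[cur]]
    }
    if (!is.na(depth[[cur]])) {
      depth[rev(chain)] <- depth[[cur]] + seq_along(chain)
    }
  }
  depth
}

#' Serialize a taxonomy to taxdump-dialect lines
#'
#' @param tax A taxonomy.
#' @return List with `names` and `nodes` character vectors of lines.
#' @export
write_taxdump <- function(tax) {
  cls_out <- c(scientific = "scientific name", synonym = "synonym",
               vernacular = "common name", catalog = "catalog")
  list(
    names = paste0(tax$names$taxid, "\t|\t", tax$names$name, "\t|\t\t|\t",
                   cls_out[tax$names$name_class], "\t|"),
    nodes = paste0(tax$nodes$taxid, "\t|\t", tax$nodes$parent, "\t|\t",
                   tax$nodes$rank, "\t|")
  )
}

#' Scientific name of taxa
#' @param tax A taxonomy.
#' @param taxid Taxid(s).
#' @return Character vector of scientific names.
#' @export
scientific_name <- function(tax, taxid) {
  sci <- tax$names[tax$names$name_class == "scientific", ]
  sci$name[match(taxid, sci$taxid)]
}

#' Rank of taxa
#' @param tax A taxonomy.
#' @param taxid Taxid(s).
#' @return Character vector of ranks.
#' @export
taxon_rank <- function(tax, taxid) tax$nodes$rank[match(taxid, tax$nodes$taxid)]

#' @export
descendants.hm_taxonomy <- function(x, id) {
  if (!id %in% x$nodes$taxid) stop("unknown taxid: ", id, call. = FALSE)
  non_root <- x$nodes$taxid != x$nodes$parent
  kids <- split(x$nodes$taxid[non_root],
                factor(x$nodes$parent[non_root], levels = x$nodes$taxid))
  setdiff(reachable(id, kids), id)
}

#' @export
ancestors.hm_taxonomy <- function(x, id) {
  if (!id %in% x$nodes$taxid) stop("unknown taxid: ", id, call. = FALSE)
  pmap <- stats::setNames(x$nodes$parent, x$nodes$taxid)
  out <- character()
  while (id != pmap[[id]]) {
    id <- pmap[[id]]
    out <- c(out, id)
  }
  out
}

#' Reserved identifier of the synthetic super-root
#'
#' Microorganisms have no single common ancestor, so restricting a taxonomy
#' to a set of high-level taxa re-roots the selection under a synthetic
#' super-root with this reserved taxid.
#' @return The reserved taxid string.
#' @export
super_root_id <- function() "__MICROBIAL_ROOT__"

#' Restrict a taxonomy to selected subtrees
#'
#' Keeps `root_ids` and all their descendants, re-rooted under a synthetic
#' super-root ([super_root_id()]). The selection models a curated list of
#' high-level microbial taxa that jointly delimit "microorganisms", which
#' have no single common ancestor clade.
#'
#' @param tax A taxonomy.
#' @param root_ids Character vector of taxids to keep (with descendants).
#' @return A new, validated taxonomy.
#' @export
select_microbial_subtree <- function(tax, root_ids) {
  unknown <- setdiff(root_ids, tax$nodes$taxid)
  if (length(unknown)) stop("unknown root id(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  if (super_root_id() %in% tax$nodes$taxid && tax$root != super_root_id()) {
    stop("input taxonomy uses the reserved super-root id", call. = FALSE)
  }
  root_ids <- setdiff(root_ids, super_root_id())
  keep <- unique(unlist(lapply(root_ids, function(r) c(r, descendants(tax, r)))))
  nodes <- tax$nodes[tax$nodes$taxid %in% keep, ]
  nodes$parent[nodes$taxid %in% root_ids] <- super_root_id()
  nodes <- dplyr::bind_rows(
    tibble::tibble(taxid = super_root_id(), parent = super_root_id(), rank = "no rank"),
    nodes)
  nms <- tax$names[tax$names$taxid %in% keep, ]
  nms <- dplyr::bind_rows(
    tibble::tibble(taxid = super_root_id(), name = "microbial super-root",
                   name_class = "scientific"),
    nms)
  validate_taxonomy(new_taxonomy(nodes, nms, root = super_root_id()))
}
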