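# NCBI-taxdump-style taxonomy: parse nodes/names files into an in-memory
# index and resolve any taxon ID to named ranks in O(depth) per lookup.

.split_dmp <- function(lines) {
  # taxdump dialect: fields separated by "\t|\t", rows terminated by "\t|"
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

#' Load an NCBI-style taxonomy dump
#'
#' Parses pipe-and-tab delimited \code{nodes.dmp} / \code{names.dmp} files
#' (the NCBI taxdump dialect) into an in-memory index mapping every taxon ID
#' to its parent, rank, and scientific name. The whole index is held resident
#' so downstream annotation can resolve lineages from organism (OX) IDs in
#' constant time per step. Only rows of name class \code{"scientific name"}
#' are used from the names file; an ID without one gets an empty name.
#'
#' @param nodes_path path to the nodes file (\code{tax_id | parent | rank | ...}).
#' @param names_path path to the names file
#'   (\code{tax_id | name | unique name | name class}).
#' @return an object of class \code{taxonomy_index}.
#' @export
load_taxdump <- function(nodes_path, names_path) {
  if (!file.exists(nodes_path)) stop("nodes file not found: ", nodes_path, call. = FALSE)
  if (!file.exists(names_path)) stop("names file not found: ", names_path, call. = FALSE)

  nl <- readLines(nodes_path, warn = FALSE)
  nl <- nl[nzchar(nl)]
  nf <- .split_dmp(nl)
  bad <- which(vapply(nf, length, 1L) < 3L)
  if (length(bad))
    stop("malformed row at line ", bad[1L], " of nodes file: expected at least ",
         "'tax_id | parent | rank'", call. = FALSE)
  ids <- suppressWarnings(as.integer(vapply(nf, `[[`, "", 1L)))
  parents <- suppressWarnings(as.integer(vapply(nf, `[[`, "", 2L)))
  ranks <- trimws(vapply(nf, `[[`, "", 3L))
  bad <- which(is.na(ids) | is.na(parents))
  if (length(bad))
    stop("malformed row at line ", bad[1L], " of nodes file: non-integer taxon ID",
         call. = FALSE)

  ml <- readLines(names_path, warn = FALSE)
  ml <- ml[nzchar(ml)]
  nm_id <- integer(0); nm_txt <- character(0)
  if (length(ml)) {
    mf <- .split_dmp(ml)
    bad <- which(vapply(mf, length, 1L) < 4L)
    if (length(bad))
      stop("malformed row at line ", bad[1L], " of names file: expected ",
           "'tax_id | name | unique name | name class'", call. = FALSE)
    cls <- trimws(vapply(mf, `[[`, "", 4L))
    sci <- cls == "scientific name"
    nm_id <- suppressWarnings(as.integer(vapply(mf[sci], `[[`, "", 1L)))
    nm_txt <- trimws(vapply(mf[sci], `[[`, "", 2L))
    bad <- which(is.na(nm_id))
    if (length(bad))
      stop("malformed row in names file: non-integer taxon ID", call. = FALSE)
  }

  names_full <- character(length(ids))
  m <- match(ids, nm_id)
  names_full[!is.na(m)] <- nm_txt[m[!is.na(m)]]

  env <- new.env(hash = TRUE, parent = emptyenv(), size = length(ids))
  for (i in seq_along(ids)) {
    assign(as.character(ids[i]),
           list(parent = parents[i], rank = ranks[i], name = names_full[i]),
           envir = env)
  }
  structure(list(nodes = env, ids = sort(ids)), class = "taxonomy_index")
}

#' @export
print.taxonomy_index <- function(x, ...) {
  cat("Taxonomy index:", length(x$ids), "taxa\n")
  invisible(x)
}

.taxon_node <- function(index, taxon_id) {
  get0(as.character(taxon_id), envir = index$nodes, inherits = FALSE)
}

#' Resolve a taxon to requested ranks along its lineage
#'
#' Walks from the taxon to the root, reporting for each requested rank the
#' nearest ancestor (or the taxon itself) carrying that rank. A rank with no
#' ancestor is reported as absent (\code{NULL}) -- never imputed -- so
#' downstream uniqueness logic can treat "absent" as its own category.
#' Non-canonical ranks such as \code{"no rank"} or \code{"clade"} never match
#' a requested standard rank. If a node's parent is missing from the index
#' (dangling parent), the walk stops there and reports the ranks found so far.
#'
#' @param index a \code{\link{load_taxdump}} index.
#' @param taxon_id a single known taxon ID.
#' @param ranks non-empty character vector of rank names, e.g.
#'   \code{c("species", "genus", "superkingdom")}.
#' @return named list over \code{ranks}; each element either
#'   \code{list(taxon_id =, name =)} or \code{NULL} when absent.
#' @export
lineage <- function(index, taxon_id, ranks) {
  stopifnot(inherits(index, "taxonomy_index"))
  if (length(ranks) < 1L) stop("ranks must be non-empty", call. = FALSE)
  taxon_id <- as.integer(taxon_id)
  node <- .taxon_node(index, taxon_id)
  if (is.null(node))
    stop(structure(class = c("taxopep_unknown_taxon", "error", "condition"),
                   list(message = paste0("unknown taxon ID: ", taxon_id),
                        call = sys.call())))
  out <- stats::setNames(vector("list", length(ranks)), ranks)
  id <- taxon_id
  seen <- character(0)
  repeat {
    key <- as.character(id)
    if (key %in% seen) break                       # cycle guard
    seen <- c(seen, key)
    if (node$rank %in% ranks && is.null(out[[node$rank]]))
      out[[node$rank]] <- list(taxon_id = id, name = node$name)
    if (node$parent == id) break                   # root is its own parent
    id <- node$parent
    node <- .taxon_node(index, id)
    if (is.null(node)) break                       # dangling parent: stop here
  }
  out
}

# vectorized lineage with memoization; returns a data.frame of
# taxon_id x rank -> (rank_taxon_id, rank_name), NA when absent
.lineage_table <- function(index, taxon_ids, ranks) {
  taxon_ids <- unique(as.integer(taxon_ids))
  res <- lapply(taxon_ids, function(id) {
    ln <- lineage(index, id, ranks)
    data.frame(
      taxon_id = id, rank = ranks,
      rank_taxon_id = vapply(ln, function(e) if (is.null(e)) NA_integer_ else e$taxon_id, 1L),
      rank_name = vapply(ln, function(e) if (is.null(e)) NA_character_ else e$name, ""),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, res)
}
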