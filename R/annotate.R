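# Annotate experimental peptide tables with taxa and genes, apply
# taxon-specificity filters ("assume one organism" vs "species-unique only"),
# roll quantitation up to gene symbols, normalize against a reference pool,
# and compute peptidome-sharing statistics.

#' Read a tab-delimited peptide table
#'
#' Reads search-engine peptide output (e.g. the MaxQuant \code{peptides.txt}
#' dialect: a \code{Sequence} column plus named quantitative columns).
#' Column names are preserved verbatim.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_peptide_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Annotate a peptide table with taxa and genes from a PCDB
#'
#' Each row's sequence is modification-stripped, canonicalized with the
#' database's stored parameters, and looked up; hits are resolved to the
#' requested taxonomic ranks through the lineage index. Quantitative columns
#' are carried through unmodified. Rows with zero database hits are retained
#' and flagged unmatched so match-rate QC is possible.
#'
#' Added columns: \code{stripped_sequence}, \code{matched}, \code{n_hits},
#' \code{genes} (semicolon-joined union over hits), \code{n_genes}, and per
#' requested rank \code{taxa_<rank>} (semicolon-joined names) and
#' \code{unique_<rank>} (\code{TRUE} iff all hits resolve to a single named
#' taxon at that rank; hits lacking the rank count as their own "absent"
#' category and therefore break uniqueness). A \code{hits} list-column
#' retains the per-row hit detail for downstream filtering.
#'
#' @param table data frame with a peptide-sequence column.
#' @param handle an indexed \code{pcdb} handle.
#' @param index a \code{\link{load_taxdump}} taxonomy index.
#' @param ranks character vector of ranks to annotate, e.g.
#'   \code{c("species", "genus")}.
#' @param sequence_col name of the sequence column (default
#'   \code{"Sequence"}).
#' @return the annotated table (class \code{annotated_peptides}).
#' @export
annotate_peptides <- function(table, handle, index,
                              ranks = c("species", "genus"),
                              sequence_col = "Sequence") {
  stopifnot(inherits(handle, "pcdb"), inherits(index, "taxonomy_index"))
  if (!sequence_col %in% names(table))
    stop("schema error: expected a '", sequence_col, "' column; found: ",
         paste(names(table), collapse = ", "), call. = FALSE)

  out <- table
  stripped <- strip_modifications(table[[sequence_col]])
  canonical <- canonicalize_peptide(stripped, handle$params$il_equivalence)
  out$stripped_sequence <- stripped

  hits <- .query_canonical(handle, canonical)
  if (nrow(hits)) {
    lt <- .lineage_table(index, unique(hits$taxon_id), ranks)
    for (r in ranks) {
      sl <- lt[lt$rank == r, ]
      m <- match(hits$taxon_id, sl$taxon_id)
      hits[[paste0("rank_id_", r)]] <- sl$rank_taxon_id[m]
      hits[[paste0("rank_name_", r)]] <- sl$rank_name[m]
    }
  }
  hit_split <- if (nrow(hits)) split(hits, hits$peptide) else list()

  n <- nrow(out)
  out$hits <- lapply(seq_len(n), function(i) {
    h <- hit_split[[canonical[i]]]
    if (is.null(h)) hits[0, , drop = FALSE] else h
  })
  out$n_hits <- vapply(out$hits, nrow, 1L)
  out$matched <- out$n_hits > 0L
  gene_sets <- lapply(out$hits, function(h) sort(unique(h$gene[nzchar(h$gene)])))
  out$genes <- vapply(gene_sets, paste, "", collapse = ";")
  out$n_genes <- lengths(gene_sets)
  for (r in ranks) {
    idc <- paste0("rank_id_", r); nmc <- paste0("rank_name_", r)
    taxa <- lapply(out$hits, function(h) {
      if (!nrow(h)) return(character(0))
      sort(unique(h[[nmc]][!is.na(h[[idc]])]))
    })
    uniq <- vapply(seq_len(n), function(i) {
      h <- out$hits[[i]]
      if (!nrow(h)) return(FALSE)
      ids <- unique(h[[idc]])
      length(ids) == 1L && !anyNA(ids)
    }, TRUE)
    out[[paste0("taxa_", r)]] <- vapply(taxa, paste, "", collapse = ";")
    out[[paste0("unique_", r)]] <- uniq
  }
  attr(out, "ranks") <- ranks
  attr(out, "sequence_col") <- sequence_col
  class(out) <- c("annotated_peptides", "data.frame")
  out
}

#' Taxon-specificity filter
#'
#' Two regimes mirror the two ways mixed-species data are commonly analyzed.
#' With \code{require_unique = TRUE} ("species-unique" semantics), a row is
#' kept only if its hits are unique to a single taxon at \code{rank} (and
#' that taxon passes the include/exclude lists). With
#' \code{require_unique = FALSE} and a \code{default_taxon} ("assume one
#' organism" semantics, simulating a search against a single organism's
#' proteome), a row is kept whenever the default taxon is among its plausible
#' assignments, and attributed to it, even if other taxa also match; rows
#' hitting only excluded taxa are dropped.
#'
#' @param rank rank name at which specificity is evaluated.
#' @param include optional allowlist of taxon names at that rank.
#' @param exclude optional blocklist (disjoint from \code{include}).
#' @param default_taxon optional taxon name receiving shared peptides in the
#'   non-unique regime.
#' @param require_unique require taxon-unique peptides (default
#'   \code{FALSE}).
#' @return a \code{taxon_filter} object.
#' @export
taxon_filter <- function(rank, include = NULL, exclude = NULL,
                         default_taxon = NULL, require_unique = FALSE) {
  if (length(intersect(include, exclude)))
    stop("include and exclude lists must be disjoint", call. = FALSE)
  if (!is.null(default_taxon) && require_unique && length(include) > 1L)
    stop("ambiguous filter: default_taxon with require_unique and multiple ",
         "include entries", call. = FALSE)
  structure(list(rank = rank, include = include, exclude = exclude,
                 default_taxon = default_taxon,
                 require_unique = isTRUE(require_unique)),
            class = "taxon_filter")
}

#' Apply a taxon-specificity filter to an annotated table
#'
#' Adds an \code{assigned_taxon} column and, when per-row hit detail is
#' available, restricts \code{genes}/\code{n_genes} to the hits of the
#' assigned taxon. Unmatched rows are always dropped by filtering.
#'
#' @param annotated an \code{\link{annotate_peptides}} result annotated at
#'   the filter's rank.
#' @param filter a \code{\link{taxon_filter}}.
#' @return the filtered table; number of dropped rows in attribute
#'   \code{"dropped"}.
#' @export
apply_taxon_filter <- function(annotated, filter) {
  stopifnot(inherits(filter, "taxon_filter"))
  rank <- filter$rank
  tcol <- paste0("taxa_", rank); ucol <- paste0("unique_", rank)
  if (!tcol %in% names(annotated))
    stop("table is not annotated at rank '", rank, "'", call. = FALSE)
  taxa_list <- strsplit(annotated[[tcol]], ";", fixed = TRUE)
  taxa_list <- lapply(taxa_list, function(x) x[nzchar(x)])

  assigned <- rep(NA_character_, nrow(annotated))
  keep <- logical(nrow(annotated))
  for (i in seq_len(nrow(annotated))) {
    taxa <- taxa_list[[i]]
    if (!length(taxa)) next
    if (filter$require_unique) {
      if (!isTRUE(annotated[[ucol]][i])) next
      tx <- taxa[1L]
      if (length(filter$exclude) && tx %in% filter$exclude) next
      if (length(filter$include) && !tx %in% filter$include) next
      keep[i] <- TRUE; assigned[i] <- tx
    } else {
      eff <- setdiff(taxa, filter$exclude)
      if (!is.null(filter$default_taxon)) {
        if (filter$default_taxon %in% taxa) {
          keep[i] <- TRUE; assigned[i] <- filter$default_taxon
        }
      } else if (length(filter$include)) {
        sel <- intersect(filter$include, eff)
        if (length(sel)) { keep[i] <- TRUE; assigned[i] <- sel[1L] }
      } else if (length(eff)) {
        keep[i] <- TRUE
        assigned[i] <- if (length(eff) == 1L) eff else NA_character_
      }
    }
  }

  out <- annotated[keep, , drop = FALSE]
  out$assigned_taxon <- assigned[keep]
  # restrict genes to the assigned taxon's hits when detail is available
  if ("hits" %in% names(out) && nrow(out)) {
    nmc <- paste0("rank_name_", rank)
    for (i in seq_len(nrow(out))) {
      h <- out$hits[[i]]
      if (!nrow(h) || is.na(out$assigned_taxon[i]) || !nmc %in% names(h)) next
      g <- h$gene[!is.na(h[[nmc]]) & h[[nmc]] == out$assigned_taxon[i]]
      g <- sort(unique(g[nzchar(g)]))
      out$genes[i] <- paste(g, collapse = ";")
      out$n_genes[i] <- length(g)
    }
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!keep)
  attr(out, "ranks") <- attr(annotated, "ranks")
  out
}

#' Roll peptide quantitation up to gene symbols
#'
#' Sums each quantitative column over the peptide rows of each gene. Only
#' rows mapping to exactly one gene symbol contribute; rows mapping to zero
#' or multiple genes are dropped and counted (no fractional/razor
#' allocation). Column totals over the output equal the totals over the
#' retained rows (conservation).
#'
#' @param filtered an annotated (and typically taxon-filtered) peptide table
#'   with \code{genes} and \code{n_genes} columns.
#' @param quant_columns names of the quantitative columns to sum.
#' @return data frame with \code{gene}, \code{n_peptides}, and one summed
#'   column per quant column; dropped multi-gene row count in attribute
#'   \code{"dropped_multigene"}.
#' @export
rollup_to_genes <- function(filtered, quant_columns) {
  missing_cols <- setdiff(quant_columns, names(filtered))
  if (length(missing_cols))
    stop("schema error: quant column(s) absent: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  usable <- filtered$n_genes == 1L
  dropped_multi <- sum(filtered$n_genes > 1L)
  df <- filtered[usable, , drop = FALSE]
  if (!nrow(df)) {
    out <- data.frame(gene = character(0), n_peptides = integer(0))
    for (qc in quant_columns) out[[qc]] <- numeric(0)
    attr(out, "dropped_multigene") <- dropped_multi
    return(out)
  }
  gene <- df$genes
  qm <- as.matrix(df[, quant_columns, drop = FALSE])
  storage.mode(qm) <- "double"
  sums <- rowsum(qm, gene)
  counts <- as.integer(table(gene)[rownames(sums)])
  out <- data.frame(gene = rownames(sums), n_peptides = counts,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  for (j in seq_along(quant_columns)) out[[quant_columns[j]]] <- sums[, j]
  attr(out, "dropped_multigene") <- dropped_multi
  out
}

#' Normalize a gene-by-channel table against an internal reference pool
#'
#' In order: (1) each channel is divided by the reference-pool channel,
#' per gene; (2) log2 transform; (3) each channel is centered by its median;
#' (4) each channel is divided by its standard deviation (population SD).
#' After normalization every channel has median 0 and SD 1 (the reference
#' channel itself becomes all zeros at step 2 and is left at zero rather
#' than divided by its zero SD). Genes whose reference value is missing or
#' not strictly positive are dropped and counted.
#'
#' @param gene_table output of \code{\link{rollup_to_genes}} (or any data
#'   frame with a \code{gene} column and numeric channel columns).
#' @param reference_channel name of the reference-pool column.
#' @param channels channel columns to normalize; default: all numeric
#'   columns except \code{n_peptides}.
#' @return the normalized table; dropped-gene count in attribute
#'   \code{"dropped_reference"}.
#' @export
normalize_reference_pool <- function(gene_table, reference_channel,
                                     channels = NULL) {
  if (!reference_channel %in% names(gene_table))
    stop("reference channel '", reference_channel, "' absent", call. = FALSE)
  if (is.null(channels)) {
    channels <- names(gene_table)[vapply(gene_table, is.numeric, TRUE)]
    channels <- setdiff(channels, "n_peptides")
  }
  ref <- gene_table[[reference_channel]]
  ok <- !is.na(ref) & ref > 0
  dropped <- sum(!ok)
  out <- gene_table[ok, , drop = FALSE]
  if (nrow(out) < 2L)
    stop("fewer than 2 genes with a positive reference value: SD undefined",
         call. = FALSE)
  ref <- out[[reference_channel]]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  for (ch in channels) {
    x <- log2(out[[ch]] / ref)
    x <- x - stats::median(x)
    s <- pop_sd(x)
    out[[ch]] <- if (s > 0) x / s else x
  }
  rownames(out) <- NULL
  attr(out, "dropped_reference") <- dropped
  out
}

#' Per-gene fraction of one proteome's peptides shared with another
#'
#' Digests both collections (keeping raw canonical peptide sequences, not
#' hashes), pools peptides per gene symbol, and reports for each gene of
#' \code{proteome_a} the fraction of its peptides also produced by the
#' same-symbol gene of \code{proteome_b}. Genes absent from \code{b} get
#' fraction 0 and are flagged. The attribute
#' \code{"fraction_genes_shared"} summarizes the fraction of a's genes with
#' nonzero sharing -- the quantity that makes cross-species quantitative
#' interference visible (e.g. human vs mouse homologs in xenograft data).
#'
#' @param proteome_a,proteome_b \code{\link{protein_records}} collections
#'   carrying gene symbols.
#' @param params a \code{\link{digest_params}} object.
#' @return data frame with \code{gene}, \code{n_peptides_a},
#'   \code{n_shared}, \code{fraction_shared}, \code{gene_in_b}.
#' @export
shared_peptidome_fraction <- function(proteome_a, proteome_b,
                                      params = digest_params()) {
  gene_peptides <- function(recs) {
    recs <- recs[nzchar(recs$gene), , drop = FALSE]
    sets <- list()
    for (i in seq_len(nrow(recs))) {
      p <- digest_protein(recs$sequence[i], params)$peptide
      g <- recs$gene[i]
      sets[[g]] <- unique(c(sets[[g]], p))
    }
    sets
  }
  pa <- gene_peptides(proteome_a)
  pb <- gene_peptides(proteome_b)
  genes <- names(pa)
  n_a <- vapply(genes, function(g) length(pa[[g]]), 1L)
  n_sh <- vapply(genes, function(g) length(intersect(pa[[g]], pb[[g]])), 1L)
  out <- data.frame(gene = genes, n_peptides_a = n_a, n_shared = n_sh,
                    fraction_shared = ifelse(n_a > 0, n_sh / n_a, 0),
                    gene_in_b = genes %in% names(pb),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fraction_genes_shared") <-
    if (nrow(out)) mean(out$n_shared > 0) else NA_real_
  out
}

#' Per-genus peptidome uniqueness statistics over a PCDB
#'
#' Tallies, for every genus represented in the database, the number of
#' distinct peptides whose parent proteins include that genus (total) and
#' the number unique to it (all parents resolve to that genus). Proteins
#' with no resolvable genus are pooled in an \code{"unranked"} bucket.
#' This makes database composition bias visible: overrepresented genera
#' contribute disproportionately many peptides.
#'
#' @param handle an indexed \code{pcdb} handle.
#' @param index a taxonomy index covering the database's taxa.
#' @return data frame with \code{genus}, \code{total_peptides},
#'   \code{unique_peptides}, \code{fraction_shared}, sorted by total
#'   descending.
#' @export
genus_peptidome_stats <- function(handle, index) {
  stopifnot(inherits(handle, "pcdb"), inherits(index, "taxonomy_index"))
  df <- DBI::dbGetQuery(handle$con,
    "SELECT DISTINCT CAST(r.HashPeptide AS TEXT) AS hash, m.TaxonID AS taxon_id
       FROM Reference r JOIN MainData m ON r.ProteinKey = m.ProteinKey")
  if (!nrow(df))
    return(data.frame(genus = character(0), total_peptides = integer(0),
                      unique_peptides = integer(0), fraction_shared = numeric(0)))
  lt <- .lineage_table(index, unique(df$taxon_id), "genus")
  genus <- lt$rank_name[match(df$taxon_id, lt$taxon_id)]
  genus[is.na(genus)] <- "unranked"
  pg <- unique(data.frame(hash = df$hash, genus = genus, stringsAsFactors = FALSE))
  cnt <- table(pg$hash)
  n_genera <- as.integer(cnt[pg$hash])
  total <- table(pg$genus)
  uniq <- table(pg$genus[n_genera == 1L])
  genera <- names(total)
  out <- data.frame(genus = genera,
                    total_peptides = as.integer(total),
                    unique_peptides = as.integer(uniq[genera]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$unique_peptides[is.na(out$unique_peptides)] <- 0L
  out$fraction_shared <- ifelse(out$total_peptides > 0,
                                1 - out$unique_peptides / out$total_peptides, 0)
  out[order(-out$total_peptides, out$genus), , drop = FALSE]
}
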