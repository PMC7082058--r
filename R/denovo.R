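# Database-constrained de novo pipeline: candidate filtering, serial matching
# against a PCDB, modification-collapsed spectral counting of genus-unique
# peptides, and forward/reverse decoy genus ranking.

#' De novo pipeline parameters
#'
#' @param min_alc minimum average local confidence (ALC, 0--100) for a
#'   candidate to be considered (default 50).
#' @param min_spectral_counts minimum spectra per peptide, summed across all
#'   samples, for the peptide to be retained (default 2).
#' @param rank_for_uniqueness rank at which peptide uniqueness is required
#'   (default \code{"genus"}).
#' @param delta_threshold genera are accepted when
#'   forward - reverse counts exceed this (default 7).
#' @param mode \code{"database_constrained"}: candidates for each spectrum
#'   are checked serially in descending-confidence order until one matches
#'   the database; \code{"top_candidate"}: only the best candidate is tested.
#' @return a \code{denovo_params} object.
#' @export
denovo_params <- function(min_alc = 50, min_spectral_counts = 2L,
                          rank_for_uniqueness = "genus",
                          delta_threshold = 7,
                          mode = c("database_constrained", "top_candidate")) {
  mode <- match.arg(mode)
  if (min_alc < 0 || min_alc > 100) stop("min_alc must be in [0, 100]", call. = FALSE)
  if (min_spectral_counts < 1L) stop("min_spectral_counts must be >= 1", call. = FALSE)
  if (delta_threshold < 0) stop("delta_threshold must be >= 0", call. = FALSE)
  structure(list(min_alc = min_alc,
                 min_spectral_counts = as.integer(min_spectral_counts),
                 rank_for_uniqueness = rank_for_uniqueness,
                 delta_threshold = delta_threshold,
                 mode = mode),
            class = "denovo_params")
}

#' Read a de novo candidate table
#'
#' Reads a CSV of per-spectrum sequence candidates (the PEAKS
#' "all de novo candidates.csv" dialect by default: \code{Scan},
#' \code{Peptide}, \code{ALC (\%)}). Candidates are grouped by spectrum and
#' ordered by descending ALC; equal-ALC candidates keep their input order
#' (the emission order of the source tool). Rows with ALC outside [0, 100]
#' are rejected with a warning.
#'
#' @param path CSV file path.
#' @param spectrum_col,peptide_col,alc_col column names.
#' @return a \code{denovo_candidates} data frame with columns
#'   \code{spectrum}, \code{peptide}, \code{alc}, \code{cand_rank}.
#' @export
read_candidates <- function(path, spectrum_col = "Scan",
                            peptide_col = "Peptide", alc_col = "ALC (%)") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(spectrum_col, peptide_col, alc_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("schema error: candidate CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- data.frame(spectrum = as.character(df[[spectrum_col]]),
                    peptide = as.character(df[[peptide_col]]),
                    alc = as.numeric(df[[alc_col]]),
                    stringsAsFactors = FALSE)
  bad <- is.na(out$alc) | out$alc < 0 | out$alc > 100
  if (any(bad)) {
    warning(sum(bad), " candidate row(s) rejected: ALC outside [0, 100]",
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  o <- order(out$spectrum, -out$alc, seq_len(nrow(out)))
  out <- out[o, , drop = FALSE]
  out$cand_rank <- stats::ave(seq_len(nrow(out)), out$spectrum,
                              FUN = seq_along)
  rownames(out) <- NULL
  class(out) <- c("denovo_candidates", "data.frame")
  out
}

#' Constrain de novo candidates to a peptide database
#'
#' Candidates below the ALC floor are discarded first; the remainder are
#' modification-stripped and checked against the database in
#' descending-confidence order. In \code{database_constrained} mode the
#' first candidate of each spectrum with at least one database hit is
#' accepted and later candidates are ignored; in \code{top_candidate} mode
#' only the single best candidate is tested. At most one peptide is accepted
#' per spectrum; spectra with no matching candidate yield none.
#'
#' @param candidates a \code{\link{read_candidates}} table.
#' @param handle an indexed \code{pcdb} handle.
#' @param params a \code{\link{denovo_params}} object.
#' @return list with \code{accepted} (data frame \code{spectrum},
#'   \code{peptide} = stripped canonical sequence, \code{alc},
#'   \code{cand_rank}) and \code{hits} (data frame \code{peptide},
#'   \code{accession}, \code{taxon_id}, \code{gene} over accepted peptides).
#' @export
constrain_to_db <- function(candidates, handle, params = denovo_params()) {
  stopifnot(inherits(handle, "pcdb"))
  cand <- candidates[candidates$alc >= params$min_alc, , drop = FALSE]
  if (params$mode == "top_candidate")
    cand <- cand[cand$cand_rank == 1L, , drop = FALSE]
  cand$canonical <- canonicalize_peptide(strip_modifications(cand$peptide),
                                         handle$params$il_equivalence)
  hits <- .query_canonical(handle, unique(cand$canonical))
  matched_set <- unique(hits$peptide)
  cand$matched <- cand$canonical %in% matched_set

  accepted <- cand[0, c("spectrum", "canonical", "alc", "cand_rank")]
  if (nrow(cand)) {
    m <- cand[cand$matched, , drop = FALSE]
    # serial check == first (highest-confidence) matching candidate wins
    first <- !duplicated(m$spectrum)
    accepted <- m[first, c("spectrum", "canonical", "alc", "cand_rank")]
  }
  names(accepted)[names(accepted) == "canonical"] <- "peptide"
  rownames(accepted) <- NULL
  hits <- hits[hits$peptide %in% accepted$peptide, , drop = FALSE]
  rownames(hits) <- NULL
  list(accepted = accepted, hits = hits)
}

#' Genus-level spectral counting of accepted de novo peptides
#'
#' Pools modified and unmodified observations of the same stripped sequence
#' (one count per accepted spectrum), then retains a peptide iff it is
#' unique to a single genus, its total spectral count across all samples
#' reaches \code{min_spectral_counts}, and its annotation passes the taxon
#' allowlist (by default: bacterial superkingdom or human species, the
#' setting appropriate for oral-microbiome samples; configurable since it is
#' study-specific).
#'
#' @param constrained result of \code{\link{constrain_to_db}}.
#' @param index a taxonomy index.
#' @param params a \code{\link{denovo_params}} object.
#' @param allow list with \code{superkingdoms} and \code{species} name
#'   vectors; a peptide passes if its resolved superkingdom or species is
#'   listed. Use \code{NULL} to disable the allowlist.
#' @return data frame with \code{genus}, \code{n_peptides},
#'   \code{spectral_counts}, sorted by peptide count descending.
#' @export
genus_unique_counts <- function(constrained, index,
                                params = denovo_params(),
                                allow = list(superkingdoms = "Bacteria",
                                             species = "Homo sapiens")) {
  stopifnot(inherits(index, "taxonomy_index"))
  accepted <- constrained$accepted
  hits <- constrained$hits
  empty <- data.frame(genus = character(0), n_peptides = integer(0),
                      spectral_counts = integer(0), stringsAsFactors = FALSE)
  if (!nrow(accepted) || !nrow(hits)) return(empty)

  rank_u <- params$rank_for_uniqueness
  ranks <- unique(c(rank_u, "superkingdom", "species"))
  lt <- .lineage_table(index, unique(hits$taxon_id), ranks)
  pick <- function(r) {
    sl <- lt[lt$rank == r, ]
    list(id = sl$rank_taxon_id[match(hits$taxon_id, sl$taxon_id)],
         name = sl$rank_name[match(hits$taxon_id, sl$taxon_id)])
  }
  ru <- pick(rank_u); sk <- pick("superkingdom"); sp <- pick("species")

  counts <- table(accepted$peptide)   # spectra per modification-collapsed peptide
  peptides <- names(counts)
  keep_genus <- character(0); keep_counts <- integer(0)
  for (p in peptides) {
    sel <- hits$peptide == p
    ids <- unique(ru$id[sel])
    if (length(ids) != 1L || anyNA(ids)) next          # not genus-unique
    if (!is.null(allow)) {
      sks <- unique(sk$name[sel]); sps <- unique(sp$name[sel])
      if (!(any(sks %in% allow$superkingdoms, na.rm = TRUE) ||
            any(sps %in% allow$species, na.rm = TRUE))) next
    }
    if (counts[[p]] < params$min_spectral_counts) next
    gname <- unique(ru$name[sel][!is.na(ru$id[sel])])[1L]
    keep_genus <- c(keep_genus, gname)
    keep_counts <- c(keep_counts, counts[[p]])
  }
  if (!length(keep_genus)) return(empty)
  out <- data.frame(genus = names(table(keep_genus)),
                    n_peptides = as.integer(table(keep_genus)),
                    spectral_counts = as.integer(
                      tapply(keep_counts, keep_genus, sum)[names(table(keep_genus))]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_peptides, out$genus), , drop = FALSE]
}

#' Rank genera by forward-minus-reverse decoy difference
#'
#' Joins per-genus counts from the forward PCDB run and the reversed-decoy
#' PCDB run (produced with identical parameters), computes
#' \eqn{\Delta = forward - reverse}, and accepts genera with
#' \eqn{\Delta >} \code{delta_threshold}. Genera absent from either map
#' count 0 there.
#'
#' @param forward_counts,reverse_counts \code{\link{genus_unique_counts}}
#'   outputs for the forward and reversed databases.
#' @param params a \code{\link{denovo_params}} object.
#' @param measure which count to difference: \code{"peptides"} (distinct
#'   genus-unique peptides; the scale on which the default threshold of 7 is
#'   defined) or \code{"spectra"}.
#' @return data frame with \code{genus}, \code{forward}, \code{reverse},
#'   \code{delta}, \code{accepted}, sorted by delta descending.
#' @export
decoy_delta <- function(forward_counts, reverse_counts,
                        params = denovo_params(),
                        measure = c("peptides", "spectra")) {
  measure <- match.arg(measure)
  col <- if (measure == "peptides") "n_peptides" else "spectral_counts"
  genera <- union(forward_counts$genus, reverse_counts$genus)
  fwd <- forward_counts[[col]][match(genera, forward_counts$genus)]
  rev_ <- reverse_counts[[col]][match(genera, reverse_counts$genus)]
  fwd[is.na(fwd)] <- 0L; rev_[is.na(rev_)] <- 0L
  out <- data.frame(genus = genera, forward = fwd, reverse = rev_,
                    delta = fwd - rev_, stringsAsFactors = FALSE)
  out$accepted <- out$delta > params$delta_threshold
  out <- out[order(-out$delta, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full de novo genus-identification pipeline
#'
#' Convenience wrapper: constrains candidates against the forward and the
#' reversed-decoy databases with identical parameters, counts genus-unique
#' peptides on both arms, and returns the decoy-delta genus report.
#'
#' @param candidates a \code{\link{read_candidates}} table.
#' @param forward_handle,reverse_handle indexed \code{pcdb} handles for the
#'   forward and reversed-sequence databases.
#' @param index a taxonomy index.
#' @param params a \code{\link{denovo_params}} object.
#' @param allow taxon allowlist, see \code{\link{genus_unique_counts}}.
#' @return list with \code{report} (the \code{\link{decoy_delta}} table),
#'   \code{forward_counts}, \code{reverse_counts}.
#' @export
denovo_genus_report <- function(candidates, forward_handle, reverse_handle,
                                index, params = denovo_params(),
                                allow = list(superkingdoms = "Bacteria",
                                             species = "Homo sapiens")) {
  fwd <- genus_unique_counts(constrain_to_db(candidates, forward_handle, params),
                             index, params, allow)
  rev_ <- genus_unique_counts(constrain_to_db(candidates, reverse_handle, params),
                              index, params, allow)
  list(report = decoy_delta(fwd, rev_, params),
       forward_counts = fwd, reverse_counts = rev_)
}
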