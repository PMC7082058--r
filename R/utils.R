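#' @useDynLib taxopep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Strip modification annotations from peptide strings
#'
#' Removes bracketed or parenthesized modification tags (e.g. PEAKS-style
#' \code{"PEPT(+57.02)IDE"} or \code{"M[Oxidation]AGIC"}) and any remaining
#' non-letter characters, then uppercases. The stripped sequence is the join
#' key used for database lookup and for pooling modified/unmodified forms of
#' the same peptide during spectral counting.
#'
#' @param x character vector of peptide strings as written by a search engine.
#' @return character vector of plain uppercase residue strings.
#' @examples
#' strip_modifications("PEPT(+57.02)IDEK")
#' @export
strip_modifications <- function(x) {
  x <- as.character(x)
  repeat {
    y <- gsub("\\([^()]*\\)", "", x)
    y <- gsub("\\[[^][]*\\]", "", y)
    if (identical(y, x)) break
    x <- y
  }
  toupper(gsub("[^A-Za-z]", "", x))
}

#' Canonicalize peptide sequences for matching
#'
#' Uppercases and, when \code{il_equivalence} is on, maps isoleucine to
#' leucine (I and L are isobaric and indistinguishable by standard MS2).
#' The I -> L direction is fixed so that experimental peptides and database
#' peptides are conflated identically.
#'
#' @param x character vector of residue strings.
#' @param il_equivalence apply the I -> L mapping (default \code{TRUE}).
#' @return canonical residue strings.
#' @export
canonicalize_peptide <- function(x, il_equivalence = TRUE) {
  x <- toupper(as.character(x))
  if (isTRUE(il_equivalence)) x <- chartr("I", "L", x) else x
}

# residues that void a peptide for hashing/matching (ambiguity codes and
# selenocysteine cannot be matched by an observed sequence)
.noncanonical_pattern <- "[XUBZ]"

`%||%` <- function(a, b) if (is.null(a)) b else a

.msg_n <- function(n, singular, plural = paste0(singular, "s")) {
  if (n == 1L) singular else plural
}
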