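# In-silico proteolysis: protease rules, fragment enumeration with missed
# cleavages, N-terminal Met excision variants, I/L canonicalization, and the
# stable 64-bit peptide hash.

.protease_builtins <- list(
  "trypsin/p"    = list(residues = c("K", "R"), blocked = character(), side = "C"),
  "trypsin"      = list(residues = c("K", "R"), blocked = "P",         side = "C"),
  "lys-c"        = list(residues = "K",         blocked = character(), side = "C"),
  "chymotrypsin" = list(residues = c("F", "Y", "W"), blocked = "P",    side = "C"),
  "glu-c"        = list(residues = c("D", "E"), blocked = character(), side = "C"),
  "asp-n"        = list(residues = "D",         blocked = character(), side = "N")
)

#' Resolve a protease specification to a cleavage rule
#'
#' Built-in rules: \code{"trypsin/p"} (after K/R, proline allowed),
#' \code{"trypsin"} (after K/R unless followed by P), \code{"lys-c"},
#' \code{"chymotrypsin"} (after F/Y/W unless followed by P, high-specificity
#' convention), \code{"glu-c"} (after D/E), \code{"asp-n"} (before D).
#' A custom rule is a list with \code{residues} (cleavage residues),
#' optional \code{blocked} (residues that block cleavage when adjacent on the
#' peptide-bond side being cut) and \code{side} ("C", cut after the residue,
#' or "N", cut before it).
#'
#' @param protease a built-in rule name or a custom rule list.
#' @return a normalized rule list with fields \code{name}, \code{residues},
#'   \code{blocked}, \code{side}.
#' @export
resolve_protease <- function(protease = "trypsin/p") {
  if (is.character(protease) && length(protease) == 1L) {
    key <- tolower(protease)
    if (!key %in% names(.protease_builtins)) {
      stop("unknown protease '", protease, "'; built-ins are: ",
           paste(names(.protease_builtins), collapse = ", "),
           call. = FALSE)
    }
    rule <- .protease_builtins[[key]]
    rule$name <- key
    return(rule)
  }
  if (is.list(protease)) {
    if (is.null(protease$residues) || !length(protease$residues))
      stop("custom protease rule needs a non-empty 'residues' field", call. = FALSE)
    rule <- list(
      residues = toupper(unlist(strsplit(as.character(protease$residues), ""))),
      blocked  = toupper(unlist(strsplit(as.character(protease$blocked %||% character()), ""))),
      side     = toupper(protease$side %||% "C"),
      name     = protease$name %||% "custom"
    )
    if (!rule$side %in% c("C", "N"))
      stop("custom protease 'side' must be \"C\" or \"N\"", call. = FALSE)
    return(rule)
  }
  stop("protease must be a rule name or a custom rule list", call. = FALSE)
}

#' Digestion parameter set
#'
#' The full rule set governing in-silico proteolysis and peptide
#' canonicalization. Defaults follow common bottom-up practice: tryptic
#' peptides of 7--55 residues, trypsin/p (cleavage C-terminal to K or R,
#' including before proline), up to 2 missed cleavages, protein N-terminal
#' methionine excision, and isoleucine/leucine equivalence.
#'
#' @param min_len minimum peptide length in residues (default 7).
#' @param max_len maximum peptide length in residues (default 55).
#' @param protease rule name or custom rule list (see
#'   \code{\link{resolve_protease}}); default \code{"trypsin/p"}.
#' @param max_missed_cleavages maximum number of internal uncut sites
#'   retained within a peptide (default 2).
#' @param nterm_met_excision when the protein starts with methionine, every
#'   peptide anchored at the N-terminus also contributes its Met-less
#'   variant; both variants are length-filtered independently (default
#'   \code{TRUE}).
#' @param il_equivalence canonicalize I to L before hashing and matching
#'   (default \code{TRUE}).
#' @return an object of class \code{digest_params}.
#' @export
digest_params <- function(min_len = 7L, max_len = 55L, protease = "trypsin/p",
                          max_missed_cleavages = 2L, nterm_met_excision = TRUE,
                          il_equivalence = TRUE) {
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  if (is.na(min_len) || min_len < 1L || is.na(max_len) || max_len < min_len)
    stop("require 1 <= min_len <= max_len", call. = FALSE)
  if (is.na(max_missed_cleavages) || max_missed_cleavages < 0L)
    stop("max_missed_cleavages must be >= 0", call. = FALSE)
  rule <- resolve_protease(protease)
  structure(list(
    min_len = min_len, max_len = max_len,
    protease = rule,
    max_missed_cleavages = max_missed_cleavages,
    nterm_met_excision = isTRUE(nterm_met_excision),
    il_equivalence = isTRUE(il_equivalence)
  ), class = "digest_params")
}

#' @export
print.digest_params <- function(x, ...) {
  cat("In-silico digest parameters\n")
  cat("  protease:            ", x$protease$name,
      " (", x$protease$side, "-side of ",
      paste(x$protease$residues, collapse = ""),
      if (length(x$protease$blocked))
        paste0(", blocked by ", paste(x$protease$blocked, collapse = "")),
      ")\n", sep = "")
  cat("  peptide length:       ", x$min_len, "-", x$max_len, " residues\n", sep = "")
  cat("  missed cleavages:    <=", x$max_missed_cleavages, "\n")
  cat("  N-term Met excision: ", x$nterm_met_excision, "\n")
  cat("  I/L equivalence:     ", x$il_equivalence, "\n")
  invisible(x)
}

#' Locate proteolytic cleavage sites in a protein sequence
#'
#' Returns the 1-based residue positions after which the peptide bond is cut.
#' For trypsin/p these are all K or R positions except the final residue
#' (a cut after the last residue is not a site).
#'
#' @param sequence a single residue string.
#' @param protease rule name or custom rule list.
#' @return sorted integer vector of cut positions (possibly empty).
#' @examples
#' cleavage_sites("MAGICRHAPPYKDAYR")           # cuts after the R at 6, K at 12
#' cleavage_sites("AKPR", "trypsin")            # strict trypsin blocks K before P
#' @export
cleavage_sites <- function(sequence, protease = "trypsin/p") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("sequence must be non-empty", call. = FALSE)
  rule <- if (inherits(protease, "digest_params")) protease$protease
          else resolve_protease(protease)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (rule$side == "C") {
    pos <- which(ch %in% rule$residues)
    pos <- pos[pos < n]
    if (length(rule$blocked) && length(pos))
      pos <- pos[!(ch[pos + 1L] %in% rule$blocked)]
  } else {
    pos <- which(ch %in% rule$residues) - 1L
    pos <- pos[pos >= 1L]
    if (length(rule$blocked) && length(pos))
      pos <- pos[!(ch[pos] %in% rule$blocked)]
  }
  as.integer(pos)
}

#' Digest a protein sequence in silico
#'
#' Enumerates all peptides spanning at most \code{max_missed_cleavages}
#' internal cut sites whose length lies in \code{[min_len, max_len]}. When
#' N-terminal Met excision is on and the protein starts with M, every peptide
#' anchored at the N-terminus additionally contributes its Met-less variant
#' (length re-checked independently). Peptides containing non-canonical
#' residues (X, U, B, Z) are excluded: ambiguity codes cannot be matched by an
#' observed sequence. Canonicalization (I -> L) is applied before hashing, so
#' the returned \code{peptide} column is the canonical form; duplicates keep
#' the smallest missed-cleavage count.
#'
#' @param sequence a single protein residue string (or a one-row protein
#'   record data frame with a \code{sequence} column).
#' @param params a \code{\link{digest_params}} object.
#' @return data frame with columns \code{peptide} (canonical sequence),
#'   \code{hash} (decimal string of the signed 64-bit hash) and
#'   \code{missed} (missed-cleavage count).
#' @export
digest_protein <- function(sequence, params = digest_params()) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L, "sequence" %in% names(sequence))
    sequence <- sequence$sequence
  }
  stopifnot(inherits(params, "digest_params"))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("sequence must be non-empty", call. = FALSE)

  cuts <- cleavage_sites(sequence, params$protease)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  nf <- length(starts)

  out_start <- integer(0); out_end <- integer(0); out_mc <- integer(0)
  for (k in 0:params$max_missed_cleavages) {
    if (nf - k < 1L) break
    i <- seq_len(nf - k)
    out_start <- c(out_start, starts[i])
    out_end <- c(out_end, ends[i + k])
    out_mc <- c(out_mc, rep.int(k, length(i)))
  }
  pep <- substring(sequence, out_start, out_end)
  mcv <- out_mc

  if (params$nterm_met_excision && startsWith(sequence, "M")) {
    anchored <- out_start == 1L
    if (any(anchored)) {
      pep <- c(pep, substring(sequence, 2L, out_end[anchored]))
      mcv <- c(mcv, out_mc[anchored])
    }
  }

  len <- nchar(pep)
  keep <- len >= params$min_len & len <= params$max_len &
    !grepl(.noncanonical_pattern, pep)
  pep <- pep[keep]; mcv <- mcv[keep]
  pep <- canonicalize_peptide(pep, params$il_equivalence)

  if (length(pep)) {
    o <- order(pep, mcv)
    pep <- pep[o]; mcv <- mcv[o]
    d <- !duplicated(pep)
    pep <- pep[d]; mcv <- mcv[d]
  }
  data.frame(peptide = pep, hash = if (length(pep)) .fnv1a64(pep) else character(0),
             missed = mcv, stringsAsFactors = FALSE)
}

#' Hash a canonical peptide sequence to a stable 64-bit integer
#'
#' FNV-1a 64-bit over the residue bytes, reported as the signed value in
#' decimal (as a string, since R has no native 64-bit integer). The hash is a
#' pure function of the canonical sequence and identical across platforms and
#' processes, so databases built anywhere agree. The caller is expected to
#' canonicalize first (I -> L if configured): hashing itself never conflates
#' residues.
#'
#' @param canonical_sequence character vector of canonical residue strings.
#' @return character vector of signed 64-bit decimal values.
#' @export
hash_peptide <- function(canonical_sequence) {
  canonical_sequence <- as.character(canonical_sequence)
  if (any(!nzchar(canonical_sequence)))
    stop("cannot hash an empty peptide sequence", call. = FALSE)
  .fnv1a64(canonical_sequence)
}

#' Verify that a canonical peptide is a valid digestion product of a protein
#'
#' Used for hash-collision safety when querying the peptide database: a hash
#' hit is only reported if the canonicalized peptide literally occurs in the
#' parent protein with valid cleavage boundaries, a missed-cleavage count
#' within bounds, and a length within bounds, under the given parameters.
#'
#' @param protein_sequence the parent protein residue string (as stored).
#' @param canonical_peptide the canonical peptide to verify.
#' @param params \code{\link{digest_params}} used at database build time.
#' @return \code{TRUE} if at least one occurrence is a valid digestion
#'   product.
#' @export
peptide_occurs_in <- function(protein_sequence, canonical_peptide,
                              params = digest_params()) {
  stopifnot(inherits(params, "digest_params"))
  protein_sequence <- toupper(protein_sequence)
  prot_c <- canonicalize_peptide(protein_sequence, params$il_equivalence)
  L <- nchar(canonical_peptide)
  if (L < params$min_len || L > params$max_len) return(FALSE)
  hits <- gregexpr(canonical_peptide, prot_c, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(FALSE)
  # cut sites computed on the ORIGINAL sequence: I->L can create spurious
  # sites for residue-specific rules like chymotrypsin
  cuts <- cleavage_sites(protein_sequence, params$protease)
  n <- nchar(protein_sequence)
  metx <- params$nterm_met_excision && startsWith(protein_sequence, "M")
  for (s in as.integer(hits)) {
    e <- s + L - 1L
    n_ok <- s == 1L || ((s - 1L) %in% cuts) || (metx && s == 2L)
    c_ok <- e == n || (e %in% cuts)
    if (n_ok && c_ok &&
        sum(cuts >= s & cuts < e) <= params$max_missed_cleavages)
      return(TRUE)
  }
  FALSE
}
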