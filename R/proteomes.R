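# Protein FASTA collections with UniProt-style headers (OX=/GN= tokens):
# read, write, concatenate, decoy-reverse, and a network-optional
# acquisition contract with a pluggable transport.

#' Construct / validate a protein record collection
#'
#' A collection is a data frame with one row per protein: \code{accession},
#' \code{gene} (may be empty), \code{taxon_id} (positive integer, the NCBI
#' organism ID carried in the UniProt OX token) and \code{sequence}
#' (uppercase residues over the 20 amino acids plus X/U/B/Z). Accessions are
#' unique within a collection.
#'
#' @param accession,gene,taxon_id,sequence field vectors of equal length.
#' @return a \code{protein_records} data frame.
#' @export
protein_records <- function(accession, gene = "", taxon_id, sequence) {
  df <- data.frame(accession = as.character(accession),
                   gene = as.character(gene),
                   taxon_id = as.integer(taxon_id),
                   sequence = toupper(as.character(sequence)),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$sequence))) stop("sequences must be non-empty", call. = FALSE)
  if (any(is.na(df$taxon_id) | df$taxon_id <= 0L))
    stop("taxon_id must be a positive integer", call. = FALSE)
  if (anyDuplicated(df$accession))
    stop("accessions must be unique within a collection", call. = FALSE)
  class(df) <- c("protein_records", "data.frame")
  df
}

.as_protein_records <- function(df, rejected = 0L) {
  class(df) <- c("protein_records", "data.frame")
  attr(df, "rejected") <- as.integer(rejected)
  df
}

#' Parse protein FASTA text with UniProt-style headers
#'
#' Accepts FASTA text (a character vector of lines) whose headers carry an
#' \code{OX=<taxon>} token and optionally a \code{GN=<gene>} token, the
#' UniProt dialect (e.g. \code{>sp|P12345|NAME_HUMAN Desc GN=ABC OX=9606}).
#' The accession is the second field of a \code{db|acc|entry} header, or
#' otherwise the first whitespace-delimited word. Multi-line sequences are
#' joined and uppercased. Entries without an OX token, with an empty
#' sequence, or duplicating an earlier accession are rejected with a warning;
#' the reject count is returned in the \code{"rejected"} attribute.
#'
#' @param text character vector of FASTA lines (or a single string with
#'   embedded newlines).
#' @return a \code{\link{protein_records}} collection with a
#'   \code{"rejected"} attribute.
#' @export
parse_fasta <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  text <- text[nzchar(trimws(text))]
  if (!length(text)) return(.as_protein_records(
    data.frame(accession = character(0), gene = character(0),
               taxon_id = integer(0), sequence = character(0),
               stringsAsFactors = FALSE)))
  hdr <- startsWith(text, ">")
  if (!any(hdr)) stop("not FASTA: no '>' header lines found", call. = FALSE)
  grp <- cumsum(hdr)
  if (grp[1L] == 0L) stop("not FASTA: sequence data before first header", call. = FALSE)
  headers <- sub("^>", "", text[hdr])
  seqs <- vapply(split(text[!hdr], grp[!hdr]), paste0, "", collapse = "")
  sequence <- character(length(headers))
  sequence[as.integer(names(seqs))] <- seqs
  sequence <- toupper(gsub("[[:space:]]", "", sequence))

  first_word <- sub("[[:space:]].*$", "", headers)
  accession <- ifelse(grepl("^[^|]+\\|[^|]+\\|", first_word),
                      vapply(strsplit(first_word, "|", fixed = TRUE), `[[`, "", 2L),
                      first_word)
  extract_token <- function(h, pattern) {
    m <- regexpr(pattern, h)
    out <- rep("", length(h))
    hit <- m > 0L
    out[hit] <- substring(h[hit], m[hit] + 3L,
                          m[hit] + attr(m, "match.length")[hit] - 1L)
    out
  }
  ox <- suppressWarnings(as.integer(extract_token(headers, "OX=[0-9]+")))
  gene <- extract_token(headers, "GN=[^ \t]+")

  ok <- !is.na(ox) & ox > 0L & nzchar(sequence)
  dup <- duplicated(accession)
  keep <- ok & !dup
  rejected <- sum(!keep)
  if (rejected > 0L) {
    warning(rejected, " FASTA ", .msg_n(rejected, "entry", "entries"),
            " rejected (missing/invalid OX token, empty sequence, or ",
            "duplicate accession)", call. = FALSE)
  }
  .as_protein_records(
    data.frame(accession = accession[keep], gene = gene[keep],
               taxon_id = ox[keep], sequence = sequence[keep],
               stringsAsFactors = FALSE, row.names = NULL),
    rejected = rejected)
}

#' Read a protein FASTA file
#'
#' @param path FASTA file path.
#' @return a \code{\link{protein_records}} collection (see
#'   \code{\link{parse_fasta}}).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) return(parse_fasta(character(0)))
  lines <- as.character(rbind(paste0(">", names(aa)), as.character(aa)))
  parse_fasta(lines)
}

#' Write a protein record collection as UniProt-dialect FASTA
#'
#' Headers are \code{>accession [GN=gene] OX=taxon}; reading the file back
#' with \code{\link{read_fasta}} reproduces the collection (round trip).
#'
#' @param records a \code{\link{protein_records}} collection.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  hdr <- paste0(records$accession,
                ifelse(nzchar(records$gene), paste0(" GN=", records$gene), ""),
                " OX=", records$taxon_id)
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Concatenate protein record collections
#'
#' Order-preserving union; duplicate accessions across inputs keep the first
#' occurrence, and the number dropped is returned in the
#' \code{"duplicates"} attribute.
#'
#' @param collections list of \code{\link{protein_records}} collections.
#' @return concatenated collection.
#' @export
concatenate_proteomes <- function(collections) {
  if (is.data.frame(collections)) collections <- list(collections)
  df <- do.call(rbind, lapply(collections, function(x) as.data.frame(x)[
    , c("accession", "gene", "taxon_id", "sequence"), drop = FALSE]))
  if (is.null(df)) df <- data.frame(accession = character(0), gene = character(0),
                                    taxon_id = integer(0), sequence = character(0))
  dup <- duplicated(df$accession)
  out <- .as_protein_records(df[!dup, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "duplicates") <- sum(dup)
  out
}

#' Build a reversed-sequence decoy collection
#'
#' Reverses every protein sequence end-to-end and prefixes the accession with
#' a decoy marker; gene and taxon are preserved. Whole-protein reversal keeps
#' the amino-acid composition identical while destroying (almost all) true
#' proteolytic peptides, which is what makes the decoy arm an estimate of the
#' false-match rate.
#'
#' @param records a \code{\link{protein_records}} collection.
#' @param marker accession prefix for decoy entries (default \code{"REV_"}).
#' @return decoy collection of the same shape.
#' @export
reverse_decoy <- function(records, marker = "REV_") {
  out <- as.data.frame(records)
  out$sequence <- vapply(strsplit(out$sequence, "", fixed = TRUE),
                         function(ch) paste(rev(ch), collapse = ""), "")
  out$accession <- paste0(marker, out$accession)
  .as_protein_records(out)
}

#' A transport that serves per-taxon FASTA files from a local directory
#'
#' For tests and offline work: taxon \code{t} is served from
#' \code{<dir>/<t>.fasta}. A missing file yields an empty result (empty
#' proteome), mirroring an empty remote answer.
#'
#' @param dir directory holding \code{<taxon>.fasta} files.
#' @return a transport function \code{function(taxon_id, sources)} returning
#'   FASTA text.
#' @export
fixture_transport <- function(dir) {
  force(dir)
  function(taxon_id, sources) {
    f <- file.path(dir, paste0(taxon_id, ".fasta"))
    if (!file.exists(f)) return(character(0))
    readLines(f, warn = FALSE)
  }
}

#' A transport querying the UniProt REST API
#'
#' Query template:
#' \code{https://rest.uniprot.org/uniprotkb/stream?format=fasta&query=organism_id:<taxon>[ AND reviewed:true|false]}
#' with \code{"curated"} mapping to \code{reviewed:true}, \code{"unreviewed"}
#' to \code{reviewed:false}, and \code{"reference"} adding a reference-proteome
#' filter. Only used when explicitly injected; never exercised in tests.
#'
#' @param base_url API endpoint.
#' @return a transport function.
#' @export
uniprot_transport <- function(base_url = "https://rest.uniprot.org/uniprotkb/stream") {
  force(base_url)
  function(taxon_id, sources) {
    q <- paste0("organism_id:", taxon_id)
    if ("curated" %in% sources && !"unreviewed" %in% sources)
      q <- paste0(q, " AND reviewed:true")
    if ("unreviewed" %in% sources && !"curated" %in% sources)
      q <- paste0(q, " AND reviewed:false")
    if ("reference" %in% sources)
      q <- paste0(q, " AND proteome:*")
    url <- paste0(base_url, "?format=fasta&query=", utils::URLencode(q, reserved = TRUE))
    readLines(url, warn = FALSE)
  }
}

#' Fetch and concatenate proteomes for a set of taxa
#'
#' Retrieves one FASTA per taxon through the injected transport (with
#' retry-and-backoff), validates it, concatenates, and writes a single FASTA
#' file. An empty result for a taxon is a warning, not a failure; a malformed
#' result is an error naming the taxon.
#'
#' @param taxon_ids integer vector of organism IDs.
#' @param out_path output FASTA path.
#' @param sources subset of \code{c("curated", "unreviewed", "reference")}.
#' @param transport a function \code{(taxon_id, sources) -> FASTA text};
#'   see \code{\link{fixture_transport}} and \code{\link{uniprot_transport}}.
#' @param retries transport attempts per taxon (default 3).
#' @param backoff seconds between attempts, doubled each retry.
#' @return the concatenated \code{\link{protein_records}} collection,
#'   invisibly; per-taxon record counts in the \code{"fetch_counts"}
#'   attribute.
#' @export
fetch_proteomes <- function(taxon_ids, out_path, sources = "curated",
                            transport = uniprot_transport(),
                            retries = 3L, backoff = 0.5) {
  stopifnot(is.function(transport))
  sources <- match.arg(sources, c("curated", "unreviewed", "reference"),
                       several.ok = TRUE)
  taxon_ids <- as.integer(taxon_ids)
  if (!length(taxon_ids))
    warning("empty taxon list: writing an empty FASTA", call. = FALSE)
  parts <- list()
  counts <- stats::setNames(integer(length(taxon_ids)), taxon_ids)
  for (i in seq_along(taxon_ids)) {
    tid <- taxon_ids[i]
    txt <- NULL
    for (attempt in seq_len(max(1L, retries))) {
      txt <- tryCatch(transport(tid, sources), error = function(e) e)
      if (!inherits(txt, "error")) break
      if (attempt < retries) Sys.sleep(backoff * 2^(attempt - 1L))
    }
    if (inherits(txt, "error"))
      stop("transport failed for taxon ", tid, " after ", retries,
           " attempts: ", conditionMessage(txt), call. = FALSE)
    recs <- tryCatch(parse_fasta(txt), error = function(e)
      stop("malformed FASTA from transport for taxon ", tid, ": ",
           conditionMessage(e), call. = FALSE))
    if (!nrow(recs))
      warning("no records retrieved for taxon ", tid, call. = FALSE)
    counts[i] <- nrow(recs)
    parts[[i]] <- recs
  }
  out <- concatenate_proteomes(parts)
  write_fasta(out, out_path)
  message("fetched ", nrow(out), " records for ", length(taxon_ids), " taxa")
  attr(out, "fetch_counts") <- counts
  invisible(out)
}
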