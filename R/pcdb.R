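# The peptide database (PCDB): a single-file SQLite database with three
# relations --
#   MainData (ProteinKey, Accession, Sequence, TaxonID, Gene)
#   Reference (HashPeptide, ProteinKey)
#   DBParams  (Param, Value)
# -- holding one Reference row per (peptide, protein) incidence, the hashed
# peptide column indexed in a separate step, and the exact digestion
# parameters persisted so queries always canonicalize with the build rules.

.PCDB_SCHEMA_VERSION <- "1"

.serialize_params <- function(params) {
  rule <- params$protease
  c(min_len = as.character(params$min_len),
    max_len = as.character(params$max_len),
    protease = rule$name,
    protease_residues = paste(rule$residues, collapse = ""),
    protease_blocked = paste(rule$blocked, collapse = ""),
    protease_side = rule$side,
    max_missed_cleavages = as.character(params$max_missed_cleavages),
    nterm_met_excision = as.character(as.integer(params$nterm_met_excision)),
    il_equivalence = as.character(as.integer(params$il_equivalence)))
}

.deserialize_params <- function(kv) {
  rule_name <- kv[["protease"]]
  protease <- if (rule_name %in% names(.protease_builtins)) rule_name else
    list(name = rule_name,
         residues = kv[["protease_residues"]],
         blocked = kv[["protease_blocked"]],
         side = kv[["protease_side"]])
  digest_params(
    min_len = as.integer(kv[["min_len"]]),
    max_len = as.integer(kv[["max_len"]]),
    protease = protease,
    max_missed_cleavages = as.integer(kv[["max_missed_cleavages"]]),
    nterm_met_excision = kv[["nterm_met_excision"]] == "1",
    il_equivalence = kv[["il_equivalence"]] == "1")
}

.read_dbparams <- function(con) {
  df <- DBI::dbGetQuery(con, "SELECT Param, Value FROM DBParams")
  stats::setNames(df$Value, df$Param)
}

#' Open an existing peptide database
#'
#' @param path path to a PCDB file.
#' @return a \code{pcdb} handle (environment with the connection, path, and
#'   the digestion parameters stored at build time).
#' @export
open_pcdb <- function(path) {
  if (!file.exists(path)) stop("no PCDB at ", path, call. = FALSE)
  con <- suppressWarnings(DBI::dbConnect(RSQLite::SQLite(), path))
  ok <- tryCatch(
    all(c("MainData", "Reference", "DBParams") %in% DBI::dbListTables(con)),
    error = function(e) FALSE)
  if (!isTRUE(ok)) {
    try(DBI::dbDisconnect(con), silent = TRUE)
    stop("integrity error: ", path, " is not a readable PCDB", call. = FALSE)
  }
  kv <- .read_dbparams(con)
  h <- new.env(parent = emptyenv())
  h$con <- con
  h$path <- path
  h$params <- .deserialize_params(kv)
  h$meta <- kv
  class(h) <- "pcdb"
  h
}

#' Close a peptide database handle
#' @param handle a \code{pcdb} handle.
#' @export
close_pcdb <- function(handle) {
  stopifnot(inherits(handle, "pcdb"))
  if (!is.null(handle$con) && DBI::dbIsValid(handle$con))
    DBI::dbDisconnect(handle$con)
  invisible(NULL)
}

#' @export
print.pcdb <- function(x, ...) {
  np <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM MainData")$n
  nr <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM Reference")$n
  cat("PCDB at ", x$path, "\n  proteins: ", np,
      "\n  peptide incidences: ", nr,
      "\n  indexed: ", identical(x$meta[["indexed"]], "1"),
      "\n  protease: ", x$params$protease$name, "\n", sep = "")
  invisible(x)
}

#' Retrieve the digestion parameters stored in a PCDB
#'
#' DBParams is authoritative: queries always canonicalize with these stored
#' parameters, never with caller-side settings.
#'
#' @param handle a \code{pcdb} handle.
#' @return a \code{\link{digest_params}} object.
#' @export
pcdb_params <- function(handle) {
  stopifnot(inherits(handle, "pcdb"))
  handle$params
}

#' Build a peptide database from a protein collection
#'
#' Digests every protein under \code{params}, hashes the canonical peptides,
#' and writes the three-relation SQLite schema. One Reference row is written
#' per distinct (peptide, protein) incidence. The row multiset is identical
#' regardless of \code{workers}: parallelism partitions proteins, and a
#' single writer merges the results. Indexing is a separate step
#' (\code{\link{index_pcdb}}) so build time scales linearly with protein
#' count.
#'
#' @param records a \code{\link{protein_records}} collection (non-empty).
#' @param params a \code{\link{digest_params}} object.
#' @param path output file path.
#' @param workers digestion worker processes (forked; default 1).
#' @param overwrite replace an existing file (default \code{FALSE}: refuse).
#' @return an open \code{pcdb} handle.
#' @export
create_pcdb <- function(records, params = digest_params(), path,
                        workers = 1L, overwrite = FALSE) {
  stopifnot(inherits(params, "digest_params"))
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty protein collection", call. = FALSE)
  if (file.exists(path)) {
    if (!overwrite)
      stop("file exists at ", path, "; pass overwrite = TRUE to replace",
           call. = FALSE)
    unlink(path)
  }
  workers <- max(1L, as.integer(workers))

  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  ok <- FALSE
  on.exit({
    try(DBI::dbDisconnect(con), silent = TRUE)
    if (!ok) unlink(path)                      # no partial files
  })
  DBI::dbExecute(con, "PRAGMA journal_mode = OFF")
  DBI::dbExecute(con, "PRAGMA synchronous = OFF")
  DBI::dbExecute(con, "CREATE TABLE MainData (
      ProteinKey INTEGER PRIMARY KEY, Accession TEXT NOT NULL,
      Sequence TEXT NOT NULL, TaxonID INTEGER NOT NULL, Gene TEXT)")
  DBI::dbExecute(con, "CREATE TABLE Reference (
      HashPeptide INTEGER NOT NULL, ProteinKey INTEGER NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE DBParams (Param TEXT PRIMARY KEY, Value TEXT)")

  main <- data.frame(ProteinKey = seq_len(nrow(records)),
                     Accession = records$accession,
                     Sequence = records$sequence,
                     TaxonID = records$taxon_id,
                     Gene = records$gene,
                     stringsAsFactors = FALSE)
  DBI::dbWriteTable(con, "MainData", main, append = TRUE)

  digest_chunk <- function(keys) {
    res <- lapply(keys, function(k) {
      d <- digest_protein(records$sequence[k], params)
      if (!nrow(d)) return(NULL)
      list(hash = d$hash, key = rep.int(k, nrow(d)))
    })
    res <- res[!vapply(res, is.null, TRUE)]
    data.frame(HashText = unlist(lapply(res, `[[`, "hash"), use.names = FALSE) %||% character(0),
               ProteinKey = unlist(lapply(res, `[[`, "key"), use.names = FALSE) %||% integer(0),
               stringsAsFactors = FALSE)
  }

  keys <- seq_len(nrow(records))
  chunk_size <- 2000L
  chunks <- split(keys, ceiling(keys / chunk_size))
  digested <- if (workers > 1L) {
    res <- parallel::mclapply(chunks, digest_chunk, mc.cores = workers)
    errs <- vapply(res, inherits, TRUE, what = "try-error")
    if (any(errs) || any(vapply(res, is.null, TRUE)))
      stop("digestion worker failed; build aborted", call. = FALSE)
    res
  } else {
    lapply(chunks, digest_chunk)
  }

  DBI::dbExecute(con, "CREATE TEMP TABLE staging (HashText TEXT, ProteinKey INTEGER)")
  for (d in digested)
    if (nrow(d)) DBI::dbWriteTable(con, "staging", d, append = TRUE, temporary = TRUE)
  DBI::dbExecute(con, "INSERT INTO Reference (HashPeptide, ProteinKey)
                       SELECT CAST(HashText AS INTEGER), ProteinKey FROM staging")
  DBI::dbExecute(con, "DROP TABLE staging")

  kv <- c(.serialize_params(params),
          schema_version = .PCDB_SCHEMA_VERSION,
          hash_algorithm = "fnv1a64",
          indexed = "0",
          n_proteins = as.character(nrow(records)))
  DBI::dbWriteTable(con, "DBParams",
                    data.frame(Param = names(kv), Value = unname(kv),
                               stringsAsFactors = FALSE),
                    append = TRUE)
  ok <- TRUE
  on.exit()
  DBI::dbDisconnect(con)
  open_pcdb(path)
}

#' Index the hashed-peptide column of a PCDB
#'
#' Saved as a separate step at the end of database creation; idempotent if
#' already indexed. Sets the \code{indexed} flag in DBParams.
#'
#' @param handle a \code{pcdb} handle.
#' @return the handle, with the index present.
#' @export
index_pcdb <- function(handle) {
  stopifnot(inherits(handle, "pcdb"))
  if (identical(handle$meta[["indexed"]], "1")) return(invisible(handle))
  DBI::dbExecute(handle$con,
                 "CREATE INDEX IF NOT EXISTS idx_hashpeptide ON Reference (HashPeptide)")
  DBI::dbExecute(handle$con,
                 "UPDATE DBParams SET Value = '1' WHERE Param = 'indexed'")
  handle$meta[["indexed"]] <- "1"
  invisible(handle)
}

# batched raw lookup: canonical peptides -> verified hit rows.
# Verification makes queries collision-safe: a hash hit is reported only if
# the canonical peptide is a literal, boundary-valid digestion product of the
# stored parent sequence under the build parameters.
.query_canonical <- function(handle, canonical, verify = TRUE) {
  params <- handle$params
  empty <- data.frame(peptide = character(0), accession = character(0),
                      taxon_id = integer(0), gene = character(0),
                      stringsAsFactors = FALSE)
  canonical <- unique(canonical[nzchar(canonical)])
  lens <- nchar(canonical)
  canonical <- canonical[lens >= params$min_len & lens <= params$max_len]
  if (!length(canonical)) return(empty)
  hashes <- .fnv1a64(canonical)
  by_hash <- stats::setNames(canonical, hashes)
  out <- vector("list", 0L)
  chunk <- 400L
  for (i in seq(1L, length(hashes), by = chunk)) {
    hs <- hashes[i:min(i + chunk - 1L, length(hashes))]
    sql <- sprintf(
      "SELECT CAST(r.HashPeptide AS TEXT) AS hash, m.Accession, m.Sequence,
              m.TaxonID, m.Gene
         FROM Reference r JOIN MainData m ON r.ProteinKey = m.ProteinKey
        WHERE r.HashPeptide IN (%s)", paste(hs, collapse = ","))
    out[[length(out) + 1L]] <- DBI::dbGetQuery(handle$con, sql)
  }
  hits <- do.call(rbind, out)
  if (is.null(hits) || !nrow(hits)) return(empty)
  hits$peptide <- unname(by_hash[hits$hash])
  if (verify) {
    keep <- logical(nrow(hits))
    for (i in seq_len(nrow(hits)))
      keep[i] <- peptide_occurs_in(hits$Sequence[i], hits$peptide[i], params)
    hits <- hits[keep, , drop = FALSE]
  }
  if (!nrow(hits)) return(empty)
  res <- data.frame(peptide = hits$peptide, accession = hits$Accession,
                    taxon_id = hits$TaxonID, gene = hits$Gene,
                    stringsAsFactors = FALSE)
  unique(res)
}

#' Query a peptide database with an observed sequence
#'
#' The observed sequence is canonicalized with the database's own stored
#' parameters (DBParams is authoritative), hashed, looked up, and every hash
#' hit is verified against the stored parent protein sequence before being
#' reported (collision safety). A sequence outside the database's length
#' bounds returns an empty result, not an error.
#'
#' @param handle an indexed \code{pcdb} handle.
#' @param observed_sequence one or more observed peptide sequences
#'   (modification tags are NOT stripped here; see
#'   \code{\link{strip_modifications}}).
#' @return data frame with columns \code{peptide} (canonical form),
#'   \code{accession}, \code{taxon_id}, \code{gene}; zero rows when nothing
#'   matches.
#' @export
query_peptide <- function(handle, observed_sequence) {
  stopifnot(inherits(handle, "pcdb"))
  canonical <- canonicalize_peptide(observed_sequence,
                                    handle$params$il_equivalence)
  .query_canonical(handle, canonical)
}
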