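# Independent brute-force oracles and small fixture builders shared across
# the suite. The digestion oracle enumerates every substring and accepts it
# iff its boundaries are termini or valid cut sites (or the Met-excision
# start), its internal cut count is within bounds, and its length is in
# range. It shares no code with the implementation under test.

oracle_digest <- function(sequence, min_len = 7L, max_len = 55L,
                          residues = c("K", "R"), blocked = character(),
                          side = "C", max_missed = 2L, met_excision = TRUE,
                          il = TRUE) {
  sequence <- toupper(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cut <- rep(FALSE, n)                 # cut[p]: bond after residue p is cut
  for (p in seq_len(n - 1L)) {
    cut[p] <- if (side == "C") {
      ch[p] %in% residues && !(ch[p + 1L] %in% blocked)
    } else {
      ch[p + 1L] %in% residues && !(ch[p] %in% blocked)
    }
  }
  ncuts <- c(0L, cumsum(cut))          # ncuts[p + 1] = cuts at positions <= p
  peps <- character(0)
  for (s in seq_len(n)) {
    s_ok <- s == 1L || cut[s - 1L] ||
      (met_excision && s == 2L && ch[1L] == "M")
    if (!s_ok) next
    for (e in s:n) {
      len <- e - s + 1L
      if (len > max_len) break
      if (len < min_len) next
      if (!(e == n || cut[e])) next
      internal <- ncuts[e] - ncuts[s]  # cuts at positions s..e-1
      if (internal > max_missed) next
      pep <- substr(sequence, s, e)
      if (grepl("[XUBZ]", pep)) next
      peps <- c(peps, pep)
    }
  }
  if (il) peps <- chartr("I", "L", peps)
  sort(unique(peps))
}

oracle_params_pairs <- function(params) {
  # translate a digest_params object into oracle arguments
  list(min_len = params$min_len, max_len = params$max_len,
       residues = params$protease$residues, blocked = params$protease$blocked,
       side = params$protease$side, max_missed = params$max_missed_cleavages,
       met_excision = params$nterm_met_excision, il = params$il_equivalence)
}

digest_matches_oracle <- function(sequence, params) {
  got <- sort(digest_protein(sequence, params)$peptide)
  want <- do.call(oracle_digest, c(list(sequence), oracle_params_pairs(params)))
  identical(got, want)
}

random_protein <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                           p_noncanonical = 0) {
  ch <- sample(alphabet, len, replace = TRUE)
  if (p_noncanonical > 0) {
    flip <- stats::runif(len) < p_noncanonical
    ch[flip] <- sample(c("X", "U", "B", "Z"), sum(flip), replace = TRUE)
  }
  paste(ch, collapse = "")
}

random_digest_params <- function() {
  min_len <- sample(3:8, 1L)
  digest_params(
    min_len = min_len,
    max_len = min_len + sample(10:40, 1L),
    protease = sample(c("trypsin/p", "trypsin", "lys-c"), 1L),
    max_missed_cleavages = sample(0:3, 1L),
    nterm_met_excision = sample(c(TRUE, FALSE), 1L),
    il_equivalence = sample(c(TRUE, FALSE), 1L))
}

# hand-written 5-node taxdump fixture:
# root(1) <- Bacteria(2, superkingdom) <- Examplea(21, genus)
#   <- Examplea prima(201, species), Examplea secunda(202, species)
write_tiny_taxdump <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- c("1\t|\t1\t|\tno rank\t|",
             "2\t|\t1\t|\tsuperkingdom\t|",
             "21\t|\t2\t|\tgenus\t|",
             "201\t|\t21\t|\tspecies\t|",
             "202\t|\t21\t|\tspecies\t|")
  names_ <- c("1\t|\troot\t|\t\t|\tscientific name\t|",
              "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
              "2\t|\tbacteria\t|\t\t|\tblast name\t|",
              "21\t|\tExamplea\t|\t\t|\tscientific name\t|",
              "201\t|\tExamplea prima\t|\t\t|\tscientific name\t|",
              "202\t|\tExamplea secunda\t|\t\t|\tscientific name\t|")
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  writeLines(nodes, nodes_path)
  writeLines(names_, names_path)
  list(nodes_path = nodes_path, names_path = names_path)
}

local_pcdb <- function(records, params = digest_params(), workers = 1L,
                       env = parent.frame()) {
  path <- tempfile(fileext = ".pcdb")
  h <- index_pcdb(create_pcdb(records, params, path, workers = workers))
  withr::defer({close_pcdb(h); unlink(path)}, envir = env)
  h
}
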