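# Shared small fixture: 2 genera x 2 species x 3 proteins + 1 homolog pair
pcdb_fixture <- local({
  spec <- fixture_spec(seed = 101, n_genera = 2, species_per_genus = 2,
                       proteins_per_species = 3, homolog_pairs = 1,
                       shared_fraction = 0.4)
  dir <- tempfile()
  tax <- make_taxonomy(spec, dir)
  prot <- make_proteomes(spec, dir)
  list(spec = spec, tax = tax, prot = prot)
})

test_that("Reference row count equals the brute-force digestion census", {
  prot <- pcdb_fixture$prot
  h <- local_pcdb(prot$records)
  oracle_total <- sum(vapply(prot$records$sequence, function(s)
    length(oracle_digest(s)), 1L))
  got <- DBI::dbGetQuery(h$con, "SELECT COUNT(*) AS n FROM Reference")$n
  expect_equal(got, oracle_total)
  # referential integrity: every Reference row points at a MainData protein
  orphans <- DBI::dbGetQuery(h$con,
    "SELECT COUNT(*) AS n FROM Reference r
      LEFT JOIN MainData m ON r.ProteinKey = m.ProteinKey
      WHERE m.ProteinKey IS NULL")$n
  expect_equal(orphans, 0L)
})

test_that("stored DBParams reproduce the build parameters and drive queries", {
  prot <- pcdb_fixture$prot
  params <- digest_params(min_len = 6, max_len = 30, protease = "trypsin",
                          max_missed_cleavages = 1,
                          nterm_met_excision = FALSE, il_equivalence = FALSE)
  h <- local_pcdb(prot$records, params)
  stored <- pcdb_params(h)
  expect_equal(stored$min_len, 6L)
  expect_equal(stored$max_len, 30L)
  expect_equal(stored$protease$name, "trypsin")
  expect_equal(stored$max_missed_cleavages, 1L)
  expect_false(stored$nterm_met_excision)
  expect_false(stored$il_equivalence)
  # reopening reads the same parameters back from disk
  h2 <- open_pcdb(h$path)
  expect_equal(pcdb_params(h2), stored)
  close_pcdb(h2)
})

test_that("planted peptides query back to their parent records; absent ones do not", {
  prot <- pcdb_fixture$prot
  h <- local_pcdb(prot$records)
  man <- prot$manifest

  # a peptide unique to one protein
  uniq <- man[!man$homolog_shared, ][1, ]
  got <- query_peptide(h, uniq$peptide)
  expect_equal(nrow(got), 1L)
  expect_equal(got$accession, uniq$accession)
  expect_equal(got$taxon_id, uniq$taxon_id)
  expect_equal(got$gene, uniq$gene)

  # a homolog-shared peptide returns both parent records
  shared <- man[man$homolog_shared, ]
  sp <- shared$peptide[1]
  got2 <- query_peptide(h, sp)
  expect_setequal(got2$accession, shared$accession[shared$peptide == sp])

  # canonicalization symmetry: querying with I where the database stores L
  with_i <- sub("L", "I", uniq$peptide)
  expect_equal(query_peptide(h, with_i)$accession, uniq$accession)

  # negative controls: random absent 12-mers return empty
  set.seed(77)
  absent <- vapply(1:300, function(i)
    paste(sample(strsplit("ACDEFGHLNPQSTVWY", "")[[1L]], 12, replace = TRUE),
          collapse = ""), "")
  absent <- setdiff(absent, man$peptide)
  for (a in absent[1:100]) expect_equal(nrow(query_peptide(h, a)), 0L)

  # out-of-bounds query length: empty result, not an error
  expect_equal(nrow(query_peptide(h, "AK")), 0L)
})

test_that("build refuses to clobber, errors on empty input, and removes partial files", {
  prot <- pcdb_fixture$prot
  path <- tempfile(fileext = ".pcdb")
  h <- create_pcdb(prot$records, digest_params(), path)
  close_pcdb(h)
  expect_error(create_pcdb(prot$records, digest_params(), path), "overwrite")
  h2 <- create_pcdb(prot$records, digest_params(), path, overwrite = TRUE)
  close_pcdb(h2)
  unlink(path)

  expect_error(create_pcdb(prot$records[0, ], digest_params(), tempfile()),
               "non-empty")
})

test_that("indexing is a separate, flagged, idempotent step", {
  prot <- pcdb_fixture$prot
  path <- tempfile(fileext = ".pcdb")
  h <- create_pcdb(prot$records, digest_params(), path)
  expect_identical(h$meta[["indexed"]], "0")
  index_pcdb(h)
  expect_identical(h$meta[["indexed"]], "1")
  idx_count <- function()
    nrow(DBI::dbGetQuery(h$con,
      "SELECT name FROM sqlite_master WHERE type='index' AND tbl_name='Reference'"))
  n1 <- idx_count()
  index_pcdb(h)                       # no-op
  expect_equal(idx_count(), n1)
  close_pcdb(h)
  unlink(path)

  expect_error(open_pcdb(tempfile()), "no PCDB")
  bad <- tempfile()
  writeLines("not a database", bad)
  expect_error(open_pcdb(bad), "integrity")
})

test_that("worker count does not change queryable content", {
  prot <- pcdb_fixture$prot
  h1 <- local_pcdb(prot$records, workers = 1L)
  h4 <- local_pcdb(prot$records, workers = 4L)
  dump <- function(h) DBI::dbGetQuery(h$con,
    "SELECT CAST(HashPeptide AS TEXT) AS hp, ProteinKey FROM Reference
     ORDER BY HashPeptide, ProteinKey")
  expect_equal(dump(h1), dump(h4))
})

test_that("every digestion product round-trips through query with its parent among hits", {
  prot <- pcdb_fixture$prot
  h <- local_pcdb(prot$records)
  sample_rows <- prot$manifest[seq(1, nrow(prot$manifest), by = 7), ]
  for (i in seq_len(nrow(sample_rows))) {
    got <- query_peptide(h, sample_rows$peptide[i])
    expect_true(sample_rows$accession[i] %in% got$accession)
    # no hit lacks the peptide as a literal boundary-valid substring
    for (j in seq_len(nrow(got))) {
      parent <- prot$records$sequence[prot$records$accession == got$accession[j]]
      expect_true(peptide_occurs_in(parent, sample_rows$peptide[i], h$params))
    }
  }
})
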