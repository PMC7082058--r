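denovo_fixture <- local({
  spec <- fixture_spec(seed = 303, n_genera = 3, species_per_genus = 1,
                       proteins_per_species = 4, homolog_pairs = 0,
                       planted_unique_peptides = 10, noise_rate = 0.2)
  dir <- tempfile()
  tax <- make_taxonomy(spec, dir)
  idx <- load_taxdump(tax$nodes_path, tax$names_path)
  prot <- make_proteomes(spec, dir)
  dn <- make_denovo_candidates(spec, prot, dir, true_rank = 2)
  list(spec = spec, idx = idx, prot = prot, dn = dn)
})

test_that("candidate CSVs group by spectrum with stable descending-ALC order", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Scan,Peptide,ALC (%)",
               "s1,AAAAAAAK,80",
               "s1,CCCCCCCK,95",
               "s2,DDDDDDDK,70",
               "s1,EEEEEEEK,80"), f)
  cand <- read_candidates(f)
  expect_equal(cand$peptide[cand$spectrum == "s1"],
               c("CCCCCCCK", "AAAAAAAK", "EEEEEEEK"))   # tie keeps input order
  expect_equal(cand$cand_rank[cand$spectrum == "s1"], 1:3)
  expect_equal(sum(cand$spectrum == "s2"), 1L)

  # empty file with header; out-of-range ALC rejected with a warning
  f2 <- tempfile(fileext = ".csv")
  writeLines("Scan,Peptide,ALC (%)", f2)
  expect_equal(nrow(read_candidates(f2)), 0L)
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("Scan,Peptide,ALC (%)", "s1,AAAAAAAK,150", "s1,CCCCCCCK,60"), f3)
  expect_warning(c3 <- read_candidates(f3), "ALC")
  expect_equal(nrow(c3), 1L)
  expect_error(read_candidates(f2, alc_col = "Missing"), "schema")
})

test_that("database-constrained matching accepts the best matching candidate; top-candidate only rank 1", {
  fx <- denovo_fixture
  h <- local_pcdb(fx$prot$records)
  man <- fx$prot$manifest
  true_pep <- man$peptide[1]
  other_pep <- man$peptide[8]
  f <- tempfile(fileext = ".csv")
  writeLines(c("Scan,Peptide,ALC (%)",
               sprintf("s1,%s,90", paste(rev(strsplit(true_pep, "")[[1]]),
                                         collapse = "")),  # rank 1: decoy-like noise
               sprintf("s1,%s,80", true_pep),               # rank 2: real peptide
               "s2,WWWWWWWK,85",
               sprintf("s3,%s,88", other_pep)), f)
  cand <- read_candidates(f)

  dbc <- constrain_to_db(cand, h, denovo_params(mode = "database_constrained"))
  top <- constrain_to_db(cand, h, denovo_params(mode = "top_candidate"))
  # spectrum s1: rank-2 candidate accepted only in database-constrained mode
  expect_equal(dbc$accepted$peptide[dbc$accepted$spectrum == "s1"], true_pep)
  expect_false("s1" %in% top$accepted$spectrum)
  # spectrum s2 matches nothing in either mode
  expect_false("s2" %in% dbc$accepted$spectrum)
  # spectrum s3: rank-1 match accepted identically in both modes
  expect_equal(dbc$accepted$peptide[dbc$accepted$spectrum == "s3"],
               top$accepted$peptide[top$accepted$spectrum == "s3"])
  # the mode inequality holds by construction
  expect_gte(nrow(dbc$accepted), nrow(top$accepted))

  # ALC floor is applied before matching
  strict <- constrain_to_db(cand, h, denovo_params(min_alc = 85))
  expect_false("s1" %in% strict$accepted$spectrum)
})

test_that("genus-unique spectral counting collapses modifications and applies thresholds", {
  fx <- denovo_fixture
  h <- local_pcdb(fx$prot$records)
  man <- fx$prot$manifest
  p1 <- man$peptide[1]                       # genus 1, observed modified + plain
  p2 <- man$peptide[man$genus_id == 12][1]   # genus 2, observed once
  mod1 <- paste0(substr(p1, 1, 1), "(+57.02)", substr(p1, 2, nchar(p1)))
  f <- tempfile(fileext = ".csv")
  writeLines(c("Scan,Peptide,ALC (%)",
               sprintf("s1,%s,90", p1),
               sprintf("s2,%s,85", mod1),
               sprintf("s3,%s,90", p2)), f)
  res <- constrain_to_db(read_candidates(f), h)
  counts <- genus_unique_counts(res, fx$idx)
  # modified and unmodified observations pool to 2 spectra -> retained
  expect_equal(counts$genus, "Genus01")
  expect_equal(counts$spectral_counts, 2L)
  expect_equal(counts$n_peptides, 1L)
  # single observation fails the default 2-spectrum floor
  expect_false("Genus02" %in% counts$genus)
  # with floor 1 both genera appear
  c1 <- genus_unique_counts(res, fx$idx, denovo_params(min_spectral_counts = 1))
  expect_setequal(c1$genus, c("Genus01", "Genus02"))

  # the taxon allowlist removes non-listed clades
  c_none <- genus_unique_counts(res, fx$idx,
                                denovo_params(min_spectral_counts = 1),
                                allow = list(superkingdoms = "Archaea",
                                             species = character(0)))
  expect_equal(nrow(c_none), 0L)
})

test_that("peptides hitting multiple genera are excluded from genus counts", {
  spec <- fixture_spec(seed = 404, n_genera = 2, species_per_genus = 1,
                       proteins_per_species = 2, homolog_pairs = 1,
                       shared_fraction = 0.4)
  dir <- tempfile()
  tax <- make_taxonomy(spec, dir)
  idx <- load_taxdump(tax$nodes_path, tax$names_path)
  prot <- make_proteomes(spec, dir)
  h <- local_pcdb(prot$records)
  shared_pep <- prot$manifest$peptide[prot$manifest$homolog_shared][1]
  f <- tempfile(fileext = ".csv")
  writeLines(c("Scan,Peptide,ALC (%)",
               sprintf("s1,%s,90", shared_pep),
               sprintf("s2,%s,88", shared_pep)), f)
  res <- constrain_to_db(read_candidates(f), h)
  expect_equal(nrow(res$accepted), 2L)             # matched fine...
  counts <- genus_unique_counts(res, idx)
  expect_equal(nrow(counts), 0L)                   # ...but never genus-unique
})

test_that("decoy delta ranks genera and applies the acceptance threshold", {
  fwd <- data.frame(genus = c("A", "B", "C"), n_peptides = c(12L, 5L, 8L),
                    spectral_counts = c(30L, 9L, 20L))
  rev_ <- data.frame(genus = c("A", "B", "D"), n_peptides = c(2L, 5L, 1L),
                     spectral_counts = c(3L, 9L, 2L))
  dd <- decoy_delta(fwd, rev_)
  expect_equal(dd$genus, c("A", "C", "B", "D"))    # sorted by delta
  expect_equal(dd$delta, c(10L, 8L, 0L, -1L))
  expect_equal(dd$accepted, c(TRUE, TRUE, FALSE, FALSE))
  # absent-from-forward genus counts 0 forward
  expect_equal(dd$forward[dd$genus == "D"], 0L)
  # spectral-count measure is selectable
  dd2 <- decoy_delta(fwd, rev_, measure = "spectra")
  expect_equal(dd2$delta[dd2$genus == "A"], 27L)
})

test_that("the full pipeline recovers planted genera and rejects reversed noise", {
  fx <- denovo_fixture
  h <- local_pcdb(fx$prot$records)
  hrev <- local_pcdb(reverse_decoy(fx$prot$records))
  cand <- read_candidates(fx$dn$path)
  res <- denovo_genus_report(cand, h, hrev, fx$idx)
  planted <- sort(unique(fx$dn$truth$genus_name[!is.na(fx$dn$truth$genus_name)]))
  expect_setequal(res$report$genus[res$report$accepted], planted)
  expect_true(all(res$report$reverse == 0L))
  # database-constrained acceptance dominates top-candidate acceptance
  n_dbc <- nrow(constrain_to_db(cand, h,
                                denovo_params(mode = "database_constrained"))$accepted)
  n_top <- nrow(constrain_to_db(cand, h,
                                denovo_params(mode = "top_candidate"))$accepted)
  expect_gte(n_dbc, n_top)
  # with true peptides planted at rank 2, the gain is strict
  expect_gt(n_dbc, n_top)
})
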