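# Fixture world shared by the annotation tests: two genera, one homolog pair
# (so one gene has cross-genus shared peptides), plus search results
annot_fixture <- local({
  spec <- fixture_spec(seed = 202, n_genera = 2, species_per_genus = 1,
                       proteins_per_species = 4, homolog_pairs = 1,
                       shared_fraction = 0.4, quant_channels = 3,
                       noise_rate = 0.1)
  dir <- tempfile()
  tax <- make_taxonomy(spec, dir)
  idx <- load_taxdump(tax$nodes_path, tax$names_path)
  prot <- make_proteomes(spec, dir)
  sr <- make_search_results(spec, prot, dir, n_rows = 80)
  list(spec = spec, idx = idx, prot = prot, sr = sr)
})

test_that("annotation assigns taxa, flags uniqueness, and keeps unmatched rows", {
  fx <- annot_fixture
  h <- local_pcdb(fx$prot$records)
  man <- fx$prot$manifest
  uniq_a <- man[!man$homolog_shared & man$genus_id == 11, ][1, ]
  uniq_b <- man[!man$homolog_shared & man$genus_id == 12, ][1, ]
  shared <- man[man$homolog_shared, ][1, ]
  tab <- data.frame(Sequence = c(uniq_a$peptide, uniq_b$peptide,
                                 shared$peptide),
                    check.names = FALSE)
  ann <- annotate_peptides(tab, h, fx$idx, ranks = c("species", "genus"))
  expect_equal(ann$unique_species, c(TRUE, TRUE, FALSE))
  expect_equal(ann$unique_genus, c(TRUE, TRUE, FALSE))
  expect_equal(ann$taxa_species[1], uniq_a$species_name)
  expect_setequal(strsplit(ann$taxa_genus[3], ";")[[1]],
                  c("Genus01", "Genus02"))
  expect_true(all(ann$matched))

  # I-spelled query still matches the L-canonical database
  tab_i <- data.frame(Sequence = sub("L", "I", uniq_a$peptide))
  ann_i <- annotate_peptides(tab_i, h, fx$idx, "species")
  expect_true(ann_i$matched)

  # empty table and schema errors
  expect_equal(nrow(annotate_peptides(tab[0, , drop = FALSE], h, fx$idx,
                                      "species")), 0L)
  expect_error(annotate_peptides(data.frame(pep = "AAA"), h, fx$idx, "species"),
               "Sequence")
})

test_that("annotation agrees with a linear-scan oracle over a fixture table", {
  fx <- annot_fixture
  h <- local_pcdb(fx$prot$records)
  ann <- annotate_peptides(fx$sr$table, h, fx$idx, "species")
  for (i in seq_len(nrow(ann))) {
    pep <- ann$stripped_sequence[i]
    oracle_hits <- fx$prot$records$accession[vapply(
      fx$prot$records$sequence, peptide_occurs_in, TRUE,
      canonical_peptide = pep, params = h$params)]
    expect_setequal(ann$hits[[i]]$accession, oracle_hits)
  }
  # contaminant rows are flagged unmatched, never dropped
  cont <- fx$sr$row_truth$is_contaminant
  expect_equal(ann$matched, !cont)
  expect_equal(nrow(ann), nrow(fx$sr$table))
  # quant columns pass through untouched
  expect_equal(as.data.frame(ann)[fx$sr$quant_columns],
               fx$sr$table[fx$sr$quant_columns])
})

test_that("unique-only filtering is a subset of default-taxon filtering, and shared peptides flip", {
  fx <- annot_fixture
  h <- local_pcdb(fx$prot$records)
  ann <- annotate_peptides(fx$sr$table, h, fx$idx, c("species", "genus"))
  sp_a <- "Genus01 sp01"; sp_b <- "Genus02 sp01"

  m1 <- apply_taxon_filter(ann, taxon_filter("species", default_taxon = sp_a))
  m2 <- apply_taxon_filter(ann, taxon_filter("species", include = sp_a,
                                             require_unique = TRUE))
  # method 2 rows are exactly method 1 minus the shared peptides
  expect_true(all(m2$stripped_sequence %in% m1$stripped_sequence))
  man <- fx$prot$manifest
  shared_set <- unique(man$peptide[man$homolog_shared])
  expect_setequal(setdiff(m1$stripped_sequence, m2$stripped_sequence),
                  intersect(unique(m1$stripped_sequence), shared_set))

  # the same shared peptide is attributed to whichever default is chosen
  shared_pep <- intersect(unique(ann$stripped_sequence), shared_set)[1]
  row_a <- m1[m1$stripped_sequence == shared_pep, ][1, ]
  m1b <- apply_taxon_filter(ann, taxon_filter("species", default_taxon = sp_b))
  row_b <- m1b[m1b$stripped_sequence == shared_pep, ][1, ]
  expect_equal(row_a$assigned_taxon, sp_a)
  expect_equal(row_b$assigned_taxon, sp_b)

  # a unique-to-excluded-taxon peptide is dropped by exclusion
  excl <- apply_taxon_filter(ann, taxon_filter("species", exclude = sp_b))
  expect_false(any(vapply(excl$hits, function(h2)
    all(h2$rank_name_species == sp_b), TRUE)))

  # ambiguous configuration is rejected
  expect_error(taxon_filter("species", include = c(sp_a, sp_b),
                            default_taxon = sp_a, require_unique = TRUE),
               "ambiguous")
  expect_error(taxon_filter("species", include = sp_a, exclude = sp_a),
               "disjoint")
})

test_that("gene rollup is additive, conservative, and drops multi-gene rows", {
  fx <- annot_fixture
  h <- local_pcdb(fx$prot$records)
  ann <- annotate_peptides(fx$sr$table, h, fx$idx, "species")
  flt <- apply_taxon_filter(ann, taxon_filter("species", require_unique = TRUE))
  rolled <- rollup_to_genes(flt, fx$sr$quant_columns)
  # conservation: per-column totals match the retained single-gene rows
  retained <- flt[flt$n_genes == 1L, ]
  for (qc in fx$sr$quant_columns)
    expect_equal(sum(rolled[[qc]]), sum(retained[[qc]]))
  expect_equal(sum(rolled$n_peptides), nrow(retained))
  # two peptides of one gene sum their intensities
  g2 <- rolled$gene[rolled$n_peptides >= 2][1]
  expect_equal(rolled[rolled$gene == g2, fx$sr$quant_columns[1]],
               sum(retained[retained$genes == g2, fx$sr$quant_columns[1]]))
  expect_error(rollup_to_genes(flt, "No such column"), "absent")
})

test_that("rollup of the generated table reproduces the generator's truth totals", {
  fx <- annot_fixture
  h <- local_pcdb(fx$prot$records)
  ann <- annotate_peptides(fx$sr$table, h, fx$idx, "species")
  rolled <- rollup_to_genes(ann[ann$matched, ], fx$sr$quant_columns)
  truth <- fx$sr$gene_totals
  expect_setequal(rolled$gene, rownames(truth))
  for (g in rownames(truth))
    expect_equal(unlist(rolled[rolled$gene == g, fx$sr$quant_columns]),
                 truth[g, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("reference-pool normalization follows the four documented steps exactly", {
  # hand-worked 5-gene, 3-channel example: ratio -> log2 -> median-center ->
  # divide by population SD, computed step by step with plain arithmetic
  tab <- data.frame(gene = paste0("G", 1:5),
                    ref = c(4, 2, 8, 1, 16),
                    s1 = c(8, 2, 4, 4, 16),
                    s2 = c(2, 1, 16, 8, 32))
  manual <- function(x, ref) {
    l <- log2(x / ref)
    l <- l - median(l)
    l / sqrt(mean((l - mean(l))^2))
  }
  nm <- normalize_reference_pool(tab, "ref", channels = c("ref", "s1", "s2"))
  expect_equal(nm$s1, manual(tab$s1, tab$ref))
  expect_equal(nm$s2, manual(tab$s2, tab$ref))
  # reference against itself: all-zero column (SD scaling skipped at SD 0)
  expect_equal(nm$ref, rep(0, 5))
  # contract: median 0, SD 1
  for (ch in c("s1", "s2")) {
    expect_equal(median(nm[[ch]]), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((nm[[ch]] - mean(nm[[ch]]))^2)), 1, tolerance = 1e-9)
  }
  # genes without a positive reference are dropped and counted
  tab$ref[2] <- 0
  nm2 <- normalize_reference_pool(tab, "ref", channels = c("s1", "s2"))
  expect_equal(nrow(nm2), 4L)
  expect_equal(attr(nm2, "dropped_reference"), 1L)
  expect_error(normalize_reference_pool(tab[1:2, ], "ref"), "fewer than 2")
})

test_that("shared peptidome fractions recover engineered homolog designs", {
  fx <- annot_fixture
  hom <- fx$prot$homologs
  recs <- fx$prot$records
  a <- recs[recs$accession == hom$accession_a, ]
  b <- recs[recs$accession == hom$accession_b, ]
  res <- shared_peptidome_fraction(a, b)
  expect_equal(res$fraction_shared, hom$designed_fraction)

  # identical pair -> 1; fully divergent pair -> 0, flagged
  res1 <- shared_peptidome_fraction(a, a)
  expect_equal(res1$fraction_shared, 1)
  c_ <- recs[3, ]; c_$gene <- a$gene
  res0 <- shared_peptidome_fraction(a, c_)
  expect_equal(res0$fraction_shared, 0)
  d <- recs[4, ]                       # different gene symbol: computed vs empty set
  resx <- shared_peptidome_fraction(a, d)
  expect_equal(resx$fraction_shared, 0)
  expect_false(resx$gene_in_b)
  expect_equal(attr(res1, "fraction_genes_shared"), 1)
})

test_that("genus peptidome stats tally unique and shared peptides correctly", {
  fx <- annot_fixture
  h <- local_pcdb(fx$prot$records)
  st <- genus_peptidome_stats(h, fx$idx)
  man <- fx$prot$manifest
  # construction truth: peptides per genus, shared = homolog-shared ones
  for (g in c("Genus01", "Genus02")) {
    man_g <- man[man$genus_name == g, ]
    expect_equal(st$total_peptides[st$genus == g],
                 length(unique(man_g$peptide)))
    expect_equal(st$unique_peptides[st$genus == g],
                 length(unique(man_g$peptide[!man_g$homolog_shared])))
  }
  # partition bound: unique counts never exceed the distinct peptide count
  expect_lte(sum(st$unique_peptides), length(unique(man$peptide)))

  # single-genus database: everything unique, nothing shared
  solo <- fx$prot$records[fx$prot$records$taxon_id == 101, ]
  h1 <- local_pcdb(solo)
  st1 <- genus_peptidome_stats(h1, fx$idx)
  expect_equal(nrow(st1), 1L)
  expect_equal(st1$fraction_shared, 0)
  expect_equal(st1$unique_peptides, st1$total_peptides)
})
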