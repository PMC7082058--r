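# taxopep

Taxon-specific peptide databases and quantitation for multi-species
proteomics in R.

## The problem

Bottom-up proteomics of samples containing more than one organism — a
patient-derived xenograft (human tumor in mouse stroma), an oral-microbiome
swab, any metaproteome — identifies *peptides*, and many peptide sequences
are shared between related organisms. A human tryptic peptide is very often
identical to its murine homolog, so summing peptide intensities to genes
without asking *which organism a peptide can actually come from* biases the
quantitation of both. At the metaproteomic end the problem inverts: with
thousands of candidate organisms one needs to know which peptides are
*unique* to a genus before claiming the genus is present.

`taxopep` addresses both ends with one primitive: a **peptide-to-taxon
database** (PCDB) built by in-silico digestion of reference proteomes. Every
protein in a FASTA collection (UniProt-style headers carrying `OX=` organism
IDs and `GN=` gene symbols) is digested under configurable rules — protease
(trypsin/p by default: cleavage C-terminal to K/R, proline allowed), peptide
length 7–55, up to 2 missed cleavages, N-terminal Met excision, I/L
equivalence — and each canonical peptide is stored as a 64-bit FNV-1a hash
in a single-file SQLite database with three relations:

    MainData  (ProteinKey, Accession, Sequence, TaxonID, Gene)
    Reference (HashPeptide*, ProteinKey)        * indexed in a separate step
    DBParams  (Param, Value)                      build parameters, authoritative

Hashing compresses storage; a hash hit is always verified against the stored
parent sequence (substring + cleavage-boundary check), so queries are
collision-safe. Observed peptides are modification-stripped and
canonicalized (I→L) with the *stored* build parameters before lookup, and an
NCBI-taxdump taxonomy index resolves each hit to requested ranks (species,
genus, superkingdom, …) in memory.

On top of the PCDB:

* **Mixed-species quantitation** — annotate a search-engine peptide table
  (MaxQuant `peptides.txt` dialect), filter by taxon specificity (either
  "assume one organism" with a default taxon, or strict taxon-unique
  peptides), sum quant columns to gene symbols, and normalize against an
  internal reference-pool channel (ratio → log2 → median-center → divide by
  per-channel SD).
* **Peptidome sharing** — per-gene fraction of one proteome's tryptic
  peptides present in another (homolog interference), and per-genus
  unique/shared peptide tallies over a whole database (database
  representation bias).
* **Database-constrained de novo** — for each MS/MS spectrum, walk the
  de-novo candidates (PEAKS `all de novo candidates.csv` dialect,
  ALC ≥ 50) in descending confidence until one matches the database; pool
  modified/unmodified forms for spectral counting; keep genus-unique
  peptides with ≥ 2 spectra; and control false genus discovery with a
  reversed-protein decoy database: rank genera by Δ = forward − reverse
  counts and accept those with Δ > 7.

Synthetic fixture generators (`fixture_spec()`, `make_taxonomy()`,
`make_proteomes()`, `make_search_results()`, `make_denovo_candidates()`)
produce deterministic toy worlds — fragment-built proteins with exactly
engineered homolog sharing and ground-truth manifests — so the entire
pipeline is testable offline.

## Worked example

```r
library(taxopep)

spec <- fixture_spec(seed = 42)               # 3 genera x 2 species + homolog pairs
dir  <- tempfile()
tax  <- make_taxonomy(spec, dir)
idx  <- load_taxdump(tax$nodes_path, tax$names_path)
prot <- make_proteomes(spec, dir)

db <- index_pcdb(create_pcdb(prot$records, digest_params(),
                             file.path(dir, "demo.pcdb")))
db
#> PCDB at .../demo.pcdb
#>   proteins: 32
#>   peptide incidences: 480
#>   indexed: TRUE
#>   protease: trypsin/p

# a homolog-shared peptide hits both parent genes' records
query_peptide(db, prot$manifest$peptide[prot$manifest$homolog_shared][1])
#>      peptide accession taxon_id  gene
#> 1 LEFCFPLLTK    HOMA01      101 HOM01
#> 2 LEFCFPLLTK    HOMB01      103 HOM01

sr  <- make_search_results(spec, prot, dir)
ann <- annotate_peptides(sr$table, db, idx, ranks = c("species", "genus"))
sum(ann$matched)          # 96 of 120 rows match (the rest are contaminants)
sum(ann$unique_species)   # 92 are species-unique

flt    <- apply_taxon_filter(ann, taxon_filter("species", require_unique = TRUE))
genes  <- rollup_to_genes(flt, sr$quant_columns)
normed <- normalize_reference_pool(genes, sr$reference_channel)
head(normed[, 1:5], 3)
#>        gene n_peptides Reporter intensity 1 Reporter intensity 2 Reporter intensity 3
#> 1 GEN101X03          2                    0                0.000               -0.585
#> 2 GEN101X04          1                    0               -0.598               -0.940
#> 3 GEN101X05          7                    0                0.855               -0.622
```

The reference channel (1) is identically 0 after ratioing against itself;
every other channel has median 0 and SD 1 by construction. The shared
peptide above is exactly why `require_unique = TRUE` matters: without it,
its intensity would be credited to whichever single organism the analyst
assumed.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "taxopep", package = "taxopep")`, with subcommands
`fetch`, `build-db`, `decoy-db`, `index-db`, `annotate`, `rollup`,
`denovo`, `peptidome-stats`, and `fixtures`; every run writes a
`<output>.config.json` provenance record with its resolved parameters.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on the seeded synthetic world —
taxonomy, proteomes, forward and reversed-decoy PCDBs, annotation,
species-unique gene rollup with reference-pool normalization, homolog
shared-peptidome fraction, genus peptidome statistics, and the
database-constrained de novo genus report — prints a one-line summary, and
writes the results JSON to `--out`.
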