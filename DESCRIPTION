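Package: taxopep
Title: Taxon-Specific Peptide Databases and Quantitation for Multi-Species Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds customizable, in-silico digested peptide-to-taxon databases
    from reference proteomes and uses them for taxon-specific peptide annotation
    of bottom-up proteomics experiments. Protein FASTA collections with
    UniProt-style headers are digested with configurable protease rules
    (missed cleavages, N-terminal methionine excision, isoleucine/leucine
    equivalence) and stored as hashed 64-bit integers in a single-file SQLite
    database mapping peptides to proteins, organisms, and gene symbols.
    Supports species-specific filtering and gene-level quantitative rollup for
    mixed-species designs such as patient-derived xenografts, genus-level
    peptidome sharing statistics, and a database-constrained de novo workflow
    with reversed-sequence decoy control of genus-level false discovery.
    Includes deterministic synthetic fixture generators (taxonomies, homolog
    proteomes, search results, de novo candidate tables) so the full pipeline
    is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    DBI,
    RSQLite,
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
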