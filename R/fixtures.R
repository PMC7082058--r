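# Deterministic synthetic fixture generators: toy taxonomies, homolog-bearing
# proteomes built from K/R-terminated fragments, search-result tables, and
# de novo candidate sets. Every generator is a pure function of its spec
# (seeded; global RNG state is saved and restored), and each emits a manifest
# that downstream tests can use as ground truth without touching the pipeline
# under test.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic fixture specification
#'
#' The single knob set shared by all generators. Defaults describe a small
#' but structurally complete world: a bacterial superkingdom with a few
#' genera and species, fragment-built proteins whose tryptic structure is
#' controlled by construction, homolog pairs engineered to share an exact
#' fraction of their tryptic peptides (emulating cross-species homology such
#' as human/mouse gene pairs), TMT-style reporter channels with channel 1 as
#' the internal reference pool, and a configurable fraction of noise.
#'
#' @param seed RNG seed; the same seed yields byte-identical outputs.
#' @param n_genera number of genera (default 3).
#' @param species_per_genus species per genus (default 2).
#' @param proteins_per_species proteins per species (default 5).
#' @param fragments_per_protein tryptic fragments per protein (default 6;
#'   fragment lengths are 7--12 residues, so proteins span roughly 42--72
#'   residues and every fragment is itself a valid default-length peptide).
#' @param homolog_pairs number of cross-genus homolog gene pairs (default 2).
#' @param shared_fraction target shared-peptide fraction for homolog pairs
#'   under the default digest (default 0.4; engineered exactly, see
#'   \code{\link{make_proteomes}}).
#' @param planted_unique_peptides genus-unique peptides planted per genus in
#'   the de novo candidate generator (default 12: comfortably above the
#'   default decoy-delta threshold of 7).
#' @param quant_channels reporter channels in search results (default 6,
#'   TMT 6-plex-like; channel 1 is the reference pool).
#' @param noise_rate fraction of contaminant/noise rows or spectra
#'   (default 0.2).
#' @param include_human also plant a human clade (Eukaryota / Homo /
#'   Homo sapiens, IDs 3 / 9605 / 9606) in the taxonomy (default
#'   \code{FALSE}).
#' @return a \code{fixture_spec} object.
#' @export
fixture_spec <- function(seed = 1L, n_genera = 3L, species_per_genus = 2L,
                         proteins_per_species = 5L,
                         fragments_per_protein = 6L,
                         homolog_pairs = 2L, shared_fraction = 0.4,
                         planted_unique_peptides = 12L,
                         quant_channels = 6L, noise_rate = 0.2,
                         include_human = FALSE) {
  stopifnot(n_genera >= 1L, species_per_genus >= 1L,
            proteins_per_species >= 1L, fragments_per_protein >= 2L,
            homolog_pairs >= 0L, shared_fraction >= 0, shared_fraction <= 1,
            quant_channels >= 1L, noise_rate >= 0, noise_rate <= 1)
  structure(list(seed = as.integer(seed), n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 proteins_per_species = as.integer(proteins_per_species),
                 fragments_per_protein = as.integer(fragments_per_protein),
                 homolog_pairs = as.integer(homolog_pairs),
                 shared_fraction = shared_fraction,
                 planted_unique_peptides = as.integer(planted_unique_peptides),
                 quant_channels = as.integer(quant_channels),
                 noise_rate = noise_rate,
                 include_human = isTRUE(include_human)),
            class = "fixture_spec")
}

.fixture_species_id <- function(spec, g, s) 100L + (g - 1L) * spec$species_per_genus + s
.fixture_genus_id <- function(g) 10L + g

#' Generate a toy taxonomy in the taxdump dialect
#'
#' Writes \code{nodes.dmp} and \code{names.dmp} for a rooted tree
#' root(1) -> superkingdom Bacteria(2) -> genera -> species, with dense
#' deterministic IDs (genus g is \code{10+g}; species (g, s) is
#' \code{100 + (g-1)*S + s}). With \code{include_human}, a parallel
#' Eukaryota(3) / Homo(9605) / Homo sapiens(9606) chain is added.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param dir output directory (created if needed).
#' @return list with \code{nodes_path}, \code{names_path} and a \code{taxa}
#'   data frame (\code{taxon_id}, \code{parent}, \code{rank}, \code{name}).
#' @export
make_taxonomy <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  taxa <- data.frame(taxon_id = 1L, parent = 1L, rank = "no rank",
                     name = "root", stringsAsFactors = FALSE)
  taxa <- rbind(taxa, data.frame(taxon_id = 2L, parent = 1L,
                                 rank = "superkingdom", name = "Bacteria"))
  for (g in seq_len(spec$n_genera)) {
    gid <- .fixture_genus_id(g)
    gname <- sprintf("Genus%02d", g)
    taxa <- rbind(taxa, data.frame(taxon_id = gid, parent = 2L,
                                   rank = "genus", name = gname))
    for (s in seq_len(spec$species_per_genus)) {
      taxa <- rbind(taxa, data.frame(
        taxon_id = .fixture_species_id(spec, g, s), parent = gid,
        rank = "species", name = sprintf("%s sp%02d", gname, s)))
    }
  }
  if (spec$include_human) {
    taxa <- rbind(taxa,
      data.frame(taxon_id = 3L, parent = 1L, rank = "superkingdom",
                 name = "Eukaryota"),
      data.frame(taxon_id = 9605L, parent = 3L, rank = "genus", name = "Homo"),
      data.frame(taxon_id = 9606L, parent = 9605L, rank = "species",
                 name = "Homo sapiens"))
  }
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", taxa$taxon_id, taxa$parent,
                     taxa$rank), nodes_path)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", taxa$taxon_id,
                     taxa$name), names_path)
  list(nodes_path = nodes_path, names_path = names_path, taxa = taxa)
}

# globally unique K/R-terminated fragments; interiors avoid K/R (so cleavage
# structure is exactly the fragment structure), I (so canonicalization is the
# identity on fixtures) and non-canonical codes; never start with M (so Met
# excision never fires and the manifest needs no variants). Uniqueness is
# tracked in a hashed environment so generation stays O(1) per fragment at
# the 10^5-protein scale.
.fragment_pool <- function(existing = character(0)) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (x in existing) assign(x, TRUE, envir = env)
  env
}

.make_fragments <- function(n, pool) {
  interior_alphabet <- strsplit("ACDEFGHLNPQSTVWY", "")[[1L]]
  first_alphabet <- setdiff(interior_alphabet, "M")
  out <- character(n)
  got <- 0L
  while (got < n) {
    L <- sample(6:11, 1L)                          # interior length; +1 for K/R
    frag <- paste0(paste(c(sample(first_alphabet, 1L),
                           sample(interior_alphabet, L - 1L, replace = TRUE)),
                         collapse = ""),
                   sample(c("K", "R"), 1L))
    if (is.null(get0(frag, envir = pool, inherits = FALSE))) {
      assign(frag, TRUE, envir = pool)
      got <- got + 1L
      out[got] <- frag
    }
  }
  out
}

# all fragment runs spanning <= mc internal sites: the digestion products of
# a fragment-built protein by construction (each fragment is >= 7 residues
# and runs of <= 3 fragments are <= 36 residues, inside the default bounds)
.runs_of <- function(fragments, mc = 2L) {
  nf <- length(fragments)
  out <- character(0)
  for (k in 0:mc) {
    if (nf - k < 1L) break
    for (i in seq_len(nf - k))
      out <- c(out, paste(fragments[i:(i + k)], collapse = ""))
  }
  out
}

#' Generate a homolog-bearing fixture proteome with a ground-truth manifest
#'
#' Proteins are concatenations of globally unique K/R-terminated fragments,
#' so their digestion products under the default rules are exactly the runs
#' of up to (max missed cleavages + 1) consecutive fragments -- the manifest
#' enumerates them from the construction, independently of the digestion
#' code under test. Homolog pairs are engineered so the shared-peptide
#' fraction under the default digest is \emph{exact}: the pair's second
#' protein reuses k of the first's n fragments in reversed relative order
#' (destroying every shared adjacency), giving a shared fraction of exactly
#' k / (3n - 3) with up to 2 missed cleavages. A target of 1 copies the
#' protein verbatim; a target of 0 shares nothing.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param dir output directory; writes \code{proteome.fasta} and (when
#'   \code{manifest} is \code{TRUE}) \code{manifest.tsv}.
#' @param manifest also enumerate the ground-truth peptide manifest
#'   (default \code{TRUE}; turn off for large engineering-scale fixtures
#'   where only the FASTA is needed).
#' @return list with \code{records} (a \code{\link{protein_records}}
#'   collection), \code{manifest} (data frame: \code{peptide},
#'   \code{accession}, \code{gene}, \code{taxon_id}, \code{genus_id},
#'   \code{genus_name}, \code{species_name}, \code{homolog_shared}; or
#'   \code{NULL}), \code{homologs} (per-pair design: \code{gene},
#'   \code{accession_a}, \code{accession_b}, \code{designed_fraction}) and
#'   \code{fasta_path}, \code{manifest_path}.
#' @export
make_proteomes <- function(spec, dir, manifest = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(spec$seed + 1L, {
    nf <- spec$fragments_per_protein
    n_base <- spec$n_genera * spec$species_per_genus * spec$proteins_per_species
    n_pairs <- if (spec$n_genera >= 2L) spec$homolog_pairs else 0L
    n_prot <- n_base + n_pairs

    acc <- character(n_prot); gene <- character(n_prot)
    taxon <- integer(n_prot); gidx <- integer(n_prot); sidx <- integer(n_prot)
    prot_frag <- vector("list", n_prot)
    pool <- .fragment_pool()

    i <- 0L
    for (g in seq_len(spec$n_genera)) for (s in seq_len(spec$species_per_genus)) {
      sid <- .fixture_species_id(spec, g, s)
      for (p in seq_len(spec$proteins_per_species)) {
        i <- i + 1L
        acc[i] <- sprintf("FX%03d_%02d", sid, p)
        gene[i] <- sprintf("GEN%03dX%02d", sid, p)
        taxon[i] <- sid; gidx[i] <- g; sidx[i] <- s
        prot_frag[[i]] <- .make_fragments(nf, pool)
      }
    }

    # homolog pairs: a protein of species 1 in genus a is re-labelled with a
    # shared gene symbol, and genus b gets a partner protein reusing k of its
    # n fragments in reversed relative order, so the shared tryptic-peptide
    # fraction under the default digest is exactly k / (3n - 3)
    homologs <- data.frame(gene = character(0), accession_a = character(0),
                           accession_b = character(0),
                           designed_fraction = numeric(0),
                           stringsAsFactors = FALSE)
    if (n_pairs > 0L) {
      n_pep <- 3L * nf - 3L                  # runs with <= 2 missed cleavages
      k <- min(as.integer(round(spec$shared_fraction * n_pep)), nf)
      for (h in seq_len(n_pairs)) {
        ga <- 1L + (2L * (h - 1L)) %% spec$n_genera
        gb <- 1L + (2L * (h - 1L) + 1L) %% spec$n_genera
        sa <- .fixture_species_id(spec, ga, 1L)
        sb <- .fixture_species_id(spec, gb, 1L)
        ia <- which(taxon == sa)[min(h, sum(taxon == sa))]
        frags_a <- prot_frag[[ia]]
        frags_b <- if (spec$shared_fraction >= 1) {
          frags_a
        } else if (k == 0L) {
          .make_fragments(nf, pool)
        } else {
          c(rev(frags_a[seq_len(k)]),        # reversed order kills adjacency
            .make_fragments(nf - k, pool))
        }
        hacc_a <- sprintf("HOMA%02d", h); hacc_b <- sprintf("HOMB%02d", h)
        hgene <- sprintf("HOM%02d", h)
        acc[ia] <- hacc_a; gene[ia] <- hgene
        i <- i + 1L
        acc[i] <- hacc_b; gene[i] <- hgene; taxon[i] <- sb
        gidx[i] <- gb; sidx[i] <- 1L
        prot_frag[[i]] <- frags_b
        homologs <- rbind(homologs, data.frame(
          gene = hgene, accession_a = hacc_a, accession_b = hacc_b,
          designed_fraction = if (spec$shared_fraction >= 1) 1 else k / n_pep,
          stringsAsFactors = FALSE))
      }
    }

    sequences <- vapply(prot_frag, paste, "", collapse = "")
    records <- protein_records(acc, gene, taxon, sequences)
    fasta_path <- file.path(dir, "proteome.fasta")
    write_fasta(records, fasta_path)

    man <- NULL
    manifest_path <- NULL
    if (isTRUE(manifest)) {
      pep_list <- lapply(prot_frag, .runs_of)
      npep <- lengths(pep_list)
      idx <- rep.int(seq_len(n_prot), npep)
      man <- data.frame(
        peptide = unlist(pep_list, use.names = FALSE),
        accession = acc[idx], gene = gene[idx], taxon_id = taxon[idx],
        genus_id = .fixture_genus_id(gidx[idx]),
        genus_name = sprintf("Genus%02d", gidx[idx]),
        species_name = sprintf("Genus%02d sp%02d", gidx[idx], sidx[idx]),
        stringsAsFactors = FALSE)
      shared_peps <- man$peptide[duplicated(man$peptide) |
                                 duplicated(man$peptide, fromLast = TRUE)]
      man$homolog_shared <- man$peptide %in% shared_peps
      manifest_path <- file.path(dir, "manifest.tsv")
      utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    list(records = records, manifest = man, homologs = homologs,
         fasta_path = fasta_path, manifest_path = manifest_path)
  })
}

#' Generate a synthetic search-engine peptide table
#'
#' Emits a MaxQuant-peptides.txt-style tab-delimited table: a
#' \code{Sequence} column plus \code{Reporter intensity <c>} channels with
#' log-normal intensities (channel 1 is the internal reference pool). Rows
#' sample true peptides from the proteome manifest; a \code{noise_rate}
#' fraction are contaminant sequences absent from the proteome (they must
#' annotate as unmatched downstream). Ground-truth per-gene totals over
#' single-gene rows are returned alongside.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param proteome a \code{\link{make_proteomes}} result.
#' @param dir output directory; writes \code{search_results.tsv}.
#' @param n_rows number of peptide rows (default 120).
#' @return list with \code{table}, \code{row_truth} (per-row
#'   \code{is_contaminant}, \code{gene} -- \code{NA} when ambiguous),
#'   \code{gene_totals} (true per-gene sums per channel over single-gene
#'   rows), \code{path}, \code{quant_columns}, \code{reference_channel}.
#' @export
make_search_results <- function(spec, proteome, dir, n_rows = 120L) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(spec$seed + 2L, {
    manifest <- proteome$manifest
    if (is.null(manifest))
      stop("proteome was generated without a manifest", call. = FALSE)
    peptide_gene <- tapply(manifest$gene, manifest$peptide,
                           function(g) unique(g))
    pool <- unique(manifest$peptide)
    n_noise <- as.integer(round(n_rows * spec$noise_rate))
    n_true <- n_rows - n_noise
    true_peps <- sample(pool, n_true, replace = TRUE)

    # fragment-shaped strings absent from every protein (the pool is seeded
    # with all true peptides, so contaminants can never match the database)
    contaminants <- if (n_noise > 0L)
      .make_fragments(n_noise, .fragment_pool(pool)) else character(0)
    seqs <- c(true_peps, contaminants)
    is_cont <- c(rep(FALSE, n_true), rep(TRUE, n_noise))

    qcols <- sprintf("Reporter intensity %d", seq_len(spec$quant_channels))
    qm <- matrix(stats::rlnorm(length(seqs) * spec$quant_channels,
                               meanlog = log(1e6), sdlog = 1),
                 nrow = length(seqs))
    tab <- data.frame(Sequence = seqs, check.names = FALSE,
                      stringsAsFactors = FALSE)
    for (j in seq_along(qcols)) tab[[qcols[j]]] <- qm[, j]

    genes <- vapply(seqs, function(p) {
      g <- if (p %in% names(peptide_gene)) peptide_gene[[p]] else NULL
      if (is.null(g) || length(g) != 1L) NA_character_ else g
    }, "")
    row_truth <- data.frame(Sequence = seqs, is_contaminant = is_cont,
                            gene = genes, stringsAsFactors = FALSE,
                            row.names = NULL)
    ok <- !is.na(genes) & !is_cont
    gene_totals <- if (any(ok)) {
      gt <- rowsum(qm[ok, , drop = FALSE], genes[ok])
      colnames(gt) <- qcols
      gt
    } else matrix(numeric(0), 0, spec$quant_channels,
                  dimnames = list(NULL, qcols))

    path <- file.path(dir, "search_results.tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(table = tab, row_truth = row_truth, gene_totals = gene_totals,
         path = path, quant_columns = qcols,
         reference_channel = qcols[1L])
  })
}

#' Generate a synthetic de novo candidate table with known ground truth
#'
#' For each genus, \code{planted_unique_peptides} genus-unique peptides are
#' drawn from the manifest; each is observed in 2--3 spectra (so it clears
#' the default minimum of 2 spectral counts). Every spectrum carries 1--10
#' candidates ordered by ALC: noise candidates (reversed fixture peptides,
#' which cannot be valid digestion products of the forward proteins) above
#' and below the true peptide, which sits at \code{true_rank} with an ALC
#' comfortably over the default floor of 50. Half the true observations
#' carry a PEAKS-style modification tag, exercising modification collapsing.
#' A \code{noise_rate} fraction of extra spectra contain only noise
#' candidates. Truth lists the planted genus per spectrum (\code{NA} for
#' noise spectra).
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param proteome a \code{\link{make_proteomes}} result.
#' @param dir output directory; writes \code{denovo_candidates.csv}.
#' @param true_rank candidate position of the planted peptide within its
#'   spectrum (default 2: the top candidate is noise, so only
#'   database-constrained mode recovers the peptide).
#' @return list with \code{candidates} (data frame in the PEAKS dialect),
#'   \code{truth} (per-spectrum \code{genus_name}, \code{peptide};
#'   \code{NA} for noise spectra), \code{path}.
#' @export
make_denovo_candidates <- function(spec, proteome, dir, true_rank = 2L) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(spec$seed + 3L, {
    manifest <- proteome$manifest
    if (is.null(manifest))
      stop("proteome was generated without a manifest", call. = FALSE)
    # genus-unique single-fragment peptides: not homolog-shared, one parent
    singles <- manifest[!manifest$homolog_shared, , drop = FALSE]
    singles <- singles[!duplicated(singles$peptide), , drop = FALSE]

    rev_str <- function(x) vapply(strsplit(x, "", fixed = TRUE),
                                  function(ch) paste(rev(ch), collapse = ""), "")
    noise_pool <- rev_str(unique(manifest$peptide))

    rows <- list(); truth <- list(); scan <- 0L
    emit_spectrum <- function(true_pep, genus) {
      scan <<- scan + 1L
      n_cand <- sample(3:8, 1L)
      pos <- if (is.na(true_pep)) 0L else min(true_rank, n_cand)
      alcs <- sort(stats::runif(n_cand, 55, 95), decreasing = TRUE)
      peps <- sample(noise_pool, n_cand, replace = TRUE)
      if (pos > 0L) {
        shown <- true_pep
        if (scan %% 2L == 0L)             # exercise modification collapsing
          shown <- paste0(substring(true_pep, 1L, 1L), "(+57.02)",
                          substring(true_pep, 2L))
        peps[pos] <- shown
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        Scan = sprintf("F1:%05d", scan), Peptide = peps, ALC = alcs,
        stringsAsFactors = FALSE, check.names = FALSE)
      truth[[length(truth) + 1L]] <<- data.frame(
        spectrum = sprintf("F1:%05d", scan),
        genus_name = if (is.na(true_pep)) NA_character_ else genus,
        peptide = true_pep, stringsAsFactors = FALSE)
    }

    for (g in seq_len(spec$n_genera)) {
      gname <- sprintf("Genus%02d", g)
      gp <- singles$peptide[singles$genus_name == gname]
      planted <- sample(gp, min(spec$planted_unique_peptides, length(gp)))
      for (p in planted) {
        n_obs <- sample(2:3, 1L)
        for (o in seq_len(n_obs)) emit_spectrum(p, gname)
      }
    }
    n_noise <- as.integer(round(scan * spec$noise_rate))
    for (i in seq_len(n_noise)) emit_spectrum(NA_character_, NA_character_)

    cand <- do.call(rbind, rows)
    names(cand)[names(cand) == "ALC"] <- "ALC (%)"
    truth <- do.call(rbind, truth)
    path <- file.path(dir, "denovo_candidates.csv")
    utils::write.csv(cand, path, row.names = FALSE)
    list(candidates = cand, truth = truth, path = path)
  })
}
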