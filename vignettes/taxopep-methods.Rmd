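---
title: "taxopep: methods, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{taxopep: methods, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxopep)
```

## The model

`taxopep` treats taxon assignment of peptides as a set-membership problem
against an exhaustively pre-digested reference. Given a protein collection
with organism (`OX=`) and gene (`GN=`) annotations, in-silico proteolysis
enumerates every peptide a search engine could in principle report under
the chosen rules, and the database stores the incidence relation
*peptide → {(protein, organism, gene)}*. An observed peptide is then
assigned to the union of taxa of its parents, resolved to any requested
rank through the taxonomy; it is *unique* at a rank when all parents
resolve to a single taxon there. Everything downstream — species-specific
quantitation, genus presence calls from de novo data — reduces to queries
over this relation.

The key assumptions are the digestion model's: cleavage is perfectly
specific (no semi-tryptic or non-specific peptides), missed cleavages are
bounded (default ≤ 2), and the observable peptide universe is bounded in
length (default 7–55 residues, roughly the range detectable and
identifiable by standard LC-MS/MS). Isoleucine and leucine are isobaric
under standard MS2 fragmentation, so sequences are canonicalized I→L
before any comparison; consequently all assignments are made in I/L-blind
sequence space.

## Digestion parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `protease` | `trypsin/p` | cleave C-terminal to K/R including before proline; trypsin in practice cleaves X–P bonds at an appreciable rate, and search engines are typically run with this rule |
| `min_len`, `max_len` | 7, 55 residues | shorter peptides are rarely unique or confidently identified; longer ones are rarely observed |
| `max_missed_cleavages` | 2 | standard search-engine setting; output is monotone in this bound |
| `nterm_met_excision` | on | co-translational initiator-Met removal: every peptide anchored at the protein N-terminus also contributes its Met-less variant, both length-filtered independently |
| `il_equivalence` | on | I→L canonicalization before hashing and before every query |

Built-in proteases: `trypsin/p`, strict `trypsin` (K/R blocked by following
P), `lys-c` (after K), `chymotrypsin` (high-specificity convention: after
F/Y/W unless followed by P), `glu-c` (after D/E, the phosphate-buffer
convention), `asp-n` (before D, an N-side rule). Custom rules supply
cleavage residues, an optional blocking set, and the cleavage side. Cut
positions are reported 1-based (the R convention): the site *after* residue
*i*.

Two conventions are worth stating because alternatives exist:

* **Met excision adds a variant rather than replacing the Met-bearing
  peptide.** Retaining both maximizes matchability of observed peptides —
  a dataset may contain either form — at the cost of a slightly larger
  database.
* **A peptide containing X/U/B/Z is voided; the protein is kept.**
  Ambiguity codes cannot be matched by an observed sequence, but the rest
  of the protein digests normally.

## The database

The PCDB is a single SQLite file with three relations: `MainData`
(protein key, accession, full sequence, taxon, gene), `Reference`
(hashed peptide, protein key; one row per peptide–protein incidence), and
`DBParams` (the complete digestion parameter set, a schema version, the
hash algorithm name, and the index flag). Indexing the hash column is a
separate, idempotent step so build time scales linearly in protein count.
Parallel builds partition *proteins* across forked workers and merge with
multiset semantics, so worker count cannot change queryable content.

**Hashing.** Peptides are stored only as 64-bit FNV-1a hashes of their
canonical sequences — a fixed, published, dependency-free function, so
databases built on different machines agree (the suite pins four values
computed by an independent implementation). R has no native 64-bit
integer, so hashes travel as signed decimal strings and SQLite stores them
as true `INTEGER`s via `CAST`.

**Collision safety.** Hash collisions are possible in principle, so a hash
hit is reported only after verification against the stored parent
sequence: the canonical peptide must occur literally, with both boundaries
at cleavage sites or termini (or the Met-excision start), an internal
missed-cleavage count within bounds, and a length within bounds — all
evaluated under the parameters stored in `DBParams`, never the caller's.
Storing full protein sequences in `MainData` makes this check cheap and
keeps the system exact rather than probabilistic. Cut sites are computed
on the *original* sequence (I→L can create spurious sites for
residue-specific rules like chymotrypsin); matching happens on the
canonicalized sequence, which is position-aligned.

## Annotation, filtering, and quantitation

Observed sequences are modification-stripped (bracketed/parenthesized tags
removed, non-letters dropped) before lookup; the stripped sequence is the
join key throughout, which is also what pools modified and unmodified
forms during spectral counting. Unmatched rows are retained and flagged —
match rate is a quality-control signal, not noise to discard silently.

Two filtering regimes mirror common practice for mixed-species data:

* **Assume one organism** (`default_taxon`, no uniqueness requirement):
  a row is kept whenever the default taxon is *plausible* (among its
  hits), simulating a search against a single organism's proteome. Rows
  hitting only excluded taxa are dropped. Whether a row must survive
  exclusion to count as plausible is ambiguous in common usage; here the
  default taxon's presence among hits suffices, and the exclusion list
  independently removes rows with no non-excluded hits.
* **Taxon-unique** (`require_unique = TRUE`): a row is kept only if all
  hits resolve to one taxon at the chosen rank. Uniqueness is evaluated
  *after* lineage resolution, so two species of one genus do not break
  genus-level uniqueness. A hit whose lineage lacks the rank is its own
  "absent" category and breaks uniqueness — absence is never imputed.

The unique-only result is a subset of the assume-one-organism result for
the same taxon by construction; the difference is exactly the shared
peptides whose attribution depends on the analyst's assumption.

Gene rollup sums each quantitative column over the rows of each gene. Rows
mapping to zero or several gene symbols are dropped and counted — no
razor/fractional allocation, because fractional shares would manufacture
precision the peptide evidence does not contain. Column totals are
conserved over retained rows.

Reference-pool normalization applies, in order: per-gene ratio to the
reference channel, log2, per-channel median centering, and division by the
per-channel **population** SD (the convention here; with the sample SD the
output SD would be (n−1)/n ≠ 1 under its own definition). Output channels
therefore have median exactly 0 and SD exactly 1 (tolerance 1e−9 in
tests). The reference channel itself becomes all-zero at the log step; its
SD is zero and the division is skipped rather than producing NaN. Genes
with a missing or non-positive reference value are dropped and counted;
fewer than two remaining genes is an error because the SD is undefined.

## The de novo pipeline

De novo sequencing engines emit ranked candidate sequences per spectrum
with no reference database and hence no false-discovery control.
`taxopep` constrains candidates to biological plausibility: after an ALC
floor (default 50), candidates are checked serially in descending
confidence — ties keep the engine's emission order, which is documented
because acceptance can depend on it — and the first database match is the
spectrum's peptide (`top_candidate` mode checks only the best candidate;
the database-constrained mode accepts at least as many spectra on any
input). Retained peptides must be genus-unique, have ≥ 2 spectra across
all samples (summed over input files; per-sample detail is kept for
reporting), and pass a taxon allowlist (default: bacterial superkingdom or
human species — appropriate for human-derived microbiome samples and
configurable because it is study-specific).

False genus discovery is controlled with a decoy database built from
whole-protein reversed sequences (same digestion parameters), the
annotation repeated verbatim, and genera ranked by
Δ = forward − reverse counts; genera with Δ > 7 (the default threshold)
are accepted. Δ is computed on *distinct genus-unique peptides* by
default — the scale on which the threshold is defined — with spectral
counts available as an alternative measure.

**Why whole-protein reversal, and what symmetry holds.** Reversal
preserves amino-acid composition and protein count while destroying real
tryptic structure, which is what makes reverse matches an estimate of the
false-match rate. It is worth being precise about an intuition that is
*not* true: reversing a tryptic peptide and querying the reversed database
is not equivalent to the forward query. Digestion does not commute with
reversal — for trypsin/p, `digest(rev(P)) ≠ rev(digest(P))` (the K/R
anchors move from fragment ends to fragment starts) — and this asymmetry
is precisely why reversed candidates almost never match and why the decoy
arm measures noise. The symmetry that does hold, and that the acceptance
suite asserts exactly, is *equivariance under proteome relabeling*:
generating candidates from the reversed proteome by the same deterministic
procedure and querying the reversed database reproduces the forward
per-genus counts exactly, because the decoy arm reuses the forward code
path and parameters verbatim.

## The synthetic world

The generators produce proteins as concatenations of globally unique
K/R-terminated fragments (interiors free of K/R, of I, and of ambiguity
codes; never starting with M). This makes the digestion products *by
construction* exactly the runs of up to three consecutive fragments, so
the ground-truth manifest is enumerable without running the digestion code
under test, canonicalization is the identity, and every peptide's taxon
membership is known. Homolog pairs reuse k of a protein's n fragments in
reversed relative order, which destroys every shared adjacency and makes
the shared tryptic-peptide fraction under the default digest exactly
k/(3n−3) — testable to equality, not approximately. Default world:
3 genera × 2 species × 5 proteins of 6 fragments, two homolog pairs at
shared fraction 0.4 (homology is common but partial), 6 reporter channels
(a TMT 6-plex with channel 1 as reference pool), 20 % noise, 12 planted
genus-unique peptides per genus in de novo runs (comfortably above the
Δ > 7 threshold, as a real present genus would be), each observed in 2–3
spectra with the true candidate at rank 2 and reversed-peptide noise
around it.

What the generators deliberately do **not** emulate: mass-spectral error
(candidate sequences are either exactly right or exactly absent),
retention time and fragmentation, shared peptides *within* a species,
isoforms, and realistic intensity structure beyond log-normal channels. A
green test therefore establishes the combinatorial and bookkeeping
correctness of digestion, storage, querying, filtering, rollup, and decoy
ranking — not the biological error rates of any instrument or engine.

## Numerical and edge-case choices

* Hash: FNV-1a 64-bit over residue bytes; empty sequences are errors.
* Duplicate canonical peptides within one protein keep the smallest
  missed-cleavage count.
* Tables with spaces in column names (`Reporter intensity 1`) are read and
  written with names preserved verbatim.
* A query sequence outside the database's length bounds returns an empty
  result, not an error — the database simply cannot contain it.
* Dangling taxonomy parents stop the lineage walk and report the ranks
  found so far; unknown taxon IDs raise a typed error
  (`taxopep_unknown_taxon`), distinguishable from "rank absent".
* Non-canonical taxonomy ranks ("no rank", "clade") never satisfy a
  standard rank request.
* FASTA entries without an `OX=` token, with empty sequences, or with
  duplicate accessions are rejected with a warning and counted, never
  silently dropped.

## Limitations

* No semi-specific or non-specific digestion, and no modification-aware
  cleavage; peptide mass is never computed.
* Protein-level inference is by gene symbol only; entries lacking `GN=`
  are carried with an empty gene and excluded from rollup (counted).
* A PCDB is immutable once built: no incremental updates or merging.
* Hash values are specific to this package's canonicalization and hash
  choice; databases are not interchangeable with other tools' files.
* Differential-expression statistics and pathway analysis are out of
  scope; the gene × sample tables are designed to feed standard tools
  (limma, ANOVA + BH, …) downstream.
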