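---
title: "Curated viral databases and kmer classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curated viral databases and kmer classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virdbkit)
```

# Overview

`virdbkit` maintains family-partitioned nucleotide reference databases and
classifies reads against them. This vignette documents the methods the
package implements, the parameters that matter, the choices made where the
design was genuinely open, and what the synthetic test bed does and does
not demonstrate about real data.

# Database construction

A database is defined by an input table of sub-database specifications: a
name (one virus family, by convention) and an NCBI-style Boolean search
string. Queries can be augmented, in a fixed order, with patent exclusion
(`NOT gbdiv_pat[Properties]`), human-taxid exclusion
(`NOT txid9606[Organism]`), a `complete` title keyword, and a sequence
length range (SLEN). The augmentation grammar is this package's own
contract: downstream code and the offline fetcher both rely on it, and the
exact token order makes augmented queries reproducible strings that can be
logged and compared.

Downloads go through an *EntryFetcher* interface with two operations,
`search(query)` and `fetch_batch(accessions)`. The live implementation
(`entrez_fetcher()`) speaks the URL-based E-utilities; the offline
implementation (`fixture_fetcher()`) evaluates a restricted query grammar
over in-memory records — taxonomy-id terms, title keywords and length
ranges, with `NOT`-terms as exclusions. Full Boolean query semantics are
deliberately not emulated: the fixture fetcher exists so that batching,
verification, retry, update and rollback logic can be exercised
deterministically, not to reimplement a search engine. Batch size defaults
to 100 accessions, with 3 retries per failing batch and a configurable
inter-batch delay (default 0 s; set a few tenths of a second for live
servers). A batch is accepted only when the parsed records match the
requested accessions exactly; `verify_download()` reports missing and
unexpected accessions across a whole sub-database.

## Complete-genome restriction

Two independent mechanisms restrict a database to (near-)complete genomes:

* **Length criteria**: a family's accepted window is
  `[round(0.9 * shortest), round(1.1 * largest)]` where shortest/largest
  are the known genome or segment length extremes (user-supplied, e.g.
  curated from a genome-length resource). The 10% buffers admit divergent
  or slightly mis-trimmed complete genomes while rejecting gene fragments;
  bounds are inclusive, and the same window can be applied either inside
  the query (SLEN) or as a local post-filter — the two agree by
  construction and are tested to agree on fixtures. Segmented families get
  a single per-family window spanning all segments by default; listing one
  spec per segment gives per-segment windows when more precision is
  wanted.
* **Title criteria**: keep entries whose description contains "genome"
  together with "complete", optionally also accepting "partial". This
  trusts submitter annotation, requires no prior knowledge, and is the
  fallback when no length table exists.

## Versioning

The manifest maps each sub-database to its ordered accession list and
carries an append-only history (one JSON event per added or removed
accession, with a version number). Updating re-runs each search and
applies the set difference: only new accessions are fetched, vanished ones
are dropped from the current FASTA files, and the version counter
increments once per applied update. Two decisions go beyond bare accession
bookkeeping:

* **Removals are archived, not deleted.** Every record ever fetched stays
  in `archive.fasta` until an explicit `purge`, so rollback to any stored
  version is a purely local operation and never re-downloads. Rollback
  mints a *new* version whose membership equals the target's, recorded
  through ordinary add/remove events — history is never rewritten, and
  membership at any version can be reconstructed by replaying events.
* **Atomic commits.** State files are written to a temporary file and
  renamed into place, and all fetching happens before any file is touched,
  so a failed update leaves the directory exactly as it was.

Identical versioned accessions are treated as unchanged content; a
re-submission under the same accession.version is not re-fetched.

# Cleaning

Cleaning runs in a fixed order — blocklist, contamination screen, exact
dereplication, optional clustering — each stage feeding the next, and
every removed entry carries exactly one primary reason in the report.

The **blocklist** is a user-maintained file of accessions known to be
misassembled or mislabelled; entries match with or without a version
suffix and are removed unconditionally.

The **contamination screen** indexes the user-supplied contaminant FASTA
(vectors, plasmids, rRNA, marker genes and similar) with canonical k-mers
and removes any entry whose k-mer matches cover a contaminant at or above
the threshold. Coverage is measured *of the contaminant*: the union of
k-base windows at matched contaminant positions, divided by contaminant
length. Counting covered bases rather than matched windows keeps the
statistic in [0, 1] and insensitive to overlap; accepting split (non
contiguous) matches is a deliberate choice — a vector insert chopped in
two by the assembler is still vector. The default threshold is 0.5: in a
sweep over 0.5/0.6/0.75/0.95 removal counts are monotone non-increasing
by construction, and the lowest rung is the conservative "no contamination
survives" setting, accepting some loss of completeness. The screen is
nucleotide-only; protein records pass through with a notice, and
contaminants shorter than k are ignored with a warning.

**Dereplication** removes exact, case-insensitive, forward-strand
duplicate sequences, keeping the first occurrence. Only exact matches are
removed by default because intra-family diversity varies too much for a
single similarity cutoff to be defensible; reverse-complement duplicates
and near-duplicates are left to the optional **greedy clustering**
(length-descending, join the first centroid with shared-kmer identity at
or above the user threshold, identity normalized by the shorter sequence's
distinct-kmer count).

# Classification

References are indexed with canonical k-mers, k = 16 by default — long
enough that chance matches are negligible (4^16 ≈ 4.3e9 words), short
enough to tolerate moderate divergence; the same k is used for the
contamination screen for consistency, and both are configurable.

Each read (FASTQ) or contig (FASTA) is assigned to the template containing
the most of its canonical k-mers, counted with multiplicity. Ties are
broken deterministically: fewer distinct template k-mers first (the more
specific template), then the lexicographically smaller accession, with a
tie flag retained. Reads are assigned wholly, never fractionally; paired
reads are classified independently.

Per template, **coverage** is the fraction of its distinct unmasked
k-mers seen in at least one assigned read, and **identity** is total
matched over total k-mers across its assigned reads. Coverage over
distinct k-mers (not base intervals) was chosen because it aggregates
naturally across overlapping reads without positional alignment and
remains well-defined under masking. A hit passes at coverage >= 0.8 and
identity >= 0 by default; the high coverage bar is what suppresses
spurious hits from local similarity. Note that identity degrades quickly
with substitution errors — one substitution spoils up to k overlapping
k-mers — so identity thresholds should be set with the error rate in mind.

**Host masking** adds every canonical k-mer of a host reference to the
index's masked set; masked k-mers are invisible to all subsequent
matching. This targets the classic failure mode where database entries
carry host-derived fragments (endogenous elements, misassemblies): host
reads tile exactly those fragments and the entry passes the coverage bar.
Masking makes host reads unassignable and can only decrease mapped-read
counts and coverage — monotonicity that is property-tested. The masked
fraction of the index vocabulary is reported per run. Two caveats are
inherent: genuinely host-overlapping viruses (integrating families) lose
sensitivity, and a chimeric entry's *viral* portion stays matchable, so
reads from the donor genome region can still tie onto the chimera; the
residual is typically zero or one passing hit in the synthetic study.

# The synthetic module

All tests and the acceptance script run on generated data: uniform random
genomes, GenBank flat-file fixtures that round-trip the parser, chimeras
spliced from genome + contaminant or genome + host fragment, and a
wgsim-style read simulator (uniform starts and strands, substitution-only
errors, constant quality strings, deterministic per seed). The standard
mock community holds 5 families x 3 genomes of 3 kb, one 20 kb host, two
600 nt vectors, one vector-spiked chimera and one mostly-host chimera;
reads are 100 nt, typically 150 per genome and 800 from the host — sizes
chosen so every stage's expected behaviour (tiling coverage ≈ 0.99 per
genome, host-chimera coverage ≈ 0.88 from host reads) has comfortable
margin over the 0.8 threshold while the full suite runs in well under a
minute per scenario.

What this emulates: the combinatorics of overlapping queries, batching
faults, update diffs, contaminated and duplicated entries, host-driven
false positives, and even family mixtures. What it does not: real
phylogenetic structure (uniform random genomes share no k-mers between
families, so cross-family misassignment is essentially impossible here),
indels and quality-dependent errors, abundance skew, and real NCBI query
semantics. Passing tests therefore demonstrate the correctness of the
machinery and its decision rules, not classification accuracy on real
viromes.

# Numerical and degenerate-input conventions

* Ambiguity-code windows (N, R, ...) are skipped during kmerization, never
  enumerated: deterministic, cheap, and a read or reference loses only the
  windows that touch the ambiguous base.
* Reads shorter than k are unassigned with zero total k-mers; empty query
  files produce empty reports and a warning, not an error.
* An empty contamination database screens nothing (warning); an empty
  index reports masked fraction 0 by convention.
* Equal-coverage contaminants resolve to the first maximum; assignment
  ties use the explicit two-level tie-break above.
* Length bounds are inclusive and rounded to nearest integer; coverage
  comparisons use plain `>=` with no epsilon, since all quantities are
  ratios of exact integer counts.
* Accessions duplicated across overlapping sub-database queries appear in
  every sub-database's manifest list but exactly once in the concatenated
  FASTA (first sub-database in input order wins), because a classifier
  index needs unique templates.
* The annotated FASTA header carries accession, sub-database, taxonomy id
  and organism only; free-text descriptions stay out of the header (and
  are therefore not round-tripped) to keep the dialect unambiguous to
  parse with four pipe-delimited fields.

# Known limitations

* The contamination screen removes whole entries; it does not mask or trim
  the contaminated region within an entry.
* No protein-mode contamination screening; protein databases can be built
  and downloaded but are cleaned only by blocklist and dereplication.
* The classifier is a k-mer counter with deterministic tie-breaks, not a
  full mapper: no alignment extension, consensus calling, abundance
  correction or LCA logic.
* Fractional assignment of multi-mapping reads is intentionally not
  implemented; ties are flagged so downstream consumers can handle them
  explicitly.
* The live E-utilities client is a thin convenience and is not exercised
  by the automated tests; offline fixtures are the tested path.
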