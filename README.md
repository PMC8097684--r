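# virdbkit

Build, clean and incrementally update family-specific viral sequence
databases from GenBank-style records, and classify sequencing reads or
assembled contigs against them with a canonical k-mer index.

## The problem

Broad viral metagenomics (virome sequencing, agnostic diagnostics,
surveillance) needs reference databases that are at once comprehensive and
trustworthy. Public nucleotide archives grow by thousands of viral entries
per month, but a naive "download everything matching this taxon" strategy
pulls in gene fragments, patent submissions, cloning-vector sequence,
misassembled composites and host-derived material — all of which turn into
false positives when short reads are classified against the database.
`virdbkit` automates the whole curation loop for users who maintain their
own family-partitioned databases:

* **Download** — one sub-database per named Boolean search string (typically
  one virus family), fetched in verified batches through a pluggable fetcher
  interface, with optional restriction to complete genomes either by title
  keywords (`complete`/`partial` + `genome`) or by family-specific length
  windows spanning 10% below the shortest to 10% above the largest known
  genome or segment.
* **Clean** — unconditional removal of blocklisted accessions; removal of
  entries whose k-mer matches cover a contaminant sequence (UniVec-style
  vectors, marker genes, rRNA — user-supplied FASTA) at or above a coverage
  threshold (default 50%); exact dereplication; optional greedy clustering.
* **Version** — a manifest records which accessions belong to which
  sub-database, with an append-only history log; updates download only new
  entries, removals are archived rather than deleted, and any prior version
  can be rolled back to without re-downloading.
* **Classify** — reads (FASTQ) or contigs (FASTA) are assigned to the
  template sharing the most canonical 16-mers; per-template hits are called
  on template k-mer coverage (default 80%) and identity, and compositions
  are reported at family and species level. k-mers shared with a host
  reference can be masked beforehand, suppressing the host-driven false
  positives that chimeric database entries otherwise cause.

## The statistic at the core

All screening and hit calling reduces to one primitive: **canonical k-mer
coverage**. A canonical k-mer is min(w, revcomp(w)) for a k-length window
w, collapsing strand. For a database entry q and contaminant c, the
removal statistic is

    cov(c | q) = |union of [p, p+k-1] over matched positions p of c| / |c|

where a position of c is *matched* when its canonical k-mer occurs among
q's canonical k-mers — covered bases, not window counts, so overlapping
matches are not double-counted. The classifier uses the same machinery per
template, with coverage over the template's distinct unmasked k-mers seen
in assigned reads.

A deterministic synthetic module (random genomes, GenBank flat-file
fixtures, vector-spiked chimeras, wgsim-style reads with a substitution
error model) makes the entire pipeline runnable and testable offline.

## Worked example

Everything below runs offline against the built-in mock community (five
synthetic virus families, three genomes each, one vector-spiked chimera,
two vector contaminants, one host genome).

```r
library(virdbkit)

mc <- make_mock_community(seed = 1)
db <- file.path(tempdir(), "virdb")

# 1. download: one sub-database per family query, via the offline fetcher
manifest <- download_database(mc$specs, fixture_fetcher(mc$records), db)
manifest
#> <db_manifest> version 1 - 5 sub-database(s), 16 accession(s), 16 history event(s)

# 2. clean at the default 50% contaminant-coverage threshold
recs <- read_annotated_fasta(file.path(db, "db.fasta"))
res <- clean_records(recs, contaminants = mc$contaminants, threshold = 0.5)
res$report
#>    accession          subdb        reason contaminant coverage
#> 1 SYNCHIM1.1 Synthviridae_A contamination      VEC001        1
write_annotated_fasta(res$kept, file.path(db, "db.fasta"))

# 3. classify reads simulated from three genomes (1% substitution errors),
#    masking host kmers
reads <- do.call(rbind, lapply(1:3, function(i)
  simulate_reads(mc$records$sequence[i], n = 150, read_length = 100,
                 error_rate = 0.01, seed = 100 + i,
                 genome_id = mc$records$accession[i])))
qf <- file.path(db, "reads.fastq")
write_fastq(reads, qf)
out <- classify_run(db, qf, host_mask = mc$host)
out$hits[, c("template", "subdb", "organism", "reads", "coverage", "identity", "pass")]
#>     template          subdb      organism reads  coverage  identity pass
#> 1 SYN00001.1 Synthviridae_A Synthvirus a1   150 0.9728643 0.8623529 TRUE
#> 2 SYN00002.1 Synthviridae_A Synthvirus a2   150 0.9765494 0.8709020 TRUE
#> 3 SYN00003.1 Synthviridae_A Synthvirus a3   150 0.9520938 0.8414902 TRUE
round(out$composition_family$fractions, 3)
#> Synthviridae_A
#>              1
```

The one chimeric entry carrying a full vector copy is removed at coverage
1.0; each source genome comes back as a passing hit (coverage above the
0.8 threshold, identity depressed to ~0.86 by the 1% substitution rate —
a single substitution spoils up to k = 16 overlapping k-mers), and all
assigned reads belong to the one family the reads were drawn from.

The same workflow is available as subcommands (`download`, `update`,
`clean`, `dedup`, `index`, `classify`, `simulate`, `purge`) through
`vdb_cli()` or the `inst/scripts/virdbkit` wrapper; live NCBI downloads
use `entrez_fetcher()` in place of the offline fixture fetcher.

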