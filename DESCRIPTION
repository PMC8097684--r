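Package: virdbkit
Title: Family-Specific Sequence Database Curation and Kmer-Based Viral
    Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds, cleans and incrementally updates family-specific
    nucleotide reference databases from GenBank-style records, and
    classifies sequencing reads or assembled contigs against the cleaned
    database using a canonical k-mer index.  Database construction is
    driven by named Boolean search strings (one sub-database per virus
    family), with optional restriction to complete genomes via
    family-specific length criteria or title keywords.  Cleaning removes
    blocklisted accessions, entries covering user-supplied contaminant
    sequences (UniVec-style vectors, marker genes) above a coverage
    threshold, and exact duplicates, with optional greedy clustering.
    Databases are versioned with an append-only history log supporting
    diff-based updates and rollback.  Classification supports host k-mer
    masking, per-template coverage and identity thresholds, and
    family/species composition reports.  A deterministic synthetic module
    generates genomes, GenBank flat-file fixtures, vector-spiked chimeras
    and wgsim-style reads so the entire pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
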