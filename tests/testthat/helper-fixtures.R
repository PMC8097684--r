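# Shared fixtures and independent oracles.

rand_seq <- function(n, seed) virdbkit::random_genome(n, seed)

revcomp_oracle <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Independent brute-force coverage oracle: scan every window of the
# reference and substring-search the query and its reverse complement.
# Deliberately avoids the package's canonicalization/indexing path.
oracle_coverage <- function(query, ref, k) {
  n <- nchar(ref)
  if (n < k) return(0)
  starts <- seq_len(n - k + 1L)
  wins <- substring(ref, starts, starts + k - 1L)
  valid <- !grepl("[^ACGT]", wins)
  rcq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
  hit <- valid & vapply(wins, function(w) {
    grepl(w, query, fixed = TRUE) || grepl(w, rcq, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
  covered <- logical(n)
  for (p in starts[hit]) covered[p:(p + k - 1L)] <- TRUE
  sum(covered) / n
}

# (query, reference) pair with a planted shared segment so coverage is
# usually strictly between 0 and 1; the segment may be reverse-complemented.
random_pair <- function(seed, ref_len = 120, query_len = 200) {
  ref <- rand_seq(ref_len, seed)
  query <- rand_seq(query_len, seed + 10000L)
  set.seed(seed + 20000L)
  seg_len <- sample.int(ref_len, 1)
  at <- sample.int(ref_len - seg_len + 1L, 1)
  seg <- substr(ref, at, at + seg_len - 1L)
  if (runif(1) < 0.5)
    seg <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  ins <- sample.int(query_len - seg_len + 1L, 1)
  query <- paste0(substr(query, 1, ins - 1L), seg,
                  substr(query, ins + seg_len, query_len))
  list(query = query, ref = ref)
}

# small record set for IO round-trips
random_records <- function(n, seed, subdb = "TestDB") {
  accs <- sprintf("RND%05d.%d", seq_len(n), (seq_len(n) %% 3) + 1L)
  orgs <- paste("Testvirus", letters[(seq_len(n) %% 26) + 1L], seq_len(n))
  set.seed(seed)
  lens <- sample(50:200, n, replace = TRUE)
  virdbkit::sequence_records(
    accession = accs,
    sequence = vapply(seq_len(n), function(i) rand_seq(lens[i], seed * 100L + i),
                      character(1)),
    description = paste0(orgs, ", complete genome"),
    organism = orgs,
    taxid = 999100L + seq_len(n),
    lineage = lapply(seq_len(n), function(i) c("Viruses", "Testviridae")),
    subdb = subdb)
}

# fetcher decorator whose first call for each batch returns truncated text
flaky_fetcher <- function(fetcher) {
  seen <- new.env()
  list(
    search = fetcher$search,
    fetch_batch = function(accessions) {
      key <- paste(accessions, collapse = ",")
      txt <- fetcher$fetch_batch(accessions)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        return(substr(txt, 1, nchar(txt) %/% 2))
      }
      txt
    }
  )
}
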