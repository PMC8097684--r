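# Search-string augmentation and batched, verified downloads through a
# pluggable fetcher contract.  An EntryFetcher is a list with two functions:
#   search(query)          -> ordered character vector of accessions
#   fetch_batch(accessions) -> GenBank flat-file text for exactly those
# The offline fixture fetcher used throughout the tests matches entries by
# taxonomy id, title keywords and sequence length only; full NCBI Boolean
# semantics are not emulated.

#' Standard query augmentation flags
#'
#' @param exclude_patents append `NOT gbdiv_pat[Properties]` (patent entries
#'   are largely redundant).
#' @param exclude_human append `NOT txid9606[Organism]` (human co-annotated
#'   entries are a common contamination source).
#' @param complete_keyword append `AND complete` to restrict toward complete
#'   genomes by title.
#' @param length_bounds optional `c(min, max)` sequence-length restriction in
#'   residues (SLEN range).
#' @return a list of class `query_flags`.
#' @export
query_flags <- function(exclude_patents = FALSE, exclude_human = FALSE,
                        complete_keyword = FALSE, length_bounds = NULL) {
  if (!is.null(length_bounds)) {
    stopifnot(length(length_bounds) == 2, length_bounds[1] <= length_bounds[2])
  }
  structure(list(exclude_patents = exclude_patents,
                 exclude_human = exclude_human,
                 complete_keyword = complete_keyword,
                 length_bounds = length_bounds),
            class = "query_flags")
}

#' Augment a Boolean search string with standard restrictions
#'
#' Appends, in fixed order: patent exclusion, human exclusion, the
#' `complete` keyword, and an SLEN length range.  With all flags off the
#' query is returned untouched.
#'
#' @param spec one row of [parse_input_spec()] output (or a list with
#'   `query`, optionally `min_len`/`max_len`).
#' @param flags a [query_flags()] object.
#' @return the augmented query string.
#' @examples
#' s <- parse_input_spec("Coronaviridae\ttxid11118[Organism:exp]")
#' augment_query(s[1, ], query_flags(exclude_patents = TRUE,
#'                                   exclude_human = TRUE))
#' @export
augment_query <- function(spec, flags = query_flags()) {
  q <- spec$query
  stopifnot(nzchar(q))
  if (isTRUE(flags$exclude_patents)) q <- paste0(q, " NOT gbdiv_pat[Properties]")
  if (isTRUE(flags$exclude_human))   q <- paste0(q, " NOT txid9606[Organism]")
  if (isTRUE(flags$complete_keyword)) q <- paste0(q, " AND complete")
  lb <- flags$length_bounds
  if (is.null(lb) && !is.null(spec$min_len) && !is.na(spec$min_len))
    lb <- c(spec$min_len, spec$max_len)
  if (!is.null(lb))
    q <- paste0(q, " AND (\"", lb[1], "\"[SLEN] : \"", lb[2], "\"[SLEN])")
  q
}

#' Offline fetcher backed by in-memory records
#'
#' Implements the EntryFetcher contract over a fixed universe of records.
#' `search()` evaluates the restricted query grammar produced by
#' [augment_query()]: `txidN[Organism]` terms match by taxonomy id, SLEN
#' ranges by sequence length, `gbdiv_pat[Properties]` and bare keywords by
#' case-insensitive title match; terms after `NOT` exclude.  Deterministic:
#' accessions are returned in universe order.
#'
#' @param records a [sequence_records()] universe.
#' @return an EntryFetcher (list with `search` and `fetch_batch`).
#' @export
fixture_fetcher <- function(records) {
  universe <- records
  match_term <- function(term) {
    term <- trimws(term)
    if (grepl("^txid[0-9]+\\[", term)) {
      tid <- as.integer(sub("^txid([0-9]+)\\[.*$", "\\1", term))
      return(universe$taxid == tid)
    }
    m <- regmatches(term,
      regexec("^\\(\"([0-9]+)\"\\[SLEN\\] : \"([0-9]+)\"\\[SLEN\\]\\)$", term))[[1]]
    if (length(m) == 3) {
      len <- nchar(universe$sequence)
      return(len >= as.integer(m[2]) & len <= as.integer(m[3]))
    }
    if (grepl("^gbdiv_pat\\[", term))
      return(grepl("patent", tolower(universe$description), fixed = TRUE))
    word <- sub("\\[.*$", "", term)
    grepl(tolower(word), tolower(universe$description), fixed = TRUE)
  }
  list(
    search = function(query) {
      if (!nrow(universe)) return(character(0))
      chunks <- strsplit(query, " NOT ", fixed = TRUE)[[1]]
      pos_terms <- strsplit(chunks[1], " AND ", fixed = TRUE)[[1]]
      keep <- Reduce(`&`, lapply(pos_terms, match_term))
      for (neg in chunks[-1]) keep <- keep & !match_term(neg)
      universe$accession[keep]
    },
    fetch_batch = function(accessions) {
      idx <- match(accessions, universe$accession)
      if (anyNA(idx))
        stop("fixture fetcher: unknown accession(s): ",
             paste(accessions[is.na(idx)], collapse = ", "))
      emit_genbank_fixture(universe[idx, , drop = FALSE])
    }
  )
}

#' Offline fetcher backed by a directory of GenBank flat files
#'
#' Parses every `*.gb` / `*.gbk` / `*.txt` file in `dir` into a record
#' universe and delegates to [fixture_fetcher()].
#'
#' @param dir directory of GenBank flat files.
#' @return an EntryFetcher.
#' @export
fixture_fetcher_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(gb|gbk|txt)$", full.names = TRUE)
  recs <- do.call(bind_records,
                  lapply(files, parse_genbank_records, subdb = ""))
  fixture_fetcher(recs)
}

#' Live NCBI E-utilities fetcher
#'
#' Thin EntryFetcher over the URL-based esearch/efetch endpoints.  Provided
#' for real downloads; network behaviour is untested and all automated tests
#' use the fixture fetcher.
#'
#' @param moltype `"nucleotide"` or `"protein"` (selects the E-utilities db).
#' @param base_url E-utilities base URL.
#' @return an EntryFetcher.
#' @export
entrez_fetcher <- function(moltype = "nucleotide",
                           base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/") {
  db <- if (moltype == "protein") "protein" else "nuccore"
  list(
    search = function(query) {
      url <- paste0(base_url, "esearch.fcgi?db=", db,
                    "&retmax=100000&idtype=acc&term=",
                    utils::URLencode(query, reserved = TRUE))
      xml <- paste(readLines(url, warn = FALSE), collapse = "\n")
      m <- regmatches(xml, gregexpr("<Id>[^<]+</Id>", xml))[[1]]
      gsub("</?Id>", "", m)
    },
    fetch_batch = function(accessions) {
      url <- paste0(base_url, "efetch.fcgi?db=", db,
                    "&rettype=gb&retmode=text&id=",
                    paste(accessions, collapse = ","))
      paste(readLines(url, warn = FALSE), collapse = "\n")
    }
  )
}

#' Download one sub-database in verified batches
#'
#' Searches with the augmented query, then fetches the matching accessions
#' in batches.  A batch whose parsed-record count differs from the request,
#' or whose fetch raises, is retried up to `retries` times; persistent
#' failure raises an error listing the missing accessions.  An inter-batch
#' delay reduces pressure on a live server (leave at 0 for offline
#' fetchers).
#'
#' @param spec one sub-database spec row.
#' @param fetcher an EntryFetcher.
#' @param flags a [query_flags()] object.
#' @param batch_size accessions per fetch call (default 100).
#' @param retries re-attempts per failing batch (default 3).
#' @param delay seconds between batches (default 0).
#' @return list with `records` (stamped with `spec$name` as subdb) and
#'   `accessions` (the search result, in order).
#' @export
download_subdatabase <- function(spec, fetcher, flags = query_flags(),
                                 batch_size = 100, retries = 3, delay = 0) {
  stopifnot(batch_size >= 1)
  accessions <- fetcher$search(augment_query(spec, flags))
  if (!length(accessions))
    return(list(records = empty_records(), accessions = character(0)))
  batches <- split(accessions,
                   ceiling(seq_along(accessions) / batch_size))
  parts <- vector("list", length(batches))
  for (b in seq_along(batches)) {
    want <- batches[[b]]
    got <- NULL
    for (attempt in seq_len(retries + 1L)) {
      res <- tryCatch({
        txt <- fetcher$fetch_batch(want)
        recs <- suppressWarnings(
          parse_genbank_records(txt, subdb = spec$name))
        if (nrow(recs) != length(want) || !setequal(recs$accession, want))
          stop("batch content mismatch")
        recs
      }, error = function(e) e)
      if (!inherits(res, "error")) { got <- res; break }
    }
    if (is.null(got)) {
      stop("download failed after ", retries, " retries; missing accessions: ",
           paste(want, collapse = ", "))
    }
    parts[[b]] <- got
    if (delay > 0 && b < length(batches)) Sys.sleep(delay)
  }
  list(records = do.call(bind_records, parts), accessions = accessions)
}

#' Compare downloaded records against the expected accession list
#'
#' @param records parsed records.
#' @param expected accession vector returned by the search.
#' @return list with `missing` (expected but not parsed), `unexpected`
#'   (parsed but not expected) and `count_ok` (TRUE iff both are empty).
#' @export
verify_download <- function(records, expected) {
  parsed <- records$accession
  missing <- sort(setdiff(expected, parsed))
  unexpected <- sort(setdiff(parsed, expected))
  list(missing = missing, unexpected = unexpected,
       count_ok = !length(missing) && !length(unexpected))
}
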