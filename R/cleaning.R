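# Database cleaning: blocklist removal, contaminant-coverage screening,
# exact dereplication, optional greedy clustering.  Stage order is fixed:
# blocklist -> contamination -> dedup -> (clustering), each stage feeding
# the next.

#' Read a blocklist file
#'
#' One accession per line (bare or versioned); `#` starts a comment.
#'
#' @param path blocklist file.
#' @return character vector of accessions.
#' @export
read_blocklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

strip_version <- function(acc) sub("\\.[0-9]+$", "", acc)

#' Remove blocklisted accessions
#'
#' Known problematic entries (misassemblies, mislabelled clones) are removed
#' unconditionally.  A blocklist entry matches with or without its version
#' suffix, so `MF468140` removes `MF468140.1`.
#'
#' @param records a [sequence_records()] object.
#' @param blocklist character vector of accessions.
#' @return list with `kept`, `removed`, and `report` (accession, subdb,
#'   reason, contaminant, coverage).
#' @export
apply_blocklist <- function(records, blocklist) {
  bare_bl <- unique(strip_version(blocklist))
  hit <- records$accession %in% blocklist |
    strip_version(records$accession) %in% bare_bl
  unused <- !(blocklist %in% records$accession |
                strip_version(blocklist) %in% strip_version(records$accession))
  if (any(unused))
    warning("blocklist entries matching nothing: ",
            paste(blocklist[unused], collapse = ", "), call. = FALSE)
  list(kept = records[!hit, , drop = FALSE],
       removed = records[hit, , drop = FALSE],
       report = cleaning_report_rows(records[hit, , drop = FALSE], "blocklist"))
}

cleaning_report_rows <- function(removed, reason, contaminant = NA_character_,
                                 coverage = NA_real_) {
  data.frame(accession = removed$accession,
             subdb = removed$subdb,
             reason = rep(reason, nrow(removed)),
             contaminant = rep_len(contaminant, nrow(removed)),
             coverage = rep_len(coverage, nrow(removed)),
             stringsAsFactors = FALSE)
}

#' Screen records against a contamination database
#'
#' Builds a canonical-kmer index over the contaminant sequences and removes
#' any nucleotide record that covers a contaminant at or above the
#' threshold, where coverage is the fraction of the contaminant's bases
#' covered by kmer matches from the record (see [reference_coverage()]).
#' Protein records pass through untouched with a notice (nucleotide-only
#' screen); contaminants shorter than k are ignored with a warning.
#'
#' @param records a [sequence_records()] object.
#' @param contaminants named character vector of contaminant sequences (or a
#'   FASTA path).
#' @param threshold removal threshold on contaminant coverage, in (0, 1];
#'   default 0.5.
#' @param k kmer length (default 16).
#' @return list with `kept`, `removed`, and `report` recording the best
#'   contaminant and its coverage for every removed record.
#' @export
screen_contamination <- function(records, contaminants, threshold = 0.5,
                                 k = 16) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.character(contaminants) && length(contaminants) == 1 &&
      file.exists(contaminants) && is.null(names(contaminants)))
    contaminants <- read_fasta_seqs(contaminants)
  if (!length(contaminants)) {
    warning("empty contamination database: nothing screened", call. = FALSE)
    return(list(kept = records, removed = records[0, , drop = FALSE],
                report = cleaning_report_rows(records[0, , drop = FALSE],
                                              "contamination")))
  }
  short <- nchar(contaminants) < k
  if (any(short)) {
    warning("ignoring contaminant(s) shorter than k: ",
            paste(names(contaminants)[short], collapse = ", "), call. = FALSE)
    contaminants <- contaminants[!short]
  }
  idx <- build_kmer_index(contaminants, k = k)
  n <- nrow(records)
  best_id <- rep(NA_character_, n)
  best_cov <- rep(0, n)
  screenable <- records$moltype == "nucleotide"
  if (any(!screenable))
    message(sum(!screenable),
            " protein record(s) passed through unscreened (nucleotide-only)")
  for (i in which(screenable)) {
    qk <- unique(canonical_kmers(records$sequence[i], k)$kmer)
    cands <- unique(unlist(idx$kmer_refs[qk], use.names = FALSE))
    cands <- cands[!is.na(cands)]
    if (!length(cands)) next
    covs <- vapply(cands, function(cid)
      reference_coverage(records$sequence[i], idx, cid), numeric(1))
    j <- which.max(covs)
    best_id[i] <- cands[j]
    best_cov[i] <- covs[j]
  }
  rm_flag <- screenable & best_cov >= threshold
  removed <- records[rm_flag, , drop = FALSE]
  list(kept = records[!rm_flag, , drop = FALSE],
       removed = removed,
       report = cleaning_report_rows(removed, "contamination",
                                     contaminant = best_id[rm_flag],
                                     coverage = best_cov[rm_flag]))
}

#' Remove exact duplicate sequences
#'
#' Case-insensitive exact sequence equality on the forward strand only
#' (derep semantics; reverse-complement near-duplicates are left to
#' clustering).  The first occurrence in input order is retained.
#'
#' @param records a [sequence_records()] object.
#' @return list with `kept`, `removed`, `report`, and `duplicate_of`: a
#'   named character vector mapping each removed accession to the retained
#'   one.
#' @export
dedup_exact <- function(records) {
  key <- toupper(records$sequence)
  first <- !duplicated(key)
  retained <- records$accession[first][match(key[!first], key[first])]
  removed <- records[!first, , drop = FALSE]
  rep_rows <- cleaning_report_rows(removed, "duplicate",
                                   contaminant = retained)
  dup_of <- stats::setNames(retained, removed$accession)
  list(kept = records[first, , drop = FALSE], removed = removed,
       report = rep_rows, duplicate_of = dup_of)
}

#' Greedy length-sorted clustering by shared-kmer identity
#'
#' Records are visited in order of decreasing length (stable for ties); each
#' joins the first existing centroid whose shared-kmer identity reaches the
#' threshold, otherwise it founds a new centroid.  Identity between two
#' sequences is the number of shared distinct canonical kmers divided by the
#' distinct-kmer count of the shorter sequence.
#'
#' @param records a [sequence_records()] object.
#' @param identity_threshold in \[0, 1\]; 1 collapses only kmer-identical
#'   sequences, 0 collapses everything onto the longest record.
#' @param k kmer length (default 16).
#' @return list with `centroids` (a `seq_records`), `membership` (named
#'   character vector: member accession -> centroid accession, centroids
#'   mapping to themselves) and `report` rows for non-centroid members.
#' @export
cluster_greedy <- function(records, identity_threshold, k = 16) {
  stopifnot(identity_threshold >= 0, identity_threshold <= 1)
  ord <- order(-nchar(records$sequence))
  recs <- records[ord, , drop = FALSE]
  kms <- lapply(recs$sequence, function(s) unique(canonical_kmers(s, k)$kmer))
  cent_idx <- integer(0)
  assign_to <- integer(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    placed <- FALSE
    for (ci in cent_idx) {
      shorter_n <- length(kms[[i]])  # visited in decreasing length order
      shared <- length(intersect(kms[[i]], kms[[ci]]))
      ident <- if (shorter_n == 0) 0 else shared / shorter_n
      if (ident >= identity_threshold) {
        assign_to[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cent_idx <- c(cent_idx, i)
      assign_to[i] <- i
    }
  }
  centroids <- recs[cent_idx, , drop = FALSE]
  membership <- stats::setNames(recs$accession[assign_to], recs$accession)
  members <- recs[assign_to != seq_len(nrow(recs)), , drop = FALSE]
  list(centroids = centroids,
       membership = membership,
       report = cleaning_report_rows(members, "cluster-member",
                                     contaminant = recs$accession[
                                       assign_to[assign_to != seq_len(nrow(recs))]]))
}

#' Run the full cleaning pipeline
#'
#' Fixed stage order: blocklist removal, contamination screening, exact
#' dereplication, then optional clustering.  Every input record ends up
#' kept or removed with exactly one primary reason.
#'
#' @param records a [sequence_records()] object.
#' @param contaminants named contaminant sequences or FASTA path (NULL skips
#'   the screen).
#' @param blocklist accession vector (NULL skips).
#' @param threshold contamination coverage threshold (default 0.5).
#' @param k kmer length.
#' @param cluster_identity optional clustering threshold; NULL disables
#'   clustering.
#' @return list with `kept` and a combined `report` data.frame.
#' @export
clean_records <- function(records, contaminants = NULL, blocklist = NULL,
                          threshold = 0.5, k = 16, cluster_identity = NULL) {
  report <- cleaning_report_rows(records[0, , drop = FALSE], "none")[0, ]
  kept <- records
  if (length(blocklist)) {
    st <- apply_blocklist(kept, blocklist)
    kept <- st$kept
    report <- rbind(report, st$report)
  }
  if (!is.null(contaminants)) {
    st <- screen_contamination(kept, contaminants, threshold = threshold, k = k)
    kept <- st$kept
    report <- rbind(report, st$report)
  }
  st <- dedup_exact(kept)
  kept <- st$kept
  report <- rbind(report, st$report)
  if (!is.null(cluster_identity)) {
    st <- cluster_greedy(kept, cluster_identity, k = k)
    kept <- st$centroids
    report <- rbind(report, st$report)
  }
  rownames(report) <- NULL
  list(kept = kept, report = report)
}
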