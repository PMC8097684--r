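# Canonical-kmer extraction, indexing and reference-coverage computation.
# Shared by the contamination screen (coverage of a contaminant by a database
# entry) and the classifier (coverage of a template by assigned reads).

#' Extract canonical kmers with positions
#'
#' A canonical kmer is the lexicographically smaller of a k-length window and
#' its reverse complement, collapsing strand so that matches are detected
#' regardless of orientation.  Windows containing any ambiguity code (N, R,
#' ...) are skipped rather than expanded: deterministic and cheap.
#'
#' @param sequence a single nucleotide sequence.
#' @param k word length (>= 1).
#' @return a data.frame with columns `pos` (0-based window start) and `kmer`
#'   (canonical form); empty when the sequence is shorter than `k`.
#' @examples
#' canonical_kmers("AAAT", 3)  # AAT beats its reverse complement ATT
#' @export
canonical_kmers <- function(sequence, k) {
  stopifnot(length(sequence) == 1, k >= 1)
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < k) return(data.frame(pos = integer(), kmer = character(),
                               stringsAsFactors = FALSE))
  starts <- seq_len(n - k + 1L)
  km <- substring(s, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", km)
  starts <- starts[ok]
  km <- km[ok]
  rc <- revcomp_kmers(km, k)
  swap <- rc < km
  km[swap] <- rc[swap]
  data.frame(pos = starts - 1L, kmer = km, stringsAsFactors = FALSE)
}

#' Build a canonical-kmer index over reference sequences
#'
#' Stores, per reference, the ordered (position, canonical kmer) inventory,
#' plus a global map from canonical kmer to the set of references carrying
#' it, and an (initially empty) masked-kmer set.  The default word length of
#' 16 is the standard choice for nucleotide read classification at this
#' scale.
#'
#' @param references named character vector of nucleotide sequences; names
#'   are reference ids and must be unique.
#' @param k word length (default 16).
#' @return an object of class `kmer_index`.
#' @export
build_kmer_index <- function(references, k = 16) {
  ids <- names(references)
  if (length(references) && (is.null(ids) || any(!nzchar(ids))))
    stop("references must be named")
  if (anyDuplicated(ids))
    stop("duplicate reference id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  inv <- lapply(as.character(references), canonical_kmers, k = k)
  names(inv) <- ids
  nper <- vapply(inv, nrow, integer(1))
  pairs <- unique(data.frame(
    kmer = unlist(lapply(inv, `[[`, "kmer"), use.names = FALSE),
    ref = rep(ids, nper),
    stringsAsFactors = FALSE))
  kmer_refs <- if (nrow(pairs)) split(pairs$ref, pairs$kmer) else
    stats::setNames(list(), character())
  structure(list(
    k = as.integer(k),
    ref_len = stats::setNames(nchar(as.character(references)), ids),
    inventories = inv,
    kmer_refs = kmer_refs,
    masked = character()
  ), class = "kmer_index")
}

# distinct unmasked canonical kmers of one reference
template_kmers <- function(index, ref_id) {
  km <- unique(index$inventories[[ref_id]]$kmer)
  setdiff(km, index$masked)
}

# total length of the union of intervals [p, p+k-1] over sorted unique
# 0-based starts p
covered_bases <- function(pos, k) {
  if (!length(pos)) return(0L)
  pos <- sort(unique(pos))
  if (length(pos) == 1L) return(as.integer(k))
  as.integer(k + sum(pmin(diff(pos), k)))
}

#' Fraction of a reference covered by kmer matches from a query
#'
#' The matched positions are the reference's inventory positions whose
#' canonical kmer is unmasked and occurs among the query's canonical kmers.
#' Coverage is the length of the union of the k-base windows at those
#' positions, divided by the reference length -- covered bases, not matched
#' window counts, so overlapping matches are not double-counted.
#'
#' @param query a single query sequence.
#' @param index a [build_kmer_index()] object.
#' @param ref_id reference id within the index.
#' @return coverage fraction in \[0, 1\].
#' @export
reference_coverage <- function(query, index, ref_id) {
  if (!ref_id %in% names(index$inventories))
    stop("unknown reference id: ", ref_id)
  inv <- index$inventories[[ref_id]]
  qk <- unique(canonical_kmers(query, index$k)$kmer)
  if (length(index$masked)) qk <- setdiff(qk, index$masked)
  m <- inv$pos[inv$kmer %in% qk]
  covered_bases(m, index$k) / index$ref_len[[ref_id]]
}

#' Mask kmers shared with a set of sequences
#'
#' Adds every canonical kmer of the mask sequences (typically a host genome)
#' to the index's masked set; masked kmers are ignored by all subsequent
#' lookups and coverage computations.  Used to suppress host-driven false
#' positives when database entries carry host-derived fragments.
#'
#' @param index a `kmer_index`.
#' @param mask_sequences character vector of nucleotide sequences.
#' @return a list with elements `index` (the masked index) and
#'   `masked_fraction`: the fraction of the index's distinct kmers that are
#'   now masked (0 by convention for an empty index).
#' @export
mask_kmers <- function(index, mask_sequences) {
  mk <- unique(unlist(lapply(mask_sequences, function(s)
    canonical_kmers(s, index$k)$kmer), use.names = FALSE))
  index$masked <- union(index$masked, mk)
  vocab <- names(index$kmer_refs)
  frac <- if (length(vocab))
    length(intersect(index$masked, vocab)) / length(vocab) else 0
  list(index = index, masked_fraction = frac)
}

#' Serialize a kmer index to JSON
#'
#' Lossless round-trip container recording k, reference lengths,
#' inventories, the global kmer map and the masked set.
#'
#' @param index a `kmer_index`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_kmer_index <- function(index, path) {
  payload <- list(
    format = "virdbkit-kmer-index",
    version = 1L,
    k = index$k,
    ref_len = as.list(index$ref_len),
    inventories = index$inventories,
    kmer_refs = index$kmer_refs,
    masked = index$masked
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_kmer_index
#' @export
load_kmer_index <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "virdbkit-kmer-index"))
    stop("not a kmer index file: ", path)
  inv <- lapply(p$inventories, function(d) {
    if (!length(d) || !NROW(d))
      return(data.frame(pos = integer(), kmer = character(),
                        stringsAsFactors = FALSE))
    data.frame(pos = as.integer(d$pos), kmer = as.character(d$kmer),
               stringsAsFactors = FALSE)
  })
  kr <- lapply(p$kmer_refs, as.character)
  if (!length(kr)) kr <- stats::setNames(list(), character())
  structure(list(
    k = as.integer(p$k),
    ref_len = stats::setNames(as.integer(unlist(p$ref_len)), names(p$ref_len)),
    inventories = inv,
    kmer_refs = kr,
    masked = as.character(p$masked %||% character())
  ), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k =", x$k, "-", length(x$inventories), "reference(s),",
      length(x$kmer_refs), "distinct kmer(s),",
      length(x$masked), "masked kmer(s)\n")
  invisible(x)
}
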