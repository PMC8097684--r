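# Complete-genome restriction: family-specific length bounds with a 10%
# buffer on either side, or title-keyword criteria ("complete"/"partial"
# plus "genome").

#' Length bounds from known genome/segment extremes
#'
#' A family's accepted length window spans from 10% below the shortest known
#' genome (or segment) to 10% above the largest, rounded to the nearest
#' integer.  The buffer admits slightly divergent or mis-trimmed complete
#' genomes while excluding gene fragments.
#'
#' @param shortest,largest known genome/segment length extremes in nt.
#' @return integer vector `c(min_len, max_len)`.
#' @examples
#' compute_length_bounds(25000, 32000)  # 22500, 35200
#' @export
compute_length_bounds <- function(shortest, largest) {
  if (!is.finite(shortest) || !is.finite(largest) ||
      shortest <= 0 || shortest > largest)
    stop("need 0 < shortest <= largest")
  c(min_len = as.integer(round(0.9 * shortest)),
    max_len = as.integer(round(1.1 * largest)))
}

#' Read a family length-criteria table
#'
#' Tab-separated columns: family, shortest, largest (header optional).  The
#' genome-length extremes themselves are user data (e.g. curated from Viral
#' Zone); the package only derives the buffered bounds.
#'
#' @param path TSV file.
#' @return data.frame with columns `family`, `shortest`, `largest`,
#'   `min_len`, `max_len`.
#' @export
read_length_criteria <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (!is.numeric(d[[2]])) d <- d[-1, , drop = FALSE]  # header row
  d <- data.frame(family = as.character(d[[1]]),
                  shortest = as.numeric(d[[2]]),
                  largest = as.numeric(d[[3]]),
                  stringsAsFactors = FALSE)
  b <- t(mapply(compute_length_bounds, d$shortest, d$largest))
  d$min_len <- b[, 1]
  d$max_len <- b[, 2]
  d
}

#' Attach length criteria to sub-database specs
#'
#' @param specs data.frame from [parse_input_spec()].
#' @param criteria data.frame from [read_length_criteria()].
#' @return specs with `min_len`/`max_len` filled where the family is listed.
#' @export
attach_length_criteria <- function(specs, criteria) {
  i <- match(specs$name, criteria$family)
  specs$min_len <- ifelse(is.na(i), specs$min_len, criteria$min_len[i])
  specs$max_len <- ifelse(is.na(i), specs$max_len, criteria$max_len[i])
  specs
}

#' Filter records by sequence length
#'
#' Inclusive on both bounds; input order preserved.
#'
#' @param records a [sequence_records()] object.
#' @param bounds `c(min_len, max_len)`.
#' @return list with `kept`, `removed` (both `seq_records`) and `report`
#'   (accession, length, reason = "length" for removed rows).
#' @export
filter_by_length <- function(records, bounds) {
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[1] <= bounds[2])
  len <- nchar(records$sequence)
  ok <- len >= bounds[1] & len <= bounds[2]
  report <- data.frame(accession = records$accession[!ok],
                       length = len[!ok],
                       reason = rep("length", sum(!ok)),
                       stringsAsFactors = FALSE)
  list(kept = records[ok, , drop = FALSE],
       removed = records[!ok, , drop = FALSE],
       report = report)
}

#' Filter records by title completeness keywords
#'
#' Keeps entries whose description contains "genome" together with
#' "complete" (or, when `allow_partial`, "partial").  Case-insensitive.
#'
#' @param records a [sequence_records()] object.
#' @param allow_partial also accept titles declaring a partial genome.
#' @return list with `kept` and `removed`.
#' @export
filter_by_title <- function(records, allow_partial = FALSE) {
  d <- tolower(records$description)
  ok <- grepl("genome", d, fixed = TRUE) &
    (grepl("complete", d, fixed = TRUE) |
       (allow_partial & grepl("partial", d, fixed = TRUE)))
  list(kept = records[ok, , drop = FALSE],
       removed = records[!ok, , drop = FALSE])
}
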