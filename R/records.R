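#' Construct a set of annotated sequence records
#'
#' The central container of the package: one row per database entry, holding
#' the versioned accession, free-text description, organism name, NCBI
#' taxonomy id (0 when unknown), taxonomic lineage (a list column, possibly
#' empty), molecule type, the sequence itself (uppercase), and the
#' sub-database label the entry belongs to.
#'
#' @param accession character vector of versioned accessions (e.g.
#'   `"MF468140.1"`).
#' @param sequence character vector of sequences; stored uppercased.
#' @param description free-text entry titles. Default `""`.
#' @param organism species names. Default `""`.
#' @param taxid non-negative integer taxonomy ids; 0 means unknown.
#' @param lineage list of character vectors (taxonomy rank names, root first);
#'   empty vectors mean unknown lineage.
#' @param moltype `"nucleotide"` or `"protein"`, recycled.
#' @param subdb sub-database labels, recycled.
#' @return a `data.frame` of class `seq_records` with columns `accession`,
#'   `description`, `organism`, `taxid`, `lineage`, `moltype`, `sequence`,
#'   `subdb`.
#' @examples
#' r <- sequence_records("SYN1.1", "ACGTACGT", organism = "Synthvirus alpha",
#'                       taxid = 999001, subdb = "Synthviridae")
#' r$accession
#' @export
sequence_records <- function(accession, sequence, description = "",
                             organism = "", taxid = 0L,
                             lineage = list(character()),
                             moltype = "nucleotide", subdb = "") {
  n <- length(accession)
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) stop("sequences must be non-empty")
  moltype <- rep_len(moltype, n)
  if (!all(moltype %in% c("nucleotide", "protein")))
    stop("moltype must be 'nucleotide' or 'protein'")
  taxid <- as.integer(rep_len(taxid, n))
  if (any(is.na(taxid)) || any(taxid < 0L))
    stop("taxid must be a non-negative integer")
  bad <- moltype == "nucleotide" & !is_nucleotide_seq(sequence)
  if (any(bad))
    stop("non-IUPAC nucleotide characters in: ",
         paste(accession[bad], collapse = ", "))
  if (!is.list(lineage)) lineage <- list(lineage)
  lineage <- rep_len(lineage, n)
  out <- data.frame(
    accession = as.character(accession),
    description = rep_len(as.character(description), n),
    organism = rep_len(as.character(organism), n),
    taxid = taxid,
    moltype = moltype,
    sequence = sequence,
    subdb = rep_len(as.character(subdb), n),
    stringsAsFactors = FALSE
  )
  out$lineage <- lineage
  out <- out[, c("accession", "description", "organism", "taxid", "lineage",
                 "moltype", "sequence", "subdb")]
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Row-bind sequence record sets
#' @param ... `seq_records` objects.
#' @return a combined `seq_records` object.
#' @export
bind_records <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(parts)) return(empty_records())
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("seq_records", "data.frame")
  out
}

#' An empty record set
#' @return a `seq_records` object with zero rows.
#' @export
empty_records <- function() {
  out <- data.frame(accession = character(), description = character(),
                    organism = character(), taxid = integer(),
                    moltype = character(), sequence = character(),
                    subdb = character(), stringsAsFactors = FALSE)
  out$lineage <- list()
  out <- out[, c("accession", "description", "organism", "taxid", "lineage",
                 "moltype", "sequence", "subdb")]
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Keep each accession once across overlapping sub-databases
#'
#' Sub-database queries may overlap, so the same accession can be downloaded
#' into several sub-databases.  A classifier index needs unique templates, so
#' the concatenated database keeps the first occurrence in input order (the
#' first sub-database in the input file wins).
#'
#' @param records a `seq_records` object.
#' @return records with duplicate accessions dropped (first occurrence kept).
#' @export
concat_records <- function(records) {
  records[!duplicated(records$accession), , drop = FALSE]
}
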