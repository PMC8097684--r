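# Reading and writing: sub-database input files, GenBank flat files, and the
# package's annotated-FASTA dialect.

#' Parse a sub-database input file
#'
#' Each non-blank, non-comment line holds a sub-database name, a tab, and an
#' NCBI-style Boolean search string.  Names must be unique and contain no
#' whitespace.
#'
#' @param x path to the input file, or a character vector of lines.
#' @return a data.frame with columns `name`, `query`, `min_len`, `max_len`
#'   (NA unless length criteria are attached later) and `moltype`.
#' @examples
#' parse_input_spec("Coronaviridae\ttxid11118[Organism:exp]")
#' @export
parse_input_spec <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x, warn = FALSE) else x
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  name <- character(0); query <- character(0)
  for (i in keep) {
    line <- lines[i]
    if (!grepl("\t", line))
      stop("malformed input line ", i, ": expected <name><TAB><query>")
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    nm <- trimws(parts[1])
    qq <- trimws(paste(parts[-1], collapse = "\t"))
    if (!nzchar(nm) || grepl("\\s", nm))
      stop("malformed input line ", i, ": sub-database name must be a single token")
    if (!nzchar(qq))
      stop("malformed input line ", i, ": empty query")
    name <- c(name, nm); query <- c(query, qq)
  }
  if (anyDuplicated(name))
    stop("duplicate sub-database name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  data.frame(name = name, query = query,
             min_len = rep(NA_integer_, length(name)),
             max_len = rep(NA_integer_, length(name)),
             moltype = rep("nucleotide", length(name)),
             stringsAsFactors = FALSE)
}

#' Parse GenBank flat-file entries
#'
#' Parses the field subset needed for database construction: LOCUS,
#' DEFINITION, VERSION, ORGANISM (with lineage continuation lines), a
#' `/db_xref="taxon:N"` qualifier, and the ORIGIN sequence block.  Entries
#' missing ORIGIN or VERSION are skipped with a warning (strict mode turns
#' this into an error); live downloads can truncate, so tolerance is the
#' default.  A final entry with no `//` terminator is always an error.
#'
#' @param x path to a flat file, or a character vector of lines, or a single
#'   string containing the whole stream.
#' @param subdb sub-database label stamped on every returned record.
#' @param strict if TRUE, incomplete entries raise an error instead of a
#'   warning.
#' @return a [sequence_records()] object; the number of skipped entries is
#'   attached as attribute `"skipped"`.
#' @export
parse_genbank_records <- function(x, subdb = "", strict = FALSE) {
  lines <- genbank_lines(x)
  # drop leading blank lines between entries
  terms <- which(trimws(lines) == "//")
  starts <- c(1L, head(terms, -1) + 1L)
  if (length(lines)) {
    tail_lines <- if (length(terms)) lines[-seq_len(max(terms))] else lines
    if (any(grepl("^LOCUS", tail_lines)))
      stop("truncated final GenBank entry: no '//' terminator")
  }
  skipped <- 0L
  recs <- list()
  for (j in seq_along(terms)) {
    entry <- lines[starts[j]:(terms[j] - 1L)]
    rec <- tryCatch(parse_genbank_entry(entry, subdb),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      if (strict) stop("GenBank entry ", j, ": ", conditionMessage(rec))
      warning("skipping GenBank entry ", j, ": ", conditionMessage(rec),
              call. = FALSE)
      skipped <- skipped + 1L
    } else {
      recs[[length(recs) + 1L]] <- rec
    }
  }
  out <- do.call(bind_records, recs)
  attr(out, "skipped") <- skipped
  out
}

genbank_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  if (length(x) == 1 && grepl("\n", x))
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  as.character(x)
}

parse_genbank_entry <- function(entry, subdb) {
  field_val <- function(tag) {
    i <- grep(paste0("^", tag, "\\s"), entry)
    if (!length(i)) return(NA_character_)
    trimws(sub(paste0("^", tag, "\\s+"), "", entry[i[1]]))
  }
  version <- field_val("VERSION")
  if (is.na(version)) stop("missing VERSION")
  origin_i <- grep("^ORIGIN", entry)
  if (!length(origin_i)) stop("missing ORIGIN")

  # DEFINITION may continue over indented lines
  def_i <- grep("^DEFINITION", entry)
  description <- ""
  if (length(def_i)) {
    i <- def_i[1]
    parts <- sub("^DEFINITION\\s+", "", entry[i])
    while (i + 1L <= length(entry) && grepl("^\\s{10,}\\S", entry[i + 1L]) &&
           !grepl("^[A-Z]", entry[i + 1L])) {
      i <- i + 1L
      parts <- c(parts, trimws(entry[i]))
    }
    description <- sub("\\.$", "", paste(parts, collapse = " "))
  }

  org_i <- grep("^\\s{2,}ORGANISM\\s", entry)
  organism <- ""
  lineage <- character()
  if (length(org_i)) {
    organism <- trimws(sub("^\\s*ORGANISM\\s+", "", entry[org_i[1]]))
    i <- org_i[1] + 1L
    lin_lines <- character()
    while (i <= length(entry) && grepl("^\\s{10,}\\S", entry[i])) {
      lin_lines <- c(lin_lines, trimws(entry[i]))
      i <- i + 1L
    }
    if (length(lin_lines)) {
      lin <- sub("\\.$", "", paste(lin_lines, collapse = " "))
      lineage <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
      lineage <- lineage[nzchar(lineage)]
    }
  }

  taxid <- 0L
  tax_i <- grep("/db_xref=\"taxon:", entry, fixed = TRUE)
  if (length(tax_i)) {
    taxid <- as.integer(sub(".*taxon:([0-9]+).*", "\\1", entry[tax_i[1]]))
  }

  seq_lines <- entry[(origin_i[1] + 1L):length(entry)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("empty ORIGIN block")

  locus <- field_val("LOCUS")
  moltype <- if (!is.na(locus) && grepl("\\baa\\b", locus)) "protein" else "nucleotide"

  sequence_records(accession = version, sequence = sequence,
                   description = description, organism = organism,
                   taxid = taxid, lineage = list(lineage),
                   moltype = moltype, subdb = subdb)
}

annotated_header <- function(records) {
  paste(records$accession, records$subdb, records$taxid,
        gsub(" ", "_", records$organism), sep = "|")
}

#' Write records as annotated FASTA
#'
#' The header dialect is
#' `>{accession}|{subdb}|{taxid}|{organism_with_spaces_as_underscores}`,
#' with sequences wrapped at 70 columns.  Description and lineage are not
#' encoded in the header and are therefore not round-tripped.
#'
#' @param records a [sequence_records()] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_annotated_fasta <- function(records, path) {
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- annotated_header(records)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read annotated FASTA back into records
#'
#' @param path path to a FASTA file written by [write_annotated_fasta()].
#' @return a [sequence_records()] object (description empty, lineage empty).
#' @export
read_annotated_fasta <- function(path) {
  if (file.size(path) == 0) return(empty_records())
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) return(empty_records())
  fields <- strsplit(names(x), "|", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4))
    stop("malformed annotated-FASTA header (expected 4 '|' fields): ",
         names(x)[which(nf != 4)[1]])
  m <- do.call(rbind, fields)
  seqs <- toupper(as.character(x))
  sequence_records(accession = m[, 1], sequence = seqs,
                   organism = gsub("_", " ", m[, 4]),
                   taxid = as.integer(m[, 3]),
                   moltype = ifelse(is_nucleotide_seq(seqs),
                                    "nucleotide", "protein"),
                   subdb = m[, 2])
}

#' Read a plain FASTA file as named sequences
#' @param path FASTA file.
#' @return named character vector of uppercase sequences (first header token
#'   as name).
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
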