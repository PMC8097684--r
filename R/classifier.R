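# Kmer-based read/contig classification against a cleaned database: per-read
# best-hit assignment, per-template hit calling with coverage and identity
# thresholds, and family/species composition reports.

#' Assign one read to its best template
#'
#' For each template, counts how many of the read's canonical kmers (with
#' multiplicity) occur unmasked in that template; the template with the
#' highest count wins.  Ties are broken deterministically: fewer distinct
#' template kmers first (the more specific template), then the
#' lexicographically smaller accession; tied reads carry a tie flag.  A read
#' with no unmasked matching kmer, or shorter than k, is unassigned.
#'
#' @param read a single read/contig sequence.
#' @param index a [build_kmer_index()] object (optionally masked).
#' @return list with `template` (accession or NA), `matched`, `total`,
#'   `identity` (= matched/total), `tie` (logical), and `kmers`: the read's
#'   distinct unmasked canonical kmers (used for coverage aggregation).
#' @export
assign_read <- function(read, index) {
  assign_one(read, index, kmer_lookup_env(index))
}

# hashed kmer -> reference-set lookup, built once per read batch
kmer_lookup_env <- function(index) {
  if (length(index$kmer_refs)) list2env(index$kmer_refs, hash = TRUE)
  else new.env()
}

assign_one <- function(read, index, env) {
  km <- canonical_kmers(read, index$k)$kmer
  total <- length(km)
  unassigned <- list(template = NA_character_, matched = 0L, total = total,
                     identity = 0, tie = FALSE, kmers = character())
  if (!total) return(unassigned)
  if (length(index$masked)) km <- km[!(km %in% index$masked)]
  if (!length(km)) return(unassigned)
  refs <- unlist(mget(km, envir = env, ifnotfound = list(NULL)),
                 use.names = FALSE)
  if (!length(refs)) return(unassigned)
  counts <- table(refs)
  best_n <- max(counts)
  cands <- names(counts)[counts == best_n]
  tie <- length(cands) > 1
  if (tie) {
    nk <- vapply(cands, function(id) length(template_kmers(index, id)),
                 integer(1))
    cands <- cands[order(nk, cands)]
  }
  list(template = cands[1], matched = as.integer(best_n), total = total,
       identity = as.integer(best_n) / total, tie = tie,
       kmers = unique(km))
}

#' Assign a batch of reads
#'
#' @param reads named character vector of read sequences (names are read
#'   ids) or a data.frame with `id` and `sequence` columns.
#' @param index a `kmer_index`.
#' @return a data.frame of class `read_assignments` with one row per read
#'   (`id`, `template`, `matched`, `total`, `identity`, `tie`) and a
#'   list-column `kmers`.
#' @export
assign_reads <- function(reads, index) {
  if (is.data.frame(reads)) {
    ids <- reads$id
    seqs <- reads$sequence
  } else {
    ids <- names(reads) %||% as.character(seq_along(reads))
    seqs <- as.character(reads)
  }
  env <- kmer_lookup_env(index)
  res <- lapply(seqs, assign_one, index = index, env = env)
  out <- data.frame(
    id = ids,
    template = vapply(res, `[[`, character(1), "template"),
    matched = vapply(res, `[[`, integer(1), "matched"),
    total = vapply(res, `[[`, integer(1), "total"),
    identity = vapply(res, `[[`, numeric(1), "identity"),
    tie = vapply(res, `[[`, logical(1), "tie"),
    stringsAsFactors = FALSE
  )
  out$kmers <- lapply(res, `[[`, "kmers")
  class(out) <- c("read_assignments", "data.frame")
  out
}

#' Aggregate read assignments into per-template hits
#'
#' Template coverage is the fraction of the template's distinct unmasked
#' canonical kmers observed in at least one assigned read -- robust to read
#' overlap and masking, with no positional alignment required.  Template
#' identity is total matched kmers over total kmers across the assigned
#' reads.  A hit passes when both thresholds are met; failing templates are
#' still reported, flagged.
#'
#' @param assignments a [assign_reads()] result produced against `index`.
#' @param index the same `kmer_index`.
#' @param min_identity minimum template identity (default 0).
#' @param min_coverage minimum template coverage (default 0.8, the standard
#'   hit-calling threshold).
#' @param records optional `seq_records` supplying subdb/organism/taxid
#'   annotation per template accession.
#' @return data.frame with one row per template carrying assigned reads,
#'   sorted by mapped read count (descending) then accession: `template`,
#'   `subdb`, `organism`, `taxid`, `reads`, `coverage`, `identity`, `pass`.
#' @export
call_hits <- function(assignments, index, min_identity = 0,
                      min_coverage = 0.8, records = NULL) {
  a <- assignments[!is.na(assignments$template), , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(template = character(), subdb = character(),
                      organism = character(), taxid = integer(),
                      reads = integer(), coverage = numeric(),
                      identity = numeric(), pass = logical(),
                      stringsAsFactors = FALSE))
  }
  groups <- split(seq_len(nrow(a)), a$template)
  rows <- lapply(names(groups), function(tpl) {
    ii <- groups[[tpl]]
    tk <- template_kmers(index, tpl)
    seen <- unique(unlist(a$kmers[ii], use.names = FALSE))
    cov <- if (length(tk)) length(intersect(seen, tk)) / length(tk) else 0
    ident <- sum(a$matched[ii]) / sum(a$total[ii])
    data.frame(template = tpl, reads = length(ii), coverage = cov,
               identity = ident, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$reads, hits$template), , drop = FALSE]
  if (!is.null(records)) {
    i <- match(hits$template, records$accession)
    hits$subdb <- records$subdb[i]
    hits$organism <- records$organism[i]
    hits$taxid <- records$taxid[i]
  } else {
    hits$subdb <- NA_character_
    hits$organism <- NA_character_
    hits$taxid <- NA_integer_
  }
  hits$pass <- hits$coverage >= min_coverage & hits$identity >= min_identity
  rownames(hits) <- NULL
  hits[, c("template", "subdb", "organism", "taxid", "reads", "coverage",
           "identity", "pass")]
}

#' Sample composition at family or species level
#'
#' Fractions are computed over assigned reads only; unassigned reads are
#' counted separately.
#'
#' @param assignments a [assign_reads()] result.
#' @param records `seq_records` mapping template accessions to sub-database
#'   (family) and organism (species).
#' @param level `"family"` (sub-database label) or `"species"` (organism).
#' @return list with `level`, `fractions` (named numeric, sums to 1 when any
#'   read is assigned), `assigned` and `unassigned` counts.
#' @export
compose <- function(assignments, records, level = c("family", "species")) {
  level <- match.arg(level)
  assigned <- assignments[!is.na(assignments$template), , drop = FALSE]
  unassigned_n <- nrow(assignments) - nrow(assigned)
  if (!nrow(assigned))
    return(list(level = level, fractions = stats::setNames(numeric(0), character(0)),
                assigned = 0L, unassigned = unassigned_n))
  i <- match(assigned$template, records$accession)
  if (anyNA(i))
    stop("assigned template(s) missing from the database records: ",
         paste(unique(assigned$template[is.na(i)]), collapse = ", "))
  label <- if (level == "family") records$subdb[i] else records$organism[i]
  tab <- table(label)
  list(level = level,
       fractions = stats::setNames(as.numeric(tab) / nrow(assigned),
                                   names(tab)),
       assigned = nrow(assigned), unassigned = unassigned_n)
}

read_query_file <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  fmt <- if (length(first) && startsWith(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readBStringSet(path, format = fmt)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Classify a query file against a database directory
#'
#' End-to-end run: loads the concatenated database, builds (or reuses) the
#' kmer index, applies an optional host mask, assigns every read (FASTQ) or
#' contig (FASTA) through the same per-query path, calls template hits, and
#' writes text reports into `out_dir`: `hits.tsv`,
#' `composition_family.tsv`, `composition_species.tsv` and `run.log`
#' (including the masked-kmer fraction).
#'
#' @param db_dir database directory (from [download_database()] or the
#'   cleaning pipeline).
#' @param query_file FASTA or FASTQ query path (gzipped accepted).
#' @param out_dir output directory (default: inside `db_dir`).
#' @param k kmer length used to index (default 16).
#' @param host_mask optional FASTA path or named sequences to mask.
#' @param min_identity,min_coverage hit-calling thresholds (defaults 0 and
#'   0.8).
#' @return invisible list with `assignments`, `hits`, `composition_family`,
#'   `composition_species`, `masked_fraction`.
#' @export
classify_run <- function(db_dir, query_file, out_dir = file.path(db_dir, "results"),
                         k = 16, host_mask = NULL, min_identity = 0,
                         min_coverage = 0.8) {
  db_fasta <- file.path(db_dir, "db.fasta")
  if (!file.exists(db_fasta)) stop("unreadable database: no db.fasta in ", db_dir)
  records <- read_annotated_fasta(db_fasta)
  refs <- stats::setNames(records$sequence, records$accession)
  index <- build_kmer_index(refs, k = k)
  masked_fraction <- 0
  if (!is.null(host_mask)) {
    mask_seqs <- if (is.character(host_mask) && length(host_mask) == 1 &&
                     file.exists(host_mask)) read_fasta_seqs(host_mask)
                 else host_mask
    m <- mask_kmers(index, mask_seqs)
    index <- m$index
    masked_fraction <- m$masked_fraction
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  queries <- read_query_file(query_file)
  if (!length(queries)) {
    warning("empty query file: writing empty reports", call. = FALSE)
    assignments <- assign_reads(character(0), index)
  } else {
    assignments <- assign_reads(queries, index)
  }
  hits <- call_hits(assignments, index, min_identity = min_identity,
                    min_coverage = min_coverage, records = records)
  comp_f <- compose(assignments, records, "family")
  comp_s <- compose(assignments, records, "species")
  utils::write.table(hits, file.path(out_dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_composition <- function(comp, path) {
    d <- data.frame(label = names(comp$fractions),
                    fraction = as.numeric(comp$fractions),
                    stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_composition(comp_f, file.path(out_dir, "composition_family.tsv"))
  write_composition(comp_s, file.path(out_dir, "composition_species.tsv"))
  writeLines(c(
    paste0("queries\t", length(queries)),
    paste0("assigned\t", comp_f$assigned),
    paste0("unassigned\t", comp_f$unassigned),
    paste0("masked_kmer_fraction\t", format(masked_fraction, digits = 6)),
    paste0("passing_hits\t", sum(hits$pass))
  ), file.path(out_dir, "run.log"))
  invisible(list(assignments = assignments, hits = hits,
                 composition_family = comp_f, composition_species = comp_s,
                 masked_fraction = masked_fraction))
}
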