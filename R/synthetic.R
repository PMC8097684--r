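# Deterministic synthetic fixtures: random genomes, vector-spiked chimeras,
# wgsim-style reads with a substitution-only error model, GenBank flat-file
# emission, and a standard mock community so every pipeline stage is
# testable offline.

#' Generate a random genome
#'
#' Uniform i.i.d. A/C/G/T from a seeded generator; deterministic per
#' (length, seed) and independent of the caller's RNG state.
#'
#' @param length genome length in nt (>= 1).
#' @param seed integer seed.
#' @return a single nucleotide sequence string.
#' @export
random_genome <- function(length, seed) {
  if (length < 1) stop("length must be >= 1")
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""))
}

#' Splice an insert into a genome
#'
#' Builds a chimeric sequence carrying a foreign fragment (e.g. a cloning
#' vector or host segment), mimicking the misassembled composite entries
#' that motivate contamination screening.
#'
#' @param genome backbone sequence.
#' @param insert fragment to splice in.
#' @param position 0-based insertion point in `[0, nchar(genome)]`.
#' @return the chimeric sequence (length = backbone + insert).
#' @export
make_chimera <- function(genome, insert, position) {
  n <- nchar(genome)
  if (position < 0 || position > n) stop("position out of range [0, ", n, "]")
  paste0(substr(genome, 1, position), insert,
         substr(genome, position + 1, n))
}

#' Simulate shotgun reads (wgsim-style, substitutions only)
#'
#' Start positions are uniform over the genome, strand is uniform, and each
#' base is substituted with probability `error_rate` to a uniformly chosen
#' different base.  Paired mode emits a mate read at the far end of a
#' fragment of the stated insert size, on the opposite strand.  Read ids
#' encode the source genome, 0-based fragment start and strand
#' (`<genome>:<start>:<+/->[/1 or /2]`).  Deterministic per seed.
#'
#' @param genome source sequence (single string).
#' @param n number of reads (fragments, in paired mode).
#' @param read_length read length L (<= genome length).
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param seed integer seed.
#' @param genome_id label used in read ids.
#' @param paired emit mate pairs.
#' @param insert_size fragment length for paired mode (>= read_length).
#' @return data.frame with columns `id` and `sequence`.
#' @export
simulate_reads <- function(genome, n, read_length, error_rate = 0, seed = 1,
                           genome_id = "genome", paired = FALSE,
                           insert_size = 2 * read_length) {
  glen <- nchar(genome)
  if (read_length > glen) stop("read_length exceeds genome length")
  stopifnot(error_rate >= 0, error_rate < 1)
  if (paired) stopifnot(insert_size >= read_length, insert_size <= glen)
  with_seed(seed, {
    span <- if (paired) insert_size else read_length
    starts <- sample.int(glen - span + 1L, n, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    mutate <- function(seqs) {
      vapply(seqs, function(s) {
        if (error_rate == 0) return(s)
        ch <- strsplit(s, "")[[1]]
        hit <- which(stats::runif(length(ch)) < error_rate)
        for (i in hit) {
          ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
        }
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    fwd <- substring(genome, starts + 1L, starts + read_length)
    if (!paired) {
      raw <- ifelse(strands == "+", fwd, revcomp(fwd))
      ids <- paste0(genome_id, ":", starts, ":", strands)
      return(data.frame(id = ids, sequence = mutate(raw),
                        stringsAsFactors = FALSE))
    }
    mate <- substring(genome, starts + insert_size - read_length + 1L,
                      starts + insert_size)
    r1 <- ifelse(strands == "+", fwd, revcomp(mate))
    r2 <- ifelse(strands == "+", revcomp(mate), fwd)
    ids <- paste0(genome_id, ":", starts, ":", strands)
    data.frame(id = c(paste0(ids, "/1"), paste0(ids, "/2")),
               sequence = mutate(c(r1, r2)),
               stringsAsFactors = FALSE)[order(rep(seq_len(n), 2L)), ]
  })
}

#' Write simulated reads as FASTQ
#'
#' Quality strings are constant `"I"`; the error model lives in the
#' sequence, not the qualities.
#'
#' @param reads data.frame from [simulate_reads()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (!nrow(reads)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@", reads$id),
                           reads$sequence,
                           "+",
                           strrep("I", nchar(reads$sequence))))
  writeLines(lines, path)
  invisible(path)
}

#' Emit records as GenBank flat-file text
#'
#' Minimal well-formed entries (LOCUS, DEFINITION, ACCESSION, VERSION,
#' SOURCE/ORGANISM with lineage, a source feature with a taxon db_xref,
#' ORIGIN, `//`) that [parse_genbank_records()] reads back losslessly for
#' every record field.
#'
#' @param records a [sequence_records()] object.
#' @return a single string of flat-file text.
#' @export
emit_genbank_fixture <- function(records) {
  entries <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    bare <- strip_version(r$accession)
    unit <- if (r$moltype == "protein") "aa" else "bp"
    mol <- if (r$moltype == "protein") "" else "DNA     linear"
    lines <- c(
      sprintf("LOCUS       %-16s %d %s    %s   VRL 01-JAN-2020",
              bare, nchar(r$sequence), unit, mol),
      paste0("DEFINITION  ", r$description, "."),
      paste0("ACCESSION   ", bare),
      paste0("VERSION     ", r$accession),
      paste0("SOURCE      ", r$organism),
      paste0("  ORGANISM  ", r$organism)
    )
    lin <- r$lineage[[1]]
    if (length(lin))
      lines <- c(lines, paste0("            ",
                               paste(lin, collapse = "; "), "."))
    lines <- c(lines,
      "FEATURES             Location/Qualifiers",
      sprintf("     source          1..%d", nchar(r$sequence)),
      sprintf("                     /organism=\"%s\"", r$organism),
      sprintf("                     /db_xref=\"taxon:%d\"", r$taxid),
      "ORIGIN      ")
    s <- tolower(r$sequence)
    starts <- seq(1, nchar(s), by = 60)
    for (st in starts) {
      chunk <- substr(s, st, min(st + 59, nchar(s)))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
      lines <- c(lines, sprintf("%9d %s", st, paste(blocks, collapse = " ")))
    }
    paste(c(lines, "//"), collapse = "\n")
  }, character(1))
  paste0(paste(entries, collapse = "\n"), if (length(entries)) "\n" else "")
}

#' Build the standard synthetic mock community
#'
#' Five virus families with three genomes each (a miniature of the
#' paper-scale mixed viral sample), one host genome, two vector
#' contaminants, one vector-spiked chimeric database entry, and one
#' host-fragment chimeric entry (a mostly-host misassembly of the kind that
#' attracts host reads).  Fully deterministic for a given seed.
#'
#' @param seed integer base seed; all component seeds derive from it.
#' @param n_families number of families (default 5).
#' @param genomes_per_family genomes per family (default 3).
#' @param genome_length genome length in nt (default 3000).
#' @param host_length host genome length (default 20000).
#' @param vector_length contaminant vector length (default 600).
#' @return list with `records` (the database entries: the clean genomes plus
#'   the vector chimera), `host_chimera` (a one-row `seq_records` to append
#'   when a host-contaminated database is wanted), `host` (named host
#'   sequence), `contaminants` (named vector sequences), `specs` (the
#'   matching sub-database input specs) and `families`.
#' @export
make_mock_community <- function(seed = 1, n_families = 5,
                                genomes_per_family = 3,
                                genome_length = 3000,
                                host_length = 20000,
                                vector_length = 600) {
  seed <- as.integer(seed) %% 100000L
  families <- paste0("Synthviridae_", LETTERS[seq_len(n_families)])
  recs <- list()
  idx <- 0L
  for (f in seq_len(n_families)) {
    for (g in seq_len(genomes_per_family)) {
      idx <- idx + 1L
      acc <- sprintf("SYN%05d.1", idx)
      org <- sprintf("Synthvirus %s%d", letters[f], g)
      recs[[idx]] <- sequence_records(
        accession = acc,
        sequence = random_genome(genome_length, seed * 1000L + idx),
        description = paste0(org, ", complete genome"),
        organism = org,
        taxid = 999000L + f,
        lineage = list(c("Viruses", families[f])),
        subdb = families[f])
    }
  }
  records <- do.call(bind_records, recs)
  host <- random_genome(host_length, seed * 1000L + 777L)
  contaminants <- c(
    VEC001 = random_genome(vector_length, seed * 1000L + 888L),
    VEC002 = random_genome(vector_length, seed * 1000L + 889L)
  )
  # vector-spiked chimera: first family's backbone carrying a full vector copy
  vec_chimera <- sequence_records(
    accession = "SYNCHIM1.1",
    sequence = make_chimera(records$sequence[1], contaminants[["VEC001"]],
                            position = 500),
    description = "Synthvirus a1 clone, complete genome",
    organism = "Synthvirus a1",
    taxid = 999001L,
    lineage = list(c("Viruses", families[1])),
    subdb = families[1])
  # host-fragment chimera: a mostly-host misassembly labelled as a virus
  host_frag <- substr(host, 5001, 7000)
  host_chimera <- sequence_records(
    accession = "SYNCHIM2.1",
    sequence = paste0(substr(records$sequence[4], 1, 200), host_frag),
    description = "Synthvirus b1 unverified misassembly, complete genome",
    organism = "Synthvirus b1",
    taxid = 999002L,
    lineage = list(c("Viruses", families[2])),
    subdb = families[2])
  specs <- data.frame(
    name = families,
    query = paste0("txid", 999000L + seq_len(n_families), "[Organism:exp]"),
    min_len = NA_integer_, max_len = NA_integer_,
    moltype = "nucleotide", stringsAsFactors = FALSE)
  list(records = bind_records(records, vec_chimera),
       host_chimera = host_chimera,
       host = c(HOST1 = host),
       contaminants = contaminants,
       specs = specs,
       families = families)
}
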