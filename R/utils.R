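# Internal helpers shared across modules.

#' Reverse-complement of nucleotide strings
#'
#' Vectorised over full-length sequences; handles the IUPAC ambiguity codes.
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", x)
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Reverse-complement of equal-length ACGT-only kmers; avoids per-string
# splitting by pasting the k character columns in reverse order.
revcomp_kmers <- function(kmers, k) {
  if (!length(kmers)) return(character())
  comp <- chartr("ACGT", "TGCA", kmers)
  do.call(paste0, lapply(k:1, function(i) substring(comp, i, i)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Write lines to `path` atomically: write to a temp file in the same
# directory, then rename over the target.
atomic_write_lines <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("failed to commit file: ", path)
  }
  invisible(path)
}

# TRUE when a sequence uses nucleotide IUPAC codes only.
is_nucleotide_seq <- function(x) {
  !grepl("[^ACGTUMRWSYKVHDBN]", toupper(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
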