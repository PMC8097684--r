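# Versioned database manifest: membership per sub-database plus an
# append-only history log.  The on-disk layout is a tab-separated summary of
# the current version, one JSON object per history event, and per-version
# accession lists under versions/.

#' Create a database manifest
#'
#' @param membership named list mapping sub-database name to an ordered
#'   character vector of accessions.
#' @param timestamp timestamp string recorded on the initial add events.
#' @return an object of class `db_manifest` at version 1, with one `add`
#'   history event per accession.
#' @export
new_manifest <- function(membership = list(),
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  stopifnot(is.list(membership))
  history <- manifest_events(membership, action = "add", version = 1L,
                             timestamp = timestamp)
  m <- structure(list(version = 1L,
                      membership = membership,
                      history = history,
                      prior_versions = stats::setNames(list(membership), "1")),
                 class = "db_manifest")
  m
}

manifest_events <- function(membership, action, version, timestamp) {
  if (!length(membership) || !sum(lengths(membership)))
    return(empty_history())
  data.frame(
    timestamp = timestamp,
    version = as.integer(version),
    action = action,
    accession = unlist(membership, use.names = FALSE),
    subdb = rep(names(membership), lengths(membership)),
    stringsAsFactors = FALSE
  )
}

empty_history <- function() {
  data.frame(timestamp = character(), version = integer(),
             action = character(), accession = character(),
             subdb = character(), stringsAsFactors = FALSE)
}

#' Advance a manifest to a new version
#'
#' Applies per-sub-database add/remove sets, increments the version counter,
#' appends one history event per change, and archives the previous version's
#' membership.  History is append-only: prior events are never rewritten.
#'
#' @param manifest a `db_manifest`.
#' @param adds,removes named lists (sub-database -> accessions) of changes;
#'   either may be empty.
#' @param timestamp event timestamp string.
#' @return the updated manifest (new version), or the input unchanged when
#'   there is nothing to apply.
#' @export
manifest_advance <- function(manifest, adds = list(), removes = list(),
                             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  adds <- Filter(length, adds)
  removes <- Filter(length, removes)
  if (!length(adds) && !length(removes)) return(manifest)
  v <- manifest$version + 1L
  mem <- manifest$membership
  for (sd in names(removes)) {
    mem[[sd]] <- setdiff(mem[[sd]] %||% character(), removes[[sd]])
  }
  for (sd in names(adds)) {
    mem[[sd]] <- union(mem[[sd]] %||% character(), adds[[sd]])
  }
  mem <- Filter(length, mem)
  manifest$membership <- mem
  manifest$history <- rbind(
    manifest$history,
    manifest_events(removes, "remove", v, timestamp),
    manifest_events(adds, "add", v, timestamp)
  )
  rownames(manifest$history) <- NULL
  manifest$version <- v
  manifest$prior_versions[[as.character(v)]] <- mem
  manifest
}

#' Reconstruct membership at a version by replaying history
#'
#' @param manifest a `db_manifest`.
#' @param version version number to reconstruct (default: current).
#' @return named list of accession vectors.
#' @export
replay_history <- function(manifest, version = manifest$version) {
  h <- manifest$history
  h <- h[h$version <= version, , drop = FALSE]
  mem <- list()
  if (nrow(h)) for (i in seq_len(nrow(h))) {
    sd <- h$subdb[i]
    if (h$action[i] == "add")
      mem[[sd]] <- union(mem[[sd]] %||% character(), h$accession[i])
    else
      mem[[sd]] <- setdiff(mem[[sd]] %||% character(), h$accession[i])
  }
  Filter(length, mem)
}

#' Save a manifest to a database directory
#'
#' Writes `summary.tsv` (sub-database, accession rows for the current
#' version), `history.jsonl` (one JSON event per line) and
#' `versions/v<N>.tsv` accession lists for every stored version.
#'
#' @param manifest a `db_manifest`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_manifest <- function(manifest, dir) {
  dir.create(file.path(dir, "versions"), recursive = TRUE, showWarnings = FALSE)
  atomic_write_lines(membership_tsv(manifest$membership),
                     file.path(dir, "summary.tsv"))
  h <- manifest$history
  ev_lines <- vapply(seq_len(nrow(h)), function(i) {
    jsonlite::toJSON(as.list(h[i, ]), auto_unbox = TRUE)
  }, character(1))
  atomic_write_lines(ev_lines, file.path(dir, "history.jsonl"))
  for (v in names(manifest$prior_versions)) {
    atomic_write_lines(membership_tsv(manifest$prior_versions[[v]]),
                       file.path(dir, "versions", paste0("v", v, ".tsv")))
  }
  invisible(dir)
}

membership_tsv <- function(mem) {
  if (!length(mem)) return(character(0))
  paste(rep(names(mem), lengths(mem)), unlist(mem, use.names = FALSE),
        sep = "\t")
}

parse_membership_tsv <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sd <- vapply(parts, `[[`, character(1), 1)
  acc <- vapply(parts, `[[`, character(1), 2)
  lapply(split(acc, factor(sd, levels = unique(sd))), as.character)
}

#' Load a manifest from a database directory
#'
#' Validates that stored versions form a gap-free sequence 1..V.
#'
#' @param dir directory written by [save_manifest()].
#' @return a `db_manifest`.
#' @export
load_manifest <- function(dir) {
  summary_path <- file.path(dir, "summary.tsv")
  if (!file.exists(summary_path))
    stop("no manifest found in ", dir, " (missing summary.tsv)")
  membership <- parse_membership_tsv(readLines(summary_path, warn = FALSE))
  hist_lines <- readLines(file.path(dir, "history.jsonl"), warn = FALSE)
  hist_lines <- hist_lines[nzchar(hist_lines)]
  history <- if (length(hist_lines)) {
    do.call(rbind, lapply(hist_lines, function(l) {
      e <- jsonlite::fromJSON(l)
      data.frame(timestamp = e$timestamp, version = as.integer(e$version),
                 action = e$action, accession = e$accession, subdb = e$subdb,
                 stringsAsFactors = FALSE)
    }))
  } else empty_history()
  rownames(history) <- NULL
  vfiles <- list.files(file.path(dir, "versions"), pattern = "^v[0-9]+\\.tsv$")
  vnums <- sort(as.integer(sub("^v([0-9]+)\\.tsv$", "\\1", vfiles)))
  if (!length(vnums)) stop("no stored versions in ", dir)
  if (!identical(vnums, seq_len(max(vnums))))
    stop("version gap in manifest history: stored versions ",
         paste(vnums, collapse = ","))
  prior <- lapply(vnums, function(v) {
    parse_membership_tsv(readLines(
      file.path(dir, "versions", paste0("v", v, ".tsv")), warn = FALSE))
  })
  names(prior) <- as.character(vnums)
  structure(list(version = max(vnums), membership = membership,
                 history = history, prior_versions = prior),
            class = "db_manifest")
}

#' @export
print.db_manifest <- function(x, ...) {
  cat("<db_manifest> version", x$version, "-",
      length(x$membership), "sub-database(s),",
      sum(lengths(x$membership)), "accession(s),",
      nrow(x$history), "history event(s)\n")
  invisible(x)
}
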