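# Database directory lifecycle: initial download, diff-based update,
# rollback, purge.  Layout of a database directory:
#
#   summary.tsv, history.jsonl, versions/   -- manifest (see save_manifest)
#   archive.fasta    -- every record ever fetched (annotated FASTA); removed
#                       entries are archived, not deleted, so rollback never
#                       re-downloads.  `purge_archive()` reclaims space.
#   db.fasta         -- concatenated current database, one entry per
#                       accession (first sub-database wins)
#   subdb/<name>.fasta -- current per-sub-database FASTA
#   log.txt          -- append-only structured run log

db_log <- function(dir, stage, msg) {
  line <- paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg, sep = "\t")
  cat(line, "\n", sep = "", file = file.path(dir, "log.txt"), append = TRUE)
  invisible(line)
}

# Rewrite db.fasta and subdb/ from the archive according to membership,
# then save the manifest.  Files are committed via temp-and-rename.
db_write_state <- function(dir, manifest, archive) {
  dir.create(file.path(dir, "subdb"), recursive = TRUE, showWarnings = FALSE)
  save_manifest(manifest, dir)
  write_annotated_fasta(archive, file.path(dir, "archive.fasta"))
  current <- list()
  for (sd in names(manifest$membership)) {
    idx <- match(manifest$membership[[sd]], archive$accession)
    if (anyNA(idx))
      stop("archive is missing accession(s): ",
           paste(manifest$membership[[sd]][is.na(idx)], collapse = ", "))
    recs <- archive[idx, , drop = FALSE]
    recs$subdb <- sd
    write_annotated_fasta(recs, file.path(dir, "subdb", paste0(sd, ".fasta")))
    current[[sd]] <- recs
  }
  # remove per-subdb files for sub-databases no longer present
  stale <- setdiff(list.files(file.path(dir, "subdb"), pattern = "\\.fasta$"),
                   paste0(names(manifest$membership), ".fasta"))
  unlink(file.path(dir, "subdb", stale))
  concat <- concat_records(do.call(bind_records, current))
  write_annotated_fasta(concat, file.path(dir, "db.fasta"))
  invisible(dir)
}

db_read_archive <- function(dir) {
  p <- file.path(dir, "archive.fasta")
  if (!file.exists(p)) return(empty_records())
  read_annotated_fasta(p)
}

#' Build a database directory from scratch
#'
#' Runs [download_subdatabase()] for every spec, verifies each download, and
#' writes version 1 of the database.
#'
#' @param specs data.frame from [parse_input_spec()].
#' @param fetcher an EntryFetcher.
#' @param dir target directory (created).
#' @param flags a [query_flags()] object applied to every query.
#' @param batch_size,retries,delay passed to [download_subdatabase()].
#' @return the version-1 `db_manifest`, invisibly.
#' @export
download_database <- function(specs, fetcher, dir, flags = query_flags(),
                              batch_size = 100, retries = 3, delay = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  membership <- list()
  all_recs <- list()
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    dl <- download_subdatabase(spec, fetcher, flags = flags,
                               batch_size = batch_size, retries = retries,
                               delay = delay)
    rep <- verify_download(dl$records, dl$accessions)
    if (!rep$count_ok)
      stop("download verification failed for ", spec$name,
           "; missing: ", paste(rep$missing, collapse = ","),
           "; unexpected: ", paste(rep$unexpected, collapse = ","))
    membership[[spec$name]] <- dl$accessions
    all_recs[[spec$name]] <- dl$records
    db_log(dir, "download", paste0(spec$name, "\t", length(dl$accessions),
                                   " entries"))
  }
  archive <- concat_records(do.call(bind_records, all_recs))
  manifest <- new_manifest(membership)
  db_write_state(dir, manifest, archive)
  invisible(manifest)
}

#' Diff two accession sets into an update plan
#'
#' @param old accessions in the current database version.
#' @param new accessions matching the search now.
#' @return list with `to_add` (new minus old) and `to_remove` (old minus
#'   new), both sorted.
#' @examples
#' compute_update_plan(c("A.1", "B.1"), c("B.1", "C.1"))
#' @export
compute_update_plan <- function(old, new) {
  list(to_add = sort(setdiff(new, old)),
       to_remove = sort(setdiff(old, new)))
}

#' Apply an update plan to a database directory
#'
#' Fetches only the accessions to add (and among those, only the ones not
#' already archived locally), drops removed accessions from the current
#' FASTA files and membership, advances the manifest by one version with one
#' history event per change, and preserves the previous version's accession
#' lists.  An empty plan leaves the directory untouched.  Fetch failures
#' abort before any file is modified, so there is no partial commit.
#'
#' @param dir database directory.
#' @param plans named list (sub-database -> plan from
#'   [compute_update_plan()]).
#' @param fetcher an EntryFetcher (only consulted for `to_add`).
#' @param batch_size,retries passed to the fetch loop.
#' @return the resulting `db_manifest`, invisibly.
#' @export
apply_update <- function(dir, plans, fetcher, batch_size = 100, retries = 3) {
  manifest <- load_manifest(dir)
  archive <- db_read_archive(dir)
  adds <- lapply(plans, `[[`, "to_add")
  removes <- lapply(plans, `[[`, "to_remove")
  if (!sum(lengths(adds)) && !sum(lengths(removes))) {
    db_log(dir, "update", "no changes")
    return(invisible(manifest))
  }
  need <- setdiff(unique(unlist(adds, use.names = FALSE)), archive$accession)
  if (length(need)) {
    got <- fetch_accessions(fetcher, need, batch_size, retries)
    archive <- concat_records(bind_records(archive, got))
  }
  manifest <- manifest_advance(manifest, adds = adds, removes = removes)
  db_write_state(dir, manifest, archive)
  n_add <- sum(lengths(adds)); n_rm <- sum(lengths(removes))
  db_log(dir, "update", paste0("v", manifest$version, "\t+", n_add,
                               "\t-", n_rm, "\tfetched ", length(need)))
  invisible(manifest)
}

# batched fetch of explicit accessions, with retry; used by apply_update
fetch_accessions <- function(fetcher, accessions, batch_size = 100,
                             retries = 3) {
  batches <- split(accessions, ceiling(seq_along(accessions) / batch_size))
  parts <- lapply(batches, function(want) {
    for (attempt in seq_len(retries + 1L)) {
      res <- tryCatch({
        recs <- suppressWarnings(parse_genbank_records(fetcher$fetch_batch(want)))
        if (!setequal(recs$accession, want)) stop("batch content mismatch")
        recs
      }, error = function(e) e)
      if (!inherits(res, "error")) return(res)
    }
    stop("fetch failed after ", retries, " retries; missing accessions: ",
         paste(want, collapse = ", "))
  })
  do.call(bind_records, parts)
}

#' Re-run searches and update a database in place
#'
#' For each spec, compares the current search result with the stored
#' membership ([compute_update_plan()]) and applies the combined plan.
#' Running twice against an unchanged remote store is a no-op.
#'
#' @param dir database directory.
#' @param specs data.frame from [parse_input_spec()].
#' @param fetcher an EntryFetcher.
#' @param flags a [query_flags()] object.
#' @param batch_size,retries passed through.
#' @return the resulting `db_manifest`, invisibly.
#' @export
update_database <- function(dir, specs, fetcher, flags = query_flags(),
                            batch_size = 100, retries = 3) {
  manifest <- load_manifest(dir)
  plans <- list()
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    new_accs <- fetcher$search(augment_query(spec, flags))
    old_accs <- manifest$membership[[spec$name]] %||% character()
    plans[[spec$name]] <- compute_update_plan(old_accs, new_accs)
  }
  apply_update(dir, plans, fetcher, batch_size = batch_size, retries = retries)
}

#' Roll a database back to an earlier version
#'
#' Restores the target version's membership as a *new* version (the counter
#' still increases and the history records the restoring add/remove events),
#' so history remains append-only and replayable.  Sequences come from the
#' local archive; nothing is re-downloaded.
#'
#' @param dir database directory.
#' @param target_version version number to restore.
#' @return the resulting `db_manifest`, invisibly.
#' @export
rollback_database <- function(dir, target_version) {
  manifest <- load_manifest(dir)
  key <- as.character(target_version)
  if (!key %in% names(manifest$prior_versions))
    stop("unknown version: ", target_version)
  target <- manifest$prior_versions[[key]]
  archive <- db_read_archive(dir)
  want <- unique(unlist(target, use.names = FALSE))
  miss <- setdiff(want, archive$accession)
  if (length(miss))
    stop("archived sequence(s) missing (purged?): ",
         paste(miss, collapse = ", "))
  cur <- manifest$membership
  subdbs <- union(names(cur), names(target))
  adds <- removes <- list()
  for (sd in subdbs) {
    adds[[sd]] <- setdiff(target[[sd]] %||% character(),
                          cur[[sd]] %||% character())
    removes[[sd]] <- setdiff(cur[[sd]] %||% character(),
                             target[[sd]] %||% character())
  }
  v_before <- manifest$version
  manifest <- manifest_advance(manifest, adds = adds, removes = removes)
  if (manifest$version == v_before) {
    # membership identical: still record a new version, per rollback contract
    v <- v_before + 1L
    manifest$version <- v
    manifest$prior_versions[[as.character(v)]] <- manifest$membership
  }
  # force membership order to match the target exactly
  manifest$membership <- target
  manifest$prior_versions[[as.character(manifest$version)]] <- target
  db_write_state(dir, manifest, archive)
  db_log(dir, "rollback", paste0("to v", target_version, " as v",
                                 manifest$version))
  invisible(manifest)
}

#' Drop archived sequences not in the current membership
#'
#' After a purge, rollback to versions whose entries were purged fails with
#' an explicit error.
#'
#' @param dir database directory.
#' @return number of purged entries, invisibly.
#' @export
purge_archive <- function(dir) {
  manifest <- load_manifest(dir)
  archive <- db_read_archive(dir)
  keep <- unique(unlist(manifest$membership, use.names = FALSE))
  drop_n <- sum(!archive$accession %in% keep)
  archive <- archive[archive$accession %in% keep, , drop = FALSE]
  write_annotated_fasta(archive, file.path(dir, "archive.fasta"))
  db_log(dir, "purge", paste(drop_n, "archived entries removed"))
  invisible(drop_n)
}
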