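make_db <- function(mc, dir, batch_size = 10) {
  fx <- fixture_fetcher(mc$records)
  download_database(mc$specs, fx, dir, batch_size = batch_size)
  fx
}

test_that("update plans are plain set algebra", {
  expect_equal(compute_update_plan(c("A", "B"), c("B", "C")),
               list(to_add = "C", to_remove = "A"))
  expect_equal(compute_update_plan(c("A", "B"), c("A", "B")),
               list(to_add = character(0), to_remove = character(0)))
  expect_equal(compute_update_plan(character(0), c("B", "A")),
               list(to_add = c("A", "B"), to_remove = character(0)))

  # randomized against direct membership arithmetic
  for (s in 1:20) {
    set.seed(s)
    pool <- sprintf("ACC%03d.1", 1:40)
    old <- sample(pool, sample(0:30, 1))
    new <- sample(pool, sample(0:30, 1))
    plan <- compute_update_plan(old, new)
    expect_setequal(plan$to_add, new[!new %in% old])
    expect_setequal(plan$to_remove, old[!old %in% new])
    expect_equal(plan$to_add, sort(plan$to_add))
    expect_setequal(union(setdiff(old, plan$to_remove), plan$to_add), new)
  }
})

test_that("apply_update fetches only additions and is idempotent", {
  mc <- make_mock_community(7)
  dir <- withr::local_tempdir()
  fx <- make_db(mc, dir)

  fetched <- character(0)
  spy <- list(search = fx$search,
              fetch_batch = function(a) { fetched <<- c(fetched, a); fx$fetch_batch(a) })

  # empty plan: version unchanged, no events added
  m0 <- load_manifest(dir)
  m1 <- apply_update(dir, list(Synthviridae_A = compute_update_plan("X.1", "X.1")),
                     spy)
  expect_equal(m1$version, m0$version)
  expect_equal(nrow(m1$history), nrow(m0$history))
  expect_equal(fetched, character(0))

  # drop one accession, pretend a new remote entry appeared
  fam_a <- m0$membership$Synthviridae_A
  plan <- compute_update_plan(fam_a, c(fam_a[-1], "SYN00099.1"))
  universe2 <- bind_records(
    mc$records,
    sequence_records("SYN00099.1", rand_seq(3000, 99),
                     description = "Synthvirus a99, complete genome",
                     organism = "Synthvirus a99", taxid = 999001,
                     subdb = "Synthviridae_A"))
  fx2 <- fixture_fetcher(universe2)
  fetched <- character(0)
  spy2 <- list(search = fx2$search,
               fetch_batch = function(a) { fetched <<- c(fetched, a); fx2$fetch_batch(a) })
  m2 <- apply_update(dir, list(Synthviridae_A = plan), spy2)
  expect_equal(m2$version, m0$version + 1L)
  expect_setequal(m2$membership$Synthviridae_A, c(fam_a[-1], "SYN00099.1"))
  expect_equal(fetched, "SYN00099.1")  # only the addition, never the rest
  ev <- m2$history[m2$history$version == m2$version, ]
  expect_equal(sort(ev$action), c("add", "remove"))

  # a second application of the same (old, new) pair is a no-op
  new_accs <- fx2$search(augment_query(mc$specs[1, ], query_flags()))
  plan2 <- compute_update_plan(m2$membership$Synthviridae_A, new_accs)
  m3 <- apply_update(dir, list(Synthviridae_A = plan2), spy2)
  m4 <- apply_update(dir, list(Synthviridae_A = compute_update_plan(
    m3$membership$Synthviridae_A, new_accs)), spy2)
  expect_equal(m4$version, m3$version)
  expect_equal(m4$membership, m3$membership)
})

test_that("update_database twice against an unchanged store is a no-op", {
  mc <- make_mock_community(8)
  dir <- withr::local_tempdir()
  fx <- make_db(mc, dir)
  m1 <- update_database(dir, mc$specs, fx)
  expect_equal(m1$version, 1L)
  before <- readLines(file.path(dir, "db.fasta"))
  m2 <- update_database(dir, mc$specs, fx)
  expect_equal(m2$version, 1L)
  expect_equal(readLines(file.path(dir, "db.fasta")), before)
})

test_that("fetch failure leaves the database directory unchanged", {
  mc <- make_mock_community(9)
  dir <- withr::local_tempdir()
  make_db(mc, dir)
  before_summary <- readLines(file.path(dir, "summary.tsv"))
  before_db <- readLines(file.path(dir, "db.fasta"))
  dead <- list(search = function(q) character(0),
               fetch_batch = function(a) stop("network down"))
  plan <- compute_update_plan(character(0), "NEW00001.1")
  expect_error(apply_update(dir, list(Synthviridae_A = plan), dead, retries = 1),
               "missing accessions")
  expect_equal(readLines(file.path(dir, "summary.tsv")), before_summary)
  expect_equal(readLines(file.path(dir, "db.fasta")), before_db)
})

test_that("rollback restores any prior membership as a new version", {
  mc <- make_mock_community(10)
  dir <- withr::local_tempdir()
  fx <- make_db(mc, dir)
  m1 <- load_manifest(dir)
  fam_a <- m1$membership$Synthviridae_A

  # v2 removes one entry
  plan <- compute_update_plan(fam_a, fam_a[-1])
  m2 <- apply_update(dir, list(Synthviridae_A = plan), fx)
  expect_equal(m2$version, 2L)
  expect_false(fam_a[1] %in% m2$membership$Synthviridae_A)

  # rollback to v1: new version, original membership, no re-download
  dead <- list(search = fx$search,
               fetch_batch = function(a) stop("must not fetch"))
  m3 <- rollback_database(dir, 1)
  expect_equal(m3$version, 3L)
  expect_equal(m3$membership, m1$membership)
  db <- read_annotated_fasta(file.path(dir, "db.fasta"))
  expect_true(fam_a[1] %in% db$accession)

  # rollback to the current version still mints a new version
  m4 <- rollback_database(dir, 3)
  expect_equal(m4$version, 4L)
  expect_equal(m4$membership, m3$membership)

  expect_error(rollback_database(dir, 9), "unknown version")
})

test_that("membership is reconstructible by replaying history", {
  mc <- make_mock_community(11)
  dir <- withr::local_tempdir()
  fx <- make_db(mc, dir)
  fam_a <- load_manifest(dir)$membership$Synthviridae_A
  apply_update(dir, list(Synthviridae_A = compute_update_plan(fam_a, fam_a[-2])), fx)
  rollback_database(dir, 1)
  m <- load_manifest(dir)
  for (v in seq_len(m$version)) {
    replayed <- replay_history(m, v)
    stored <- m$prior_versions[[as.character(v)]]
    expect_setequal(names(replayed), names(stored))
    for (sd in names(stored))
      expect_setequal(replayed[[sd]], stored[[sd]])
  }
})

test_that("purge drops archived entries and blocks rollback past them", {
  mc <- make_mock_community(12)
  dir <- withr::local_tempdir()
  fx <- make_db(mc, dir)
  fam_a <- load_manifest(dir)$membership$Synthviridae_A
  apply_update(dir, list(Synthviridae_A = compute_update_plan(fam_a, fam_a[-1])), fx)
  n <- purge_archive(dir)
  expect_equal(n, 1L)
  expect_error(rollback_database(dir, 1), "missing")
})
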