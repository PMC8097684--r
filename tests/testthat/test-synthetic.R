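test_that("random genomes are deterministic per (length, seed)", {
  expect_identical(random_genome(100, 1), random_genome(100, 1))
  expect_false(identical(random_genome(100, 1), random_genome(100, 2)))
  expect_match(random_genome(1, 3), "^[ACGT]$")
  expect_error(random_genome(0, 1), "length")
  # generation does not disturb the caller's RNG stream
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(random_genome(50, 5))
  expect_identical(runif(1), a)
})

test_that("chimera splicing respects position and length", {
  g <- rand_seq(50, 11)
  ins <- rand_seq(10, 12)
  expect_equal(make_chimera(g, ins, 0), paste0(ins, g))
  expect_equal(make_chimera(g, ins, 50), paste0(g, ins))
  mid <- make_chimera(g, ins, 20)
  expect_equal(nchar(mid), 60)
  expect_equal(substr(mid, 21, 30), ins)
  expect_error(make_chimera(g, ins, 51), "position")

  # a spliced-in insert is fully covered as a contaminant
  big_ins <- rand_seq(60, 13)
  chim <- make_chimera(rand_seq(500, 14), big_ins, 250)
  idx <- build_kmer_index(c(ins = big_ins), k = 16)
  expect_equal(reference_coverage(chim, idx, "ins"), 1.0)
})

test_that("error-free reads are exact substrings of the genome or its rc", {
  g <- rand_seq(400, 21)
  reads <- simulate_reads(g, 50, 60, 0, seed = 22, genome_id = "g")
  rc <- revcomp_oracle(g)
  for (i in seq_len(nrow(reads))) {
    expect_true(grepl(reads$sequence[i], g, fixed = TRUE) ||
                  grepl(reads$sequence[i], rc, fixed = TRUE))
  }
  # ids encode genome, start and strand
  expect_match(reads$id, "^g:[0-9]+:[+-]$")
  # start positions match the forward-strand reads
  fwd <- grepl(":\\+$", reads$id)
  starts <- as.integer(sub("^g:([0-9]+):.*$", "\\1", reads$id))
  expect_equal(reads$sequence[fwd],
               substring(g, starts[fwd] + 1, starts[fwd] + 60))
})

test_that("substitution rate concentrates around the requested error", {
  g <- rand_seq(1000, 31)
  reads <- simulate_reads(g, 1000, 100, 0.02, seed = 32, genome_id = "g")
  starts <- as.integer(sub("^g:([0-9]+):.*$", "\\1", reads$id))
  fwd <- grepl(":\\+$", reads$id)
  mism <- vapply(which(fwd), function(i) {
    truth <- substring(g, starts[i] + 1, starts[i] + 100)
    sum(utf8ToInt(truth) != utf8ToInt(reads$sequence[i]))
  }, numeric(1))
  rate <- sum(mism) / (100 * length(mism))
  expect_equal(rate, 0.02, tolerance = 0.25)
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.025)
})

test_that("read simulation is byte-deterministic per seed", {
  g <- rand_seq(300, 41)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(g, 20, 50, 0.05, seed = 42, paired = TRUE,
                             insert_size = 150), f1)
  write_fastq(simulate_reads(g, 20, 50, 0.05, seed = 42, paired = TRUE,
                             insert_size = 150), f2)
  expect_identical(readLines(f1), readLines(f2))
  # paired mode: two reads per fragment, mates tagged /1 and /2
  reads <- simulate_reads(g, 20, 50, 0, seed = 42, paired = TRUE,
                          insert_size = 150)
  expect_equal(nrow(reads), 40)
  expect_equal(sum(grepl("/1$", reads$id)), 20)
  expect_error(simulate_reads(g, 5, 400, 0, seed = 1), "read_length")
})

test_that("paired mates sit at the insert distance on opposite strands", {
  g <- rand_seq(500, 51)
  reads <- simulate_reads(g, 30, 50, 0, seed = 52, paired = TRUE,
                          insert_size = 200, genome_id = "g")
  r1 <- reads[grepl("/1$", reads$id), ]
  r2 <- reads[grepl("/2$", reads$id), ]
  starts <- as.integer(sub("^g:([0-9]+):.*/1$", "\\1", r1$id))
  plus <- grepl(":\\+/1$", r1$id)
  expect_equal(r1$sequence[plus], substring(g, starts[plus] + 1, starts[plus] + 50))
  expect_equal(r2$sequence[plus],
               vapply(which(plus), function(i)
                 revcomp_oracle(substring(g, starts[i] + 151, starts[i] + 200)),
                 character(1)))
})

test_that("GenBank fixture emission round-trips all record fields", {
  for (s in c(1, 2)) {
    r <- random_records(20, seed = 60 + s)
    p <- parse_genbank_records(emit_genbank_fixture(r), subdb = "TestDB")
    for (col in c("accession", "description", "organism", "taxid",
                  "moltype", "sequence", "subdb"))
      expect_equal(p[[col]], r[[col]], info = col)
    expect_equal(p$lineage, r$lineage)
  }
  # single record -> exactly one terminator
  one <- emit_genbank_fixture(random_records(1, seed = 63))
  expect_equal(length(gregexpr("\n//", one)[[1]]), 1L)
  # empty lineage is omitted yet still parses
  nl <- sequence_records("NOLIN.1", rand_seq(40, 64), organism = "X virus",
                         description = "X virus, complete genome",
                         lineage = list(character()), subdb = "D")
  p <- parse_genbank_records(emit_genbank_fixture(nl), subdb = "D")
  expect_equal(p$lineage[[1]], character(0))
})

test_that("the mock community is deterministic and correctly shaped", {
  a <- make_mock_community(1)
  b <- make_mock_community(1)
  expect_identical(a$records$sequence, b$records$sequence)
  expect_identical(a$host, b$host)
  expect_false(identical(make_mock_community(2)$host, a$host))

  expect_equal(length(a$families), 5)
  expect_equal(sum(a$records$accession != "SYNCHIM1.1"), 15)
  expect_equal(length(a$contaminants), 2)
  expect_equal(nrow(a$host_chimera), 1)
  # the vector chimera carries a full copy of the first contaminant
  idx <- build_kmer_index(a$contaminants, k = 16)
  chim_seq <- a$records$sequence[a$records$accession == "SYNCHIM1.1"]
  expect_equal(reference_coverage(chim_seq, idx, "VEC001"), 1.0)
  # the host chimera is dominated by host sequence
  hidx <- build_kmer_index(stats::setNames(a$host_chimera$sequence, "HC"), 16)
  expect_gt(mask_kmers(hidx, a$host[[1]])$masked_fraction, 0.8)
})
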