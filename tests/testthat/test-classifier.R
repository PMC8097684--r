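test_that("read assignment counts matched kmers and applies the tie rule", {
  idx <- build_kmer_index(c(R1 = strrep("A", 10)), k = 3)
  a <- assign_read("AAAA", idx)
  expect_equal(a$template, "R1")
  expect_equal(a$matched, 2L)
  expect_equal(a$total, 2L)
  expect_equal(a$identity, 1.0)

  # canonical CCC == GGG which is absent from a poly-A index
  expect_true(is.na(assign_read("CCCC", idx)$template))

  # identical templates: lexicographically smaller accession wins, tie flagged
  s <- rand_seq(50, 301)
  idx2 <- build_kmer_index(c(B.1 = s, A.1 = s), k = 16)
  t2 <- assign_read(substr(s, 1, 30), idx2)
  expect_equal(t2$template, "A.1")
  expect_true(t2$tie)

  # read shorter than k is unassigned with total 0
  short <- assign_read("ACG", build_kmer_index(c(R = s), k = 16))
  expect_true(is.na(short$template))
  expect_equal(short$total, 0L)
})

test_that("tie-break prefers the template with fewer distinct kmers", {
  core <- rand_seq(40, 311)
  small <- core
  big <- paste0(core, rand_seq(60, 312))
  idx <- build_kmer_index(c(ZSMALL = small, ABIG = big), k = 16)
  a <- assign_read(core, idx)  # matches both with equal counts
  expect_true(a$tie)
  expect_equal(a$template, "ZSMALL")  # specificity beats accession order
})

test_that("hit calling aggregates coverage and identity per template", {
  tpl <- rand_seq(500, 321)
  idx <- build_kmer_index(c(T1 = tpl), k = 16)

  # error-free reads tiling the template end to end, overlapping by k-1 so
  # junction kmers are seen too
  starts <- unique(c(seq(1, 451, by = 35), 451))
  reads <- stats::setNames(substring(tpl, starts, starts + 49),
                           paste0("r", seq_along(starts)))
  asg <- assign_reads(reads, idx)
  hits <- call_hits(asg, idx, min_coverage = 0.8)
  expect_equal(hits$template, "T1")
  expect_equal(hits$coverage, 1.0)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$reads, length(reads))
  expect_true(hits$pass)

  # reads from only the first half cover about half the distinct kmers
  half_reads <- stats::setNames(substring(tpl, seq(1, 201, 25),
                                          seq(1, 201, 25) + 49), paste0("h", 1:9))
  h2 <- call_hits(assign_reads(half_reads, idx), idx, min_coverage = 0.8)
  seen <- unique(unlist(lapply(half_reads, function(r)
    canonical_kmers(r, 16)$kmer)))
  oracle_cov <- length(intersect(seen, unique(canonical_kmers(tpl, 16)$kmer))) /
    length(unique(canonical_kmers(tpl, 16)$kmer))
  expect_equal(h2$coverage, oracle_cov)
  expect_lt(h2$coverage, 0.8)
  expect_false(h2$pass)

  # no assigned reads -> empty hit list
  none <- assign_reads(c(x = rand_seq(50, 322)), idx)
  expect_equal(nrow(call_hits(none, idx)), 0)
})

test_that("composition fractions are computed over assigned reads", {
  mc <- make_mock_community(41)
  recs <- mc$records[1:6, ]  # families A and B
  idx <- build_kmer_index(stats::setNames(recs$sequence, recs$accession), 16)
  reads <- c(
    stats::setNames(substring(recs$sequence[1], 1 + 36 * (0:79), 100 + 36 * (0:79)),
                    paste0("a", 1:80)),
    stats::setNames(substring(recs$sequence[4], 1 + 36 * (0:19), 100 + 36 * (0:19)),
                    paste0("b", 1:20)))
  asg <- assign_reads(reads, idx)
  comp <- compose(asg, recs, "family")
  expect_equal(unname(comp$fractions["Synthviridae_A"]), 0.8)
  expect_equal(unname(comp$fractions["Synthviridae_B"]), 0.2)
  expect_equal(sum(comp$fractions), 1.0)

  # all-unassigned input
  noise <- assign_reads(c(n1 = rand_seq(100, 900), n2 = rand_seq(100, 901)), idx)
  comp0 <- compose(noise, recs, "family")
  expect_equal(length(comp0$fractions), 0)
  expect_equal(comp0$unassigned, 2L)

  # assigned template missing from the annotation is an error naming it
  bad <- asg[1, ]
  bad$template <- "GHOST.1"
  expect_error(compose(bad, recs, "family"), "GHOST.1")
})

test_that("error-free reads return to their source when templates are unique", {
  mc <- make_mock_community(43)
  recs <- mc$records[1:15, ]
  idx <- build_kmer_index(stats::setNames(recs$sequence, recs$accession), 16)
  for (s in c(1, 2)) {
    for (g in c(1, 8, 15)) {
      reads <- simulate_reads(recs$sequence[g], 30, 100, 0, seed = 1000 * s + g,
                              genome_id = recs$accession[g])
      asg <- assign_reads(stats::setNames(reads$sequence, reads$id), idx)
      expect_true(all(asg$template == recs$accession[g]))
    }
  }
})

test_that("mean read identity decreases with the substitution rate", {
  mc <- make_mock_community(44)
  recs <- mc$records[1:5, ]
  idx <- build_kmer_index(stats::setNames(recs$sequence, recs$accession), 16)
  mean_ident <- vapply(c(0, 0.01, 0.05), function(e) {
    reads <- simulate_reads(recs$sequence[1], 80, 100, e, seed = 77)
    mean(assign_reads(stats::setNames(reads$sequence, reads$id), idx)$identity)
  }, numeric(1))
  expect_true(all(diff(mean_ident) < 0))
})

test_that("classify_run produces reports for FASTQ and FASTA inputs", {
  mc <- make_mock_community(45)
  dir <- withr::local_tempdir()
  download_database(mc$specs, fixture_fetcher(mc$records), dir)
  recs <- read_annotated_fasta(file.path(dir, "db.fasta"))
  cleaned <- clean_records(recs, contaminants = mc$contaminants)$kept
  write_annotated_fasta(cleaned, file.path(dir, "db.fasta"))

  reads <- do.call(rbind, lapply(c(1, 4), function(i)
    simulate_reads(mc$records$sequence[i], 150, 100, 0, seed = 4500 + i,
                   genome_id = mc$records$accession[i])))
  qf <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, qf)
  out <- classify_run(dir, qf)
  expect_true(file.exists(file.path(dir, "results", "hits.tsv")))
  expect_setequal(out$hits$template[out$hits$pass],
                  mc$records$accession[c(1, 4)])
  expect_equal(out$composition_family$assigned, nrow(reads))

  # FASTA contig input: the verbatim template comes back at coverage 1
  cf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">contig1", mc$records$sequence[7]), cf)
  out2 <- classify_run(dir, cf, out_dir = withr::local_tempdir())
  expect_equal(out2$hits$template[1], mc$records$accession[7])
  expect_equal(out2$hits$coverage[1], 1.0)

  # empty query file warns and writes empty reports
  ef <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), ef)
  expect_warning(out3 <- classify_run(dir, ef, out_dir = withr::local_tempdir()),
                 "empty")
  expect_equal(nrow(out3$hits), 0)
})

test_that("host masking suppresses host-driven false positives", {
  mc <- make_mock_community(46)
  dir <- withr::local_tempdir()
  db_records <- bind_records(mc$records, mc$host_chimera)
  download_database(
    data.frame(name = unique(db_records$subdb),
               query = paste0("txid", 999000 + seq_along(unique(db_records$subdb)),
                              "[Organism:exp]"),
               min_len = NA, max_len = NA, moltype = "nucleotide"),
    fixture_fetcher(db_records), dir)

  host_reads <- simulate_reads(mc$host[[1]], 800, 100, 0, seed = 460,
                               genome_id = "host")
  viral_reads <- do.call(rbind, lapply(1:3, function(i)
    simulate_reads(mc$records$sequence[i], 150, 100, 0, seed = 4600 + i,
                   genome_id = mc$records$accession[i])))
  qf <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rbind(viral_reads, host_reads), qf)

  unmasked <- classify_run(dir, qf, out_dir = withr::local_tempdir())
  fp <- unmasked$hits[unmasked$hits$template == "SYNCHIM2.1", ]
  expect_equal(nrow(fp), 1)
  expect_true(fp$pass)  # host reads tile the mostly-host chimera entry

  hostf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">HOST1", mc$host[[1]]), hostf)
  masked <- classify_run(dir, qf, out_dir = withr::local_tempdir(),
                         host_mask = hostf)
  expect_gt(masked$masked_fraction, 0)
  expect_false("SYNCHIM2.1" %in% masked$hits$template)
  # host reads are unassigned once their kmers are masked
  host_asg <- masked$assignments[grepl("^host", masked$assignments$id), ]
  expect_true(all(is.na(host_asg$template)))
  # true templates still pass, and masking never adds mapped reads
  expect_setequal(masked$hits$template[masked$hits$pass],
                  mc$records$accession[1:3])
  merged <- merge(unmasked$hits[, c("template", "reads")],
                  masked$hits[, c("template", "reads")],
                  by = "template", all.x = TRUE)
  merged$reads.y[is.na(merged$reads.y)] <- 0L
  expect_true(all(merged$reads.y <= merged$reads.x))
})
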