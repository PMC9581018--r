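test_that("FASTA headers split into accession and annotation", {
  recs <- parse_fasta(c(">XP_452906.1 uncharacterized protein KLLA0_C15807g",
                        "MKT", "AYI"))
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$accession, "XP_452906.1")
  expect_equal(recs$annotation, "uncharacterized protein KLLA0_C15807g")
  expect_equal(recs$residues, "MKTAYI")
})

test_that("empty input parses to an empty record table", {
  expect_equal(nrow(parse_fasta(character())), 0L)
  expect_equal(nrow(parse_fasta("")), 0L)
})

test_that("parse errors name the offending line", {
  expect_error(parse_fasta(c("MKT", ">A1 x", "ACD")), "line 1")
  expect_error(parse_fasta(c(">A1 x", ">A2 y", "ACD")), "empty sequence body")
  expect_error(parse_fasta(c(">A1 x", "AC1D")), "line 2")
  expect_error(parse_fasta(c(">A1 x", "ACD", ">A2 y", "MJK")), "line 4")
})

test_that("write_fasta emits 60-column wrapped records", {
  rec <- seq_records("A1", "ACD", annotation = "x")
  path <- withr::local_tempfile()
  write_fasta(rec, path)
  expect_equal(readLines(path), c(">A1 x", "ACD"))

  long <- seq_records("L1", paste(rep("A", 70), collapse = ""))
  write_fasta(long, path)
  lines <- readLines(path)
  expect_equal(nchar(lines), c(3L, 60L, 10L))
})

test_that("write/parse round-trips content for random synthetic records", {
  set.seed(101)
  n <- 100
  recs <- seq_records(sprintf("ACC%03d.1", 1:n),
                      vapply(sample(30:200, n, replace = TRUE), random_seq, ""),
                      annotation = sprintf("protein %d alpha beta", 1:n))
  path <- withr::local_tempfile()
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(back$accession, recs$accession)
  expect_equal(back$annotation, recs$annotation)
  expect_equal(back$residues, recs$residues)
})

test_that("FASTA I/O agrees with an independent reader/writer", {
  set.seed(202)
  recs <- seq_records(sprintf("Q%02d", 1:20),
                      vapply(sample(40:150, 20, replace = TRUE), random_seq, ""),
                      annotation = sprintf("desc %d", 1:20))
  path <- withr::local_tempfile()
  write_fasta(recs, path)
  aa <- Biostrings::readAAStringSet(path)
  expect_equal(unname(as.character(aa)), recs$residues)
  expect_equal(names(aa), paste(recs$accession, recs$annotation))

  # and reading a Biostrings-written file
  path2 <- withr::local_tempfile()
  Biostrings::writeXStringSet(aa, path2, width = 60)
  expect_equal(read_fasta(path2)$residues, recs$residues)
})

test_that("filter removes hypothetical proteins then exact duplicates", {
  recs <- seq_records(
    c("A", "B", "C", "D", "E"),
    c("ACDEF", "ACDEF", "WYWYW", "MKTAY", "CCCNN"),
    annotation = c("kinase", "kinase, second copy",
                   "hypothetical protein ABC_123", "regulator", "enzyme"))
  out <- filter_batch(recs)
  expect_equal(out$report$n_input, 5L)
  expect_equal(out$report$n_hypothetical_removed, 1L)
  expect_equal(out$report$n_duplicates_removed, 1L)
  expect_equal(out$report$n_kept, 3L)
  # first occurrence survives; match is on residues, not annotation
  expect_equal(out$records$seq_id, c("A", "D", "E"))
})

test_that("filter is conservative, idempotent, and a no-op on clean input", {
  set.seed(33)
  for (i in 1:10) {
    ds <- make_dataset(n_families = 2,
                       family = family_spec(n_members = 3, seed_length = 40,
                                            rng_seed = i),
                       n_decoys = 2, n_duplicates = i %% 3,
                       n_hypotheticals = i %% 2, rng_seed = i)
    out <- filter_batch(ds$records)
    r <- out$report
    expect_equal(r$n_input,
                 r$n_kept + r$n_hypothetical_removed + r$n_duplicates_removed)
    again <- filter_batch(out$records)
    expect_equal(again$report$n_hypothetical_removed, 0L)
    expect_equal(again$report$n_duplicates_removed, 0L)
    expect_equal(again$records, out$records)
  }

  clean <- seq_records(c("X", "Y"), c("ACD", "DCA"), annotation = "ok")
  out <- filter_batch(clean)
  expect_equal(out$records, clean)
  expect_equal(out$report$n_input, out$report$n_kept)
})

test_that("hypothetical-protein match is a case-insensitive substring test", {
  recs <- seq_records(c("A", "B"), c("ACD", "DCA"),
                      annotation = c("HYPOTHETICAL PROTEIN", "hypothetically fine"))
  out <- filter_batch(recs)
  expect_equal(out$records$seq_id, "B")
})
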