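test_that("FASTA round-trips, wraps and rejects duplicate ids", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  x <- c(a = "MKT")
  write_fasta(x, tmp)
  expect_identical(read_fasta(tmp), x)
  expect_error(write_fasta(c(a = "MK", a = "MT"), tmp), "unique")
  # empty round trip
  write_fasta(character(0), tmp)
  expect_length(read_fasta(tmp), 0)
  # many random entries, idempotent over two cycles
  set.seed(1)
  big <- setNames(
    vapply(1:200, function(i)
      paste(sample(mcrapipe:::AA_ALPHABET, 157, TRUE), collapse = ""),
      character(1)),
    paste0("s", 1:200))
  write_fasta(big, tmp)
  r1 <- read_fasta(tmp)
  write_fasta(r1, tmp)
  expect_identical(read_fasta(tmp), big)
  # 60-column wrapping
  write_fasta(c(long = strrep("A", 150)), tmp)
  expect_equal(max(nchar(readLines(tmp))), 60)
})

test_that("paired FASTQ round-trips and flags desynchronised files", {
  t1 <- withr::local_tempfile(fileext = ".fastq")
  t2 <- withr::local_tempfile(fileext = ".fastq")
  pairs <- data.frame(id = c("r1", "r2"),
                      seq1 = c("ACGT", "GGCC"), qual1 = c("IIII", "IIII"),
                      seq2 = c("TTTT", "AAAA"), qual2 = c("IIII", "IIII"))
  write_fastq_pairs(pairs, t1, t2)
  rt <- read_fastq_pairs(t1, t2)
  expect_identical(rt, pairs)
  # R1 with 3 records, R2 with 2 -> error naming record 3
  pairs3 <- rbind(pairs, data.frame(id = "r3", seq1 = "AC", qual1 = "II",
                                    seq2 = "GT", qual2 = "II"))
  t3 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_pairs(pairs3, t3, withr::local_tempfile())
  expect_error(read_fastq_pairs(t3, t2), "record 3")
  # malformed record is rejected with its index
  writeLines(c("@x", "ACGT", "+", "II"), t1) # qual length mismatch
  expect_error(mcrapipe:::parse_fastq(t1), "record 1")
})

test_that("count matrices round-trip losslessly with stable columns", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  m <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
              dimnames = list(c("s1", "s2"), c("cB", "cA")))
  write_count_matrix(m, tmp)
  expect_identical(read_count_matrix(tmp), m)
  expect_error(write_count_matrix(m - 5L, tmp), "negative")
  set.seed(2)
  big <- matrix(rpois(54 * 25, 40), 54, 25,
                dimnames = list(sprintf("s%02d", 1:54),
                                paste0("C", sample(25))))
  storage.mode(big) <- "integer"
  write_count_matrix(big, tmp)
  expect_identical(read_count_matrix(tmp), big)
})

test_that("sample sheets validate ids and treatment labels", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  sheet <- data.frame(sample = c("a", "b"), treatment = c("R", "AA"),
                      r1 = "x", r2 = "y")
  write_sample_sheet(sheet, tmp)
  expect_identical(read_sample_sheet(tmp), sheet)
  bad <- sheet; bad$treatment[1] <- "Z"
  write_sample_sheet(bad, tmp)
  expect_error(read_sample_sheet(tmp), "undeclared")
  dup <- sheet; dup$sample[2] <- "a"
  write_sample_sheet(dup, tmp)
  expect_error(read_sample_sheet(tmp), "duplicate")
})

test_that("configuration applies defaults and rejects unknown keys", {
  cfg <- pipeline_config()
  expect_equal(cfg$amplicon_length, 472L)
  expect_equal(cfg$amplicon_tolerance, 1L)
  expect_equal(cfg$cluster_identity, 0.97)
  expect_equal(cfg$cluster_min_fraction, 0.001)
  expect_equal(cfg$bootstrap_reps, 500L)
  expect_equal(cfg$collapse_support, 0.30)
  expect_equal(cfg$site_coverage_min, 0.85)
  expect_equal(cfg$random_addition_reps, 10L)
  expect_error(pipeline_config(nonsense = 1), "unknown")
  tmp <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "cluster_identity = 0.95",
               "bootstrap_reps = 100"), tmp)
  cfg2 <- read_config(tmp)
  expect_equal(cfg2$cluster_identity, 0.95)
  expect_equal(cfg2$bootstrap_reps, 100L)
  expect_equal(cfg2$amplicon_length, 472L) # default preserved
  writeLines("no_such_key = 3", tmp)
  expect_error(read_config(tmp), "unknown")
})
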