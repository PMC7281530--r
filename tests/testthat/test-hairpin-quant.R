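test_that("amplicon_total_length sums the segment model", {
  bc <- generate_barcodes("s1", barcode_len = 9, seed = 1)
  amp <- amplicon_model(bc)
  expect_identical(amplicon_total_length(amp), 634L)
  expect_equal(amplicon_total_length(53, 513, 68), 634)
  expect_equal(amplicon_total_length(0, 0, 0), 0)
  expect_equal(amplicon_total_length(1, 2, 3), 6)
})

test_that("amplicon_model enforces its invariants", {
  bc <- c(s1 = "AAAAAA", s2 = "TTTTTT")
  expect_error(amplicon_model(bc, rev_len = 10, adaptor_len = 6,
                              barcode_len = 6),
               "rev_len")
  expect_error(amplicon_model(c(s1 = "AAAAAA", s2 = "AAAAAA"),
                              adaptor_len = 6, barcode_len = 6),
               "unique")
  expect_error(amplicon_model(c(s1 = "AAAA", s2 = "TTTTTT"),
                              adaptor_len = 6, barcode_len = 6),
               "length")
})

test_that("empty FASTQ gives an all-zero matrix and report", {
  lib <- generate_library(8, 1, seq_len = 12, seed = 1)
  amp <- tiny_amplicon()
  path <- withr::local_tempfile(fileext = ".fastq")
  file.create(path)
  out <- count_hairpins(path, lib, amp)
  expect_true(all(out$counts$counts == 0))
  expect_identical(dim(out$counts$counts), c(8L, 2L))
  expect_equal(unname(out$report$overall["reads_seen"]), 0)
})

test_that("error-free generated reads reproduce the tally exactly", {
  lib <- generate_library(30, 2, seq_len = 15, seed = 3)
  p <- generate_abundance(lib, 1, seed = 4)
  amp <- tiny_amplicon(seed = 5)
  path <- withr::local_tempfile(fileext = ".fastq")
  t1 <- generate_reads(lib, p, amp, "ctrl", 3000, path, seed = 6)
  t2 <- generate_reads(lib, p, amp, "drug", 3000, path, seed = 7,
                       append = TRUE)
  out <- count_hairpins(path, lib, amp)
  expect_identical(out$counts$counts[, "ctrl"], t1$tally)
  expect_identical(out$counts$counts[, "drug"], t2$tally)
  o <- out$report$overall
  expect_equal(unname(o["assigned"] + o["unassigned_barcode"] +
                        o["ambiguous_barcode"] + o["unassigned_hairpin"] +
                        o["ambiguous_hairpin"]),
               unname(o["reads_seen"]))
})

test_that("gzip FASTQ input is accepted", {
  lib <- generate_library(10, 1, seq_len = 12, seed = 1)
  p <- generate_abundance(lib, 0, seed = 1)
  amp <- tiny_amplicon()
  path <- withr::local_tempfile(fileext = ".fastq.gz")
  sim <- generate_reads(lib, p, amp, "ctrl", 200, path, seed = 2)
  out <- count_hairpins(path, lib, amp)
  expect_identical(out$counts$counts[, "ctrl"], sim$tally)
})

test_that("a one-mismatch barcode is assigned within tolerance, not without", {
  lib <- generate_library(6, 1, seq_len = 12, seed = 1)
  p <- generate_abundance(lib, 0, seed = 1)
  amp <- tiny_amplicon(seed = 9)
  path <- withr::local_tempfile(fileext = ".fastq")
  generate_reads(lib, p, amp, "ctrl", 1, path, seed = 2)
  lines <- readLines(path)
  total <- amplicon_total_length(amp)
  lines[2] <- mutate_base(lines[2], total - 2L)  # inside the barcode
  writeLines(lines, path)

  hit <- count_hairpins(path, lib, amp, max_barcode_mismatch = 1)
  expect_equal(sum(hit$counts$counts[, "ctrl"]), 1)
  strict <- count_hairpins(path, lib, amp, max_barcode_mismatch = 0)
  expect_equal(sum(strict$counts$counts), 0)
  expect_equal(unname(strict$report$overall["unassigned_barcode"]), 1)
})

test_that("hairpin ties at equal best distance are ambiguous, never assigned", {
  lib <- manual_library(c("AAAAAAAAAAAA", "AACAAAAAAAAT"))  # distance 2
  amp <- tiny_amplicon(seed = 10)
  p <- stats::setNames(c(1, 0), lib$hairpin_id)
  path <- withr::local_tempfile(fileext = ".fastq")
  generate_reads(lib, p, amp, "ctrl", 1, path)
  lines <- readLines(path)
  hp_start <- amp$fwd_len + amp$hairpin_offset + 1L
  lines[2] <- mutate_base(lines[2], hp_start + 2L)  # A->C at position 3
  writeLines(lines, path)

  out <- count_hairpins(path, lib, amp, max_hairpin_mismatch = 2)
  expect_equal(sum(out$counts$counts), 0)
  expect_equal(unname(out$report$overall["ambiguous_hairpin"]), 1)
})

test_that("short reads are reported as unassigned, never dropped", {
  lib <- generate_library(5, 1, seq_len = 12, seed = 1)
  p <- generate_abundance(lib, 0, seed = 1)
  amp <- tiny_amplicon()
  path <- withr::local_tempfile(fileext = ".fastq")
  generate_reads(lib, p, amp, "ctrl", 2, path, seed = 3)
  lines <- readLines(path)
  lines[2] <- substr(lines[2], 1, 20)
  lines[4] <- substr(lines[4], 1, 20)
  writeLines(lines, path)
  out <- count_hairpins(path, lib, amp)
  o <- out$report$overall
  expect_equal(unname(o["too_short"]), 1)
  expect_equal(unname(o["assigned"]), 1)
  expect_equal(unname(o["reads_seen"]), 2)
})

test_that("inseparable barcode maps are rejected", {
  lib <- generate_library(5, 1, seq_len = 12, seed = 1)
  amp <- amplicon_model(c(s1 = "AAAAAA", s2 = "AAAATT"),
                        fwd_len = 8, insert_len = 40, rev_len = 16,
                        adaptor_len = 6, barcode_len = 6,
                        hairpin_offset = 5)
  path <- withr::local_tempfile(fileext = ".fastq")
  file.create(path)
  expect_error(count_hairpins(path, lib, amp, max_barcode_mismatch = 1),
               "not separable")
})

test_that("raising the hairpin mismatch tolerance never loses counts", {
  lib <- generate_library(40, 1, seq_len = 21, seed = 11)
  p <- generate_abundance(lib, 0.5, seed = 12)
  amp <- tiny_amplicon(seed = 13)
  path <- withr::local_tempfile(fileext = ".fastq")
  generate_reads(lib, p, amp, "ctrl", 800, path, error_rate = 0.01,
                 seed = 14)
  c0 <- count_hairpins(path, lib, amp, max_hairpin_mismatch = 0)$counts$counts
  c1 <- count_hairpins(path, lib, amp, max_hairpin_mismatch = 1)$counts$counts
  c2 <- count_hairpins(path, lib, amp, max_hairpin_mismatch = 2)$counts$counts
  expect_true(all(c1 >= c0))
  expect_true(all(c2 >= c1))
})

test_that("malformed FASTQ fails loudly", {
  lib <- generate_library(5, 1, seq_len = 12, seed = 1)
  amp <- tiny_amplicon()
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("not", "a", "fastq"), path)
  expect_error(count_hairpins(path, lib, amp), "malformed FASTQ")
})

test_that("count matrix TSV round trip validates against the library", {
  lib <- generate_library(6, 1, seq_len = 12, seed = 1)
  counts <- matrix(rpois(12, 50), 6, 2,
                   dimnames = list(lib$hairpin_id, c("a", "b")))
  sc <- manual_counts(counts, c("ctrl", "drug"), lib)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(sc, path)
  back <- read_counts(path, lib, samples = sc$samples)
  expect_identical(back$counts, sc$counts)

  tab <- utils::read.delim(path, check.names = FALSE)
  tab$a[1] <- -5
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_counts(path, lib), "non-negative")

  tab <- utils::read.delim(path, check.names = FALSE)[-1, ]
  tab$a[1] <- 5
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_counts(path, lib), "missing")

  tab <- utils::read.delim(path, check.names = FALSE)
  tab$hairpin_id[1] <- "sh_unknown"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_counts(path, lib), "sh_unknown|not in the library")
})
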