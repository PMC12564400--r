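test_that("assemblies round-trip through FASTA with ids and case handling", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 first pseudomolecule", "ACGTacgtNN",
               ">chr2", "ggggTTTT"), tmp)
  asm <- read_assembly(tmp)
  expect_equal(names(asm), c("chr1", "chr2"))
  expect_equal(as.character(asm[["chr1"]]), "ACGTACGTNN")  # upper-cased
  expect_equal(as.character(asm[["chr2"]]), "GGGGTTTT")
  # write back and re-read: ids, lengths, sequences preserved
  out <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(asm, out)
  asm2 <- read_assembly(out)
  expect_identical(names(asm2), names(asm))
  expect_identical(as.character(asm2), as.character(asm))
})

test_that("malformed assemblies raise distinct named failures", {
  expect_error(read_assembly(file.path(tempdir(), "absent.fa")),
               class = "telomotif_missing_file")
  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), dup)
  expect_error(read_assembly(dup), class = "telomotif_duplicate_id")
  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACXGT"), bad)
  expect_error(read_assembly(bad), class = "telomotif_illegal_character")
  emp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "", ">b", "ACGT"), emp)
  expect_error(read_assembly(emp), class = "telomotif_empty_record")
})

test_that("terminal windows cover the window arithmetic cases", {
  s <- random_dna(100, seed = 3)
  w <- terminal_windows(s, pm_id = "c", window_size = 10)
  expect_equal(c(w$five_prime$global_start, w$five_prime$global_end),
               c(1, 10))
  expect_equal(c(w$three_prime$global_start, w$three_prime$global_end),
               c(91, 100))
  # short record: both windows span the whole sequence
  w2 <- terminal_windows("ACGTACGTAC", window_size = 50000)
  expect_equal(c(w2$five_prime$global_start, w2$five_prime$global_end),
               c(1, 10))
  expect_equal(c(w2$three_prime$global_start, w2$three_prime$global_end),
               c(1, 10))
  # the 3' window always ends at the pseudomolecule terminus
  expect_equal(w$three_prime$global_end, w$three_prime$pm_length)
  expect_error(terminal_windows(s, window_size = 0))
})

test_that("window sequences equal the slice of the parent sequence", {
  set.seed(9)
  for (i in 1:5) {
    n <- sample(50:4000, 1)
    s <- random_dna(n)
    ws <- sample(c(10, 64, 5000), 1)
    w <- terminal_windows(s, window_size = ws)
    for (side in c("five_prime", "three_prime")) {
      expect_equal(w[[side]]$sequence,
                   substr(s, w[[side]]$global_start, w[[side]]$global_end))
      expect_lte(nchar(w[[side]]$sequence), ws)
    }
  }
})

test_that("reports carry the published table conventions and BED frame", {
  arrays <- data.frame(
    pm_id = c("pmA", "pmA", "pmB"),
    side = c("five_prime", "three_prime", "three_prime"),
    start = c(1, 96001, 91996), end = c(8005, 100000, 92000),
    length = c(8005, 4000, 5),
    motif = "TTGGG", k = 5L,
    oriented_motif = c("CCCAA", "TTGGG", "TTGGG"),
    purity = c(0.99, 0.97, 1), copy_number = c(1601, 800, 1),
    stringsAsFactors = FALSE)
  lens <- c(pmA = 100000, pmB = 92000, pmC = 50000)
  out <- withr::local_tempdir()
  paths <- write_reports(arrays, NULL, lens, out)
  ends <- utils::read.table(paths[["ends"]], sep = "\t", header = TRUE,
                            colClasses = "character")
  expect_equal(ends$five_prime[1], "1-8005")
  expect_equal(ends$three_prime[1], "96,001-100,000")
  expect_equal(ends$five_prime[3], "no short repeat array")
  expect_equal(ends$three_prime[3], "no short repeat array")
  bed <- read_array_bed(paths[["bed"]])
  # 1-based inclusive (1, 8005) -> BED half-open (0, 8005), read back as 1
  expect_equal(bed$start, arrays$start)
  expect_equal(bed$end, arrays$end)
  # strand: "+" for G-rich forward arrays, "-" for reverse-complement (5')
  expect_equal(bed$strand, c("-", "+", "+"))
  # BED and TSV report the same arrays
  expect_equal(nrow(bed), nrow(arrays))
  expect_true(file.exists(paths[["json"]]))
})

test_that("an assembly without arrays reports only the no-array literal", {
  out <- withr::local_tempdir()
  paths <- write_reports(empty_arrays_for_tests(), NULL,
                         c(a = 1000, b = 2000), out)
  ends <- utils::read.table(paths[["ends"]], sep = "\t", header = TRUE,
                            colClasses = "character")
  expect_true(all(unlist(ends[, c("five_prime", "three_prime")]) ==
                    "no short repeat array"))
  expect_equal(nrow(read_array_bed(paths[["bed"]])), 0L)
})
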