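# Array tables shaped like scanner output, built directly so each criterion
# is exercised in isolation.
arr_row <- function(pm_id, side, start, end, oriented, motif = "TTGGG") {
  data.frame(pm_id = pm_id, side = side, start = start, end = end,
             length = end - start + 1, motif = motif,
             k = nchar(motif), oriented_motif = oriented, purity = 0.98,
             copy_number = (end - start + 1) / nchar(motif),
             stringsAsFactors = FALSE)
}

test_that("criterion 1 accepts near-terminal arrays and rejects interior ones", {
  lens <- c(pm1 = 142396181)
  # array ending 2 bp short of the terminus passes at the default offset
  near <- arr_row("pm1", "three_prime", 142391635, 142396179, "TTGGG")
  expect_true(check_terminal(near, lens, max_offset = 100)$passed)
  at_term <- arr_row("pm1", "five_prime", 1, 8005, "CCCAA")
  expect_true(check_terminal(at_term, lens, max_offset = 100)$passed)
  interior <- arr_row("pm1", "five_prime", 5001, 9000, "CCCAA")
  res <- check_terminal(interior, lens, max_offset = 100)
  expect_false(res$passed)
  expect_equal(res$evidence$offset, 5000)
})

test_that("criterion 2 is judged at motif level so short arrays are retained", {
  lens7 <- c(8005, 4018, 4545, 3300, 228, 7554, 1225)
  arrays <- do.call(rbind, lapply(seq_along(lens7), function(i)
    arr_row(paste0("pm", i), "three_prime", 1000, 999 + lens7[i], "TTGGG")))
  res <- check_span(arrays, min_span = 300)
  expect_true(res$passed)
  expect_true(228 %in% res$evidence$length)  # the short array stays reported
  expect_false(check_span(arr_row("pm1", "three_prime", 1, 250, "TTGGG"),
                          min_span = 300)$passed)
  expect_true(check_span(arr_row("pm1", "three_prime", 1, 400, "TTGGG"),
                         min_span = 300)$passed)
})

test_that("criterion 3 requires one consistent spelling across chromosomes", {
  ok <- rbind(arr_row("pm1", "three_prime", 500, 999, "TTGGG"),
              arr_row("pm2", "five_prime", 1, 500, "CCCAA"),
              arr_row("pm3", "three_prime", 400, 899, "GGGTT"))
  expect_true(check_identity_across_chromosomes(ok)$passed)
  single <- arr_row("pm1", "three_prime", 1, 500, "TTGGG")
  expect_true(check_identity_across_chromosomes(single)$passed)
  mixed <- rbind(arr_row("pm1", "three_prime", 1, 500, "TTGGG"),
                 arr_row("pm2", "three_prime", 1, 500, "TTAGG",
                         motif = "TTAGG"))
  expect_false(check_identity_across_chromosomes(mixed)$passed)
})

test_that("criterion 4 quantifies alternative-motif coverage per end", {
  # clean single-motif telomere: alternative fraction 0
  clean <- make_window(paste0(strrep("CCTAA", 400),
                              random_dna(18000, seed = 41)),
                       side = "five_prime", pm_id = "pmC", pm_length = 80000)
  cand <- find_terminal_arrays(clean, test_params())
  res <- check_no_alternatives(list(clean), cand, test_params())
  expect_true(res$passed)
  expect_equal(res$evidence$alt_fraction, 0)
  # a 1.5 kb array of a different class behind the candidate trips the 5%
  # ceiling in a 20 kb window
  dirty <- make_window(paste0(strrep("TTAGG", 400), random_dna(150, seed = 6),
                              strrep("TTGGG", 300),
                              random_dna(16000, seed = 7)),
                       side = "five_prime", pm_id = "pmD", pm_length = 80000)
  cand2 <- find_terminal_arrays(dirty, test_params())
  cand2 <- cand2[cand2$motif == "TTAGG", ]
  res2 <- check_no_alternatives(list(dirty), cand2, test_params())
  expect_false(res2$passed)
  expect_gt(res2$evidence$alt_fraction, 0.05)
  # ends without a candidate array are not evaluated
  other <- make_window(random_dna(5000, seed = 8), side = "three_prime",
                       pm_id = "pmE", pm_length = 80000)
  res3 <- check_no_alternatives(list(clean, other), cand, test_params())
  expect_true(res3$passed)
  expect_false("pmE" %in% res3$evidence$pm_id)
})

test_that("criterion 5 demands reverse-complementary opposite ends", {
  both_ok <- rbind(arr_row("pm1", "five_prime", 1, 8005, "CCCAA"),
                   arr_row("pm1", "three_prime", 95001, 99000, "TTGGG"))
  expect_true(check_opposite_end_orientation(both_ok)$passed)
  same_strand <- rbind(arr_row("pm1", "five_prime", 1, 8005, "TTGGG"),
                       arr_row("pm1", "three_prime", 95001, 99000, "TTGGG"))
  expect_false(check_opposite_end_orientation(same_strand)$passed)
  single_ends <- rbind(arr_row("pm1", "five_prime", 1, 8005, "CCCAA"),
                       arr_row("pm2", "three_prime", 95001, 99000, "TTGGG"))
  expect_true(check_opposite_end_orientation(single_ends)$passed)  # vacuous
  # rotation of the reverse complement still counts
  rotated <- rbind(arr_row("pm1", "five_prime", 1, 8005, "CCAAC"),
                   arr_row("pm1", "three_prime", 95001, 99000, "TTGGG"))
  expect_true(check_opposite_end_orientation(rotated)$passed)
})

mock_verdict <- function(motif, n_arrays, total, qualified,
                         failed = integer(0)) {
  crit <- lapply(1:5, function(i)
    structure(list(criterion_id = i, passed = !(i %in% failed),
                   evidence = data.frame(x = 1)),
              class = "CriterionResult"))
  structure(list(motif = motif, arrays = NULL, criteria = crit,
                 qualified = qualified,
                 rank_key = c(n_arrays = n_arrays, total_length = total)),
            class = "MotifVerdict")
}

test_that("nomination ranks by array count then total length", {
  v7 <- mock_verdict("TTGGG", 7, 28875, TRUE)
  v4 <- mock_verdict("TTAGG", 4, 10990, TRUE)
  expect_equal(nominate(list(v4, v7))$nominated, "TTGGG")
  # equal counts: total length decides
  va <- mock_verdict("TTAGG", 4, 9000, TRUE)
  vb <- mock_verdict("TTGGG", 4, 12000, TRUE)
  expect_equal(nominate(list(va, vb))$nominated, "TTGGG")
})

test_that("negative verdicts name the nearest miss and failed criteria", {
  none <- nominate(list())
  expect_true(none$negative)
  expect_null(none$nominated)
  near <- mock_verdict("ACG", 3, 900, FALSE, failed = c(1, 4))
  far <- mock_verdict("AT", 1, 100, FALSE, failed = 1:4)
  res <- nominate(list(far, near))
  expect_true(res$negative)
  expect_equal(res$nearest_miss, "ACG")
  expect_equal(res$failed_criteria, c(1L, 4L))
})

test_that("screening is deterministic for identical inputs", {
  gen <- generate_assembly(synthetic_spec(19, list(
    list(length = 5e4, three_prime = planted_array("TTAGG", 800)))))
  p <- scan_params(window_size = 15000)
  s1 <- screen_assembly(gen$assembly, p)
  s2 <- screen_assembly(gen$assembly, p)
  expect_identical(s1$arrays, s2$arrays)
  expect_identical(s1$nomination, s2$nomination)
})
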