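test_that("array purity is the phase-maximized identity fraction", {
  expect_equal(array_purity("TTAGGTTAGG", "TTAGG"), 1.0)
  expect_equal(array_purity("TTAGGTTCGG", "TTAGG"), 0.9)
  expect_equal(array_purity("NNNNN", "TTAGG"), 0.0)  # N never matches
  # phase alignment: a rotated segment still scores 1
  expect_equal(array_purity("AGGTTAGGTT", "TTAGG"), 1.0)
  expect_error(array_purity("", "TTAGG"))
  expect_error(array_purity("AC", "TTAGG"))
})

test_that("a near-perfect terminal array is found with tight boundaries", {
  arr <- substitute_at(strrep("TTAGG", 100), c(40, 233, 406))
  win <- make_window(paste0(random_dna(2000, seed = 21), arr),
                     side = "three_prime", pm_length = 60000)
  found <- find_terminal_arrays(win, test_params())
  expect_equal(nrow(found), 1L)
  expect_equal(found$motif, "TTAGG")
  expect_equal(found$purity, 0.994, tolerance = 0.004)
  # planted run occupies the last 500 bp of a 60 kb pseudomolecule
  expect_lte(abs(found$start - 59501), 5)
  expect_lte(abs(found$end - 60000), 5)
  expect_equal(found$side, "three_prime")
})

test_that("a 5' array surfaces as the reverse-complement spelling", {
  win <- make_window(paste0(strrep("CCCAA", 60), random_dna(3000, seed = 8)),
                     side = "five_prime", pm_length = 50000)
  found <- find_terminal_arrays(win, test_params())
  expect_equal(nrow(found), 1L)
  expect_equal(found$motif, "TTGGG")
  expect_true(found$oriented_motif %in% rotations("CCCAA"))
  expect_equal(found$start, 1)
  expect_equal(found$length, 300, tolerance = 0.02)
})

test_that("random windows contain no qualifying arrays", {
  for (seed in c(5, 17)) {
    win <- make_window(random_dna(10000, seed = seed), side = "five_prime")
    expect_equal(nrow(find_terminal_arrays(win, test_params())), 0L)
  }
})

test_that("scanner boundaries agree with the brute-force oracle", {
  set.seed(31)
  for (i in 1:6) {
    k <- sample(c(2:6, 10), 1)
    motif <- NULL
    while (is.null(motif)) {
      m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                 collapse = "")
      if (is_primitive(m)) motif <- m
    }
    copies <- sample(12:60, 1)
    arr <- strrep(motif, copies)
    # flank the array with two breaking bases (two consecutive mismatches
    # terminate an array) so the perfect run is exactly the planted one
    brk <- substitute_at(substr(strrep(motif, 2), 1, 2), 1:2)
    s <- paste0(arr, brk, random_dna(3000))
    oracle <- oracle_perfect_runs(s, k_min = 2, k_max = 12, min_copies = 10)
    oracle <- oracle[oracle$motif ==
                       canonical_class(motif)$representative, , drop = FALSE]
    expect_equal(nrow(oracle), 1L)
    expect_equal(oracle$start, 1L)
    expect_equal(oracle$end, copies * k)
    found <- find_terminal_arrays(make_window(s, side = "five_prime"),
                                  test_params())
    found <- found[found$motif == oracle$motif, , drop = FALSE]
    expect_equal(nrow(found), 1L)
    expect_lte(abs(found$start - oracle$start), k)
    expect_lte(abs(found$end - oracle$end), k)
  }
})

test_that("detection is invariant under motif rotation of the plant", {
  reps <- character(0)
  for (spelling in rotations("TTGGG")) {
    win <- make_window(paste0(strrep(spelling, 80),
                              random_dna(2000, seed = 13)),
                       side = "five_prime", pm_length = 30000)
    found <- find_terminal_arrays(win, test_params())
    expect_equal(nrow(found), 1L)
    reps <- c(reps, found$motif)
    expect_lte(abs(found$length - 400), 5)
  }
  expect_equal(unique(reps), "TTGGG")
})

test_that("reverse-complementing a pseudomolecule swaps sides and maps coordinates", {
  for (seed in 1:3) {
    gen <- generate_assembly(synthetic_spec(seed, list(
      list(length = 6e4, five_prime = planted_array("TTAGG", 1200),
           three_prime = planted_array("TTAGG", 700)))))
    p <- scan_params(window_size = 20000)
    fwd <- screen_assembly(gen$assembly, p)$arrays
    rev <- screen_assembly(Biostrings::reverseComplement(gen$assembly),
                           p)$arrays
    expect_equal(nrow(fwd), nrow(rev))
    L <- 6e4
    mapped <- data.frame(
      side = ifelse(rev$side == "five_prime", "three_prime", "five_prime"),
      start = L - rev$end + 1, end = L - rev$start + 1,
      motif = rev$motif, stringsAsFactors = FALSE)
    mapped <- mapped[order(mapped$side, mapped$start), ]
    fwd <- fwd[order(fwd$side, fwd$start), ]
    expect_equal(fwd$side, mapped$side)
    expect_equal(fwd$start, mapped$start)
    expect_equal(fwd$end, mapped$end)
    expect_equal(fwd$motif, mapped$motif)
  }
})

test_that("reported motif classes are primitive and distinct arrays coexist", {
  # two motif classes planted in one window, the alternative behind the
  # terminal array
  s <- paste0(strrep("TTAGG", 200), random_dna(120, seed = 2),
              strrep("TTGGG", 150), random_dna(4000))
  win <- make_window(s, side = "five_prime", pm_length = 40000)
  found <- find_window_arrays(win, test_params())
  expect_setequal(found$motif, c("TTAGG", "TTGGG"))
  for (m in found$motif) expect_true(is_primitive(m))
  ttggg <- found[found$motif == "TTGGG", ]
  expect_lte(abs(ttggg$start - 1121), 5)
  expect_lte(abs(ttggg$end - 1870), 5)
})
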