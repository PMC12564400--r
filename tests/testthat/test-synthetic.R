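test_that("generation is byte-deterministic in the seed", {
  spec <- synthetic_spec(101, list(
    list(length = 3e4, five_prime = planted_array("TTGGG", 900)),
    list(length = 2e4)))
  g1 <- generate_assembly(spec)
  g2 <- generate_assembly(spec)
  expect_identical(as.character(g1$assembly), as.character(g2$assembly))
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_assembly(synthetic_spec(102, spec$chromosomes))
  expect_false(identical(as.character(g1$assembly),
                         as.character(g3$assembly)))
})

test_that("truth intervals match the emitted sequence", {
  gen <- generate_assembly(synthetic_spec(7, list(
    list(length = 4e4, five_prime = planted_array("TTGGG", 2000),
         three_prime = planted_array("TTGGG", 1500)),
    list(length = 4e4, three_prime = planted_array("TTGGG", 600,
                                                   offset = 2L)))))
  for (i in seq_len(nrow(gen$truth))) {
    tr <- gen$truth[i, ]
    seg <- substr(as.character(gen$assembly[[tr$pm_id]]), tr$start, tr$end)
    expect_equal(nchar(seg), tr$end - tr$start + 1)
    # realized purity recorded in the truth table matches the sequence
    expect_equal(array_purity(seg, tr$oriented_motif), tr$realized_purity,
                 tolerance = 0.02)
    # orientation convention: reverse complement at 5', forward at 3'
    if (tr$side == "five_prime") {
      expect_true(tr$oriented_motif %in% rotations(rc_string(tr$motif)))
      expect_equal(tr$start, 1)
    } else {
      expect_true(tr$oriented_motif %in% rotations(tr$motif))
    }
  }
  # the offset array ends 2 bp short of the terminus
  off <- gen$truth[gen$truth$pm_id == "synth_chr02", ]
  expect_equal(off$end, 4e4 - 2)
})

test_that("degradation increases from the terminus inward", {
  gen <- generate_assembly(synthetic_spec(13, list(
    list(length = 2e4, three_prime = planted_array("TTAGG", 4000,
                                                   degradation_max = 0.3)))))
  tr <- gen$truth[1, ]
  s <- as.character(gen$assembly[[1]])
  half <- floor((tr$end - tr$start + 1) / 2)
  inner <- substr(s, tr$start, tr$start + half - 1)   # 3' array: inner first
  outer <- substr(s, tr$end - half + 1, tr$end)
  expect_gt(array_purity(outer, tr$oriented_motif),
            array_purity(inner, tr$oriented_motif))
})

test_that("infeasible specifications are rejected", {
  expect_error(synthetic_spec(1, list(
    list(length = 1000, five_prime = planted_array("TTAGG", 600)))),
    class = "telomotif_infeasible_spec")
  expect_error(planted_array("TTAGG", 500, degradation_max = 0.6))
  expect_error(planted_array("ATAT", 500),
               class = "telomotif_nonprimitive")
  expect_error(generate_assembly(synthetic_spec(1, list(
    list(length = 4e4, five_prime = planted_array("TTAGG", 2000),
         retro_insertions = list(list(family = "TRAS", position = 1500)))))),
    class = "telomotif_infeasible_spec")
})

test_that("written synthetic fixtures round-trip through the reader", {
  out <- withr::local_tempdir()
  spec <- synthetic_spec(31, list(
    list(length = 2e4, three_prime = planted_array("TTAGG", 700))))
  paths <- run_generate(spec, out, quiet = TRUE)
  asm <- read_assembly(paths[["fasta"]])
  gen <- generate_assembly(spec)
  expect_identical(as.character(asm), as.character(gen$assembly))
  truth <- utils::read.table(paths[["truth"]], header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  expect_equal(truth$start, gen$truth$start)
  spec_back <- jsonlite::read_json(paths[["spec"]])
  expect_equal(spec_back$seed, 31)
})
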