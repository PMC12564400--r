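# Shared fixture builders. Test assemblies use ~100 kb chromosomes and
# 25 kb terminal windows: chromosome length enters only through coordinates,
# and a 25 kb window still holds the longest planted arrays (8 kb) with
# ample margin.

test_params <- function(...) scan_params(window_size = 25000L, ...)

random_dna <- function(n, seed = NULL, gc = 0.35) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A terminal window object built directly from a sequence string.
make_window <- function(sequence, side = "five_prime", pm_id = "chrT",
                        pm_length = nchar(sequence),
                        global_start = if (side == "five_prime") 1L else
                          pm_length - nchar(sequence) + 1L) {
  structure(list(pm_id = pm_id, side = side,
                 global_start = as.numeric(global_start),
                 global_end = as.numeric(global_start + nchar(sequence) - 1),
                 pm_length = as.numeric(pm_length), sequence = sequence),
            class = "TerminalWindow")
}

# Substitute bases of `s` at `pos` with a different base (deterministic:
# cycles A->C->G->T->A).
substitute_at <- function(s, pos) {
  nxt <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  for (p in pos) substr(s, p, p) <- nxt[[substr(s, p, p)]]
  s
}

# A detected boundary agrees with the planted one when it is within +-k bp,
# or when the deviation is short (<= 3k) and the deviating slice itself
# matches the motif at array-like density (the background can genuinely
# continue the repeat, in which case the realized array extends past the
# planted coordinate and no estimator can place the planted edge).
boundary_consistent <- function(seq_string, planted, detected, k, oriented,
                                edge = c("end", "start")) {
  edge <- match.arg(edge)
  dev <- abs(detected - planted)
  if (dev <= k) return(TRUE)
  if (dev > 3 * k) return(FALSE)
  slice <- if (edge == "end")
    substr(seq_string, min(planted, detected) + 1, max(planted, detected))
  else
    substr(seq_string, min(planted, detected), max(planted, detected) - 1)
  array_purity(slice, oriented) > 0.6
}

# Both boundaries of one detected array vs its planted truth row.
array_recovered <- function(seq_string, truth_row, det_row) {
  k <- nchar(truth_row$motif)
  boundary_consistent(seq_string, truth_row$start, det_row$start, k,
                      truth_row$oriented_motif, edge = "start") &&
    boundary_consistent(seq_string, truth_row$end, det_row$end, k,
                        truth_row$oriented_motif, edge = "end")
}

empty_arrays_for_tests <- function() {
  data.frame(pm_id = character(), side = character(), start = numeric(),
             end = numeric(), length = numeric(), motif = character(),
             k = integer(), oriented_motif = character(), purity = numeric(),
             copy_number = numeric(), stringsAsFactors = FALSE)
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  path
}
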