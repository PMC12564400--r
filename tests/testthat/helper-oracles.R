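# Independent brute-force oracles, deliberately naive.

# All maximal perfect tandem runs: for every (start, k), count exact
# head-to-tail copies by direct substring comparison; keep runs with at
# least min_copies copies whose motif is primitive, and drop runs contained
# in another reported run of the same class.
oracle_perfect_runs <- function(seq_string, k_min = 2L, k_max = 25L,
                                min_copies = 10L) {
  n <- nchar(seq_string)
  out <- data.frame(start = integer(), end = integer(), k = integer(),
                    motif = character(), stringsAsFactors = FALSE)
  for (k in k_min:k_max) {
    if (min_copies * k > n) break
    for (s in seq_len(n - min_copies * k + 1L)) {
      unit <- substr(seq_string, s, s + k - 1L)
      if (grepl("N", unit, fixed = TRUE) || !is_primitive(unit)) next
      copies <- 1L
      while (s + (copies + 1L) * k - 1L <= n &&
             substr(seq_string, s + copies * k, s + (copies + 1L) * k - 1L)
             == unit) copies <- copies + 1L
      # extend a trailing partial copy
      ext <- 0L
      while (s + copies * k + ext <= n &&
             substr(seq_string, s + copies * k + ext, s + copies * k + ext)
             == substr(unit, ext + 1L, ext + 1L) && ext < k - 1L)
        ext <- ext + 1L
      if (copies >= min_copies) {
        # maximal only: skip runs that can be extended one base to the left
        # (the same run under a rotated unit)
        if (s > 1L &&
            substr(seq_string, s - 1L, s - 1L) == substr(unit, k, k)) next
        out <- rbind(out, data.frame(
          start = s, end = s + copies * k + ext - 1L, k = k,
          motif = canonical_class(unit)$representative,
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# Naive exact substring search: compare the query against every position.
naive_search <- function(subject, query) {
  n <- nchar(subject); m <- nchar(query)
  if (m > n) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - m + 1L))
    if (substr(subject, i, i + m - 1L) == query) hits <- c(hits, i)
  hits
}

# Two-pass textbook mean / sample SD.
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  ss <- sum((x - m)^2)
  list(mean = m, sd = if (length(x) < 2) NA_real_ else
    sqrt(ss / (length(x) - 1)))
}
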