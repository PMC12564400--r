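#' Array length from 1-based inclusive coordinates
#' @param start,end coordinates, \code{start <= end}, both >= 1.
#' @return length in bp, \code{end - start + 1}.
#' @export
#' @examples
#' array_length(1, 8005)  # 8005
array_length <- function(start, end) {
  if (any(start < 1) || any(end < 1)) stop("coordinates must be >= 1")
  if (any(start > end)) stop("array_length: start > end")
  end - start + 1
}

#' Summary statistics of array lengths
#'
#' Mean, sample standard deviation (n-1 denominator), minimum and maximum.
#' The SD is undefined for a single array and reported as \code{NA}.
#'
#' @param lengths numeric vector of array lengths in bp, non-empty.
#' @return object of class \code{length_summary}: list with \code{n},
#'   \code{lengths}, \code{mean}, \code{sample_sd}, \code{min}, \code{max}.
#' @export
#' @examples
#' s <- summarize_lengths(c(8005, 4018, 4545, 3300, 228, 7554, 1225))
#' s$mean  # 4125
summarize_lengths <- function(lengths) {
  if (length(lengths) == 0L) stop("summarize_lengths: empty input")
  structure(list(
    n = length(lengths),
    lengths = as.numeric(lengths),
    mean = mean(lengths),
    sample_sd = if (length(lengths) < 2L) NA_real_ else stats::sd(lengths),
    min = min(lengths),
    max = max(lengths)
  ), class = "length_summary")
}

#' @export
print.length_summary <- function(x, ...) {
  # printed precision follows the mean: integer statistics when the mean is
  # integral ("mean 4125 bp; sample SD 2923 bp"), one decimal otherwise
  # ("mean 2747.5 bp; sample SD 710.6 bp"); digit grouping from five digits
  dec <- if (isTRUE(all.equal(x$mean, round(x$mean)))) 0L else 1L
  one <- function(v, d = 0L) {
    if (is.na(v)) return("NA")
    format(round(v, d), big.mark = if (v >= 1e4) "," else "", nsmall = d,
           scientific = FALSE, trim = TRUE)
  }
  cat(sprintf("%d arrays, %s-%s bp (mean %s bp; sample SD %s bp)\n",
              x$n, one(x$min), one(x$max), one(x$mean, dec),
              one(x$sample_sd, dec)))
  invisible(x)
}

#' Read a pseudomolecule end table
#'
#' Parses a tab-delimited table shaped like published assembly end tables:
#' one row per pseudomolecule with an accession column, a 5' cell, a 3' cell
#' and a size column. Cells hold either a coordinate range ("start-end", with
#' a hyphen or an en dash, thousands separators allowed) or the literal
#' "no short repeat array".
#'
#' @param path path to the TSV.
#' @return data.frame with one row per detected array: \code{pm_id},
#'   \code{side}, \code{start}, \code{end}, \code{length}, \code{pm_length}.
#' @export
read_end_table <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("read_end_table: no such file: %s", path),
                        class = c("telomotif_missing_file", "error", "condition")))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", fileEncoding = "UTF-8")
  if (ncol(tab) < 4L)
    stop("read_end_table: expected >= 4 columns (accession, 5', 3', size)")
  num <- function(x) as.numeric(gsub(",", "", x, fixed = TRUE))
  out <- data.frame(pm_id = character(), side = character(),
                    start = numeric(), end = numeric(), length = numeric(),
                    pm_length = numeric(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    for (side_col in c(2L, 3L)) {
      cell <- trimws(tab[i, side_col])
      if (identical(cell, NO_ARRAY) || cell == "" || is.na(cell)) next
      for (rng in strsplit(cell, ";", fixed = TRUE)[[1]]) {
        parts <- strsplit(rng, "–|—|-")[[1]]
        if (length(parts) != 2L)
          stop(sprintf("read_end_table: cannot parse range '%s'", rng))
        s <- num(parts[1L]); e <- num(parts[2L])
        out <- rbind(out, data.frame(
          pm_id = tab[i, 1L],
          side = if (side_col == 2L) "five_prime" else "three_prime",
          start = s, end = e, length = array_length(s, e),
          pm_length = num(tab[i, 4L]), stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Array-length statistics straight from an end table
#'
#' Convenience wrapper: parse a published-style end table and summarize the
#' array lengths it implies.
#'
#' @param path path to the TSV (see \code{\link{read_end_table}}).
#' @return a \code{length_summary}.
#' @export
stats_from_table <- function(path) {
  arr <- read_end_table(path)
  if (nrow(arr) == 0L) stop("stats_from_table: table contains no arrays")
  summarize_lengths(arr$length)
}
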