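#' Read a chromosome-level assembly from FASTA
#'
#' Reads one record per chromosome pseudomolecule. Sequences are upper-cased
#' (soft-masking is ignored: telomeric repeats are frequently soft-masked by
#' assembly pipelines) and validated to contain only A/C/G/T/N. Record ids are
#' the first whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file, plain or gzip-compressed.
#' @return a \code{\link[Biostrings]{DNAStringSet}} in file order, names set
#'   to record ids.
#' @export
read_assembly <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("read_assembly: no such file: %s", path),
                        class = c("telomotif_missing_file", "error", "condition")))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L)
    stop(errorCondition("read_assembly: FASTA contains no records",
                        class = c("telomotif_empty_assembly", "error", "condition")))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop(errorCondition(
      sprintf("read_assembly: duplicate record id(s): %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      class = c("telomotif_duplicate_id", "error", "condition")))
  if (any(Biostrings::width(seqs) == 0L))
    stop(errorCondition(
      sprintf("read_assembly: empty record(s): %s",
              paste(ids[Biostrings::width(seqs) == 0L], collapse = ", ")),
      class = c("telomotif_empty_record", "error", "condition")))
  chr <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad))
    stop(errorCondition(
      sprintf("read_assembly: illegal character(s) in record(s): %s",
              paste(ids[bad], collapse = ", ")),
      class = c("telomotif_illegal_character", "error", "condition")))
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- ids
  out
}

#' Terminal windows of a pseudomolecule
#'
#' Returns the 5' and 3' terminal windows of one record, the regions examined
#' for telomeric arrays. Coordinates are 1-based inclusive in the
#' pseudomolecule frame; the 5' window always starts at 1 and the 3' window
#' always ends at the pseudomolecule length. Records shorter than
#' \code{window_size} yield two windows covering the whole record.
#'
#' @param sequence a single DNA string or a length-1
#'   \code{\link[Biostrings]{DNAStringSet}} / \code{DNAString}.
#' @param pm_id pseudomolecule id; defaults to the sequence's name if present.
#' @param window_size window length in bp (default 50000, comfortably larger
#'   than the longest telomeric arrays seen in chromosome-level assemblies).
#' @return list of two \code{TerminalWindow} objects (lists with fields
#'   \code{pm_id}, \code{side} ("five_prime"/"three_prime"),
#'   \code{global_start}, \code{global_end}, \code{pm_length},
#'   \code{sequence}).
#' @export
terminal_windows <- function(sequence, pm_id = NULL, window_size = 50000L) {
  if (window_size < 1L) stop("window_size must be >= 1")
  if (inherits(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    if (is.null(pm_id)) pm_id <- names(sequence)
    sequence <- as.character(sequence[[1L]])
  } else if (inherits(sequence, "DNAString")) {
    sequence <- as.character(sequence)
  }
  if (is.null(pm_id)) pm_id <- "seq"
  len <- nchar(sequence)
  w5_end <- min(window_size, len)
  w3_start <- max(1L, len - window_size + 1L)
  mk <- function(side, gs, ge) {
    structure(list(pm_id = pm_id, side = side,
                   global_start = as.numeric(gs), global_end = as.numeric(ge),
                   pm_length = as.numeric(len),
                   sequence = substr(sequence, gs, ge)),
              class = "TerminalWindow")
  }
  list(five_prime  = mk("five_prime", 1L, w5_end),
       three_prime = mk("three_prime", w3_start, len))
}

#' Terminal windows for every record of an assembly
#' @param assembly a named \code{DNAStringSet} (see \code{\link{read_assembly}}).
#' @param window_size window length in bp.
#' @return flat list of \code{TerminalWindow}s, two per record.
#' @export
assembly_windows <- function(assembly, window_size = 50000L) {
  out <- lapply(seq_along(assembly), function(i)
    terminal_windows(assembly[i], window_size = window_size))
  unlist(out, recursive = FALSE, use.names = FALSE)
}

#' @export
print.TerminalWindow <- function(x, ...) {
  cat(sprintf("TerminalWindow %s %s [%s..%s] of %s bp\n", x$pm_id, x$side,
              format(x$global_start, big.mark = ","),
              format(x$global_end, big.mark = ","),
              format(x$pm_length, big.mark = ",")))
  invisible(x)
}

#' Format a coordinate range the way assembly end tables print them
#' @param start,end 1-based inclusive coordinates.
#' @param dash range separator (default hyphen; use "–" for an en dash).
#' @return string such as "1-8005".
#' @keywords internal
format_range <- function(start, end, dash = "-") {
  # digit grouping from five digits up, matching published end tables
  # ("1-8005" but "150,122,476-150,126,493")
  one <- function(x) format(x, big.mark = if (x >= 1e4) "," else "",
                            scientific = FALSE, trim = TRUE)
  paste0(one(start), dash, one(end))
}

# The literal used for ends without a detected array, matching published
# assembly end tables.
NO_ARRAY <- "no short repeat array"

#' Write scan reports
#'
#' Emits three artifacts to \code{out_dir}: \code{ends.tsv}, a per-
#' pseudomolecule table with one cell per end holding either "start-end" or
#' the literal "no short repeat array"; \code{arrays.bed}, BED6 with the
#' 1-based inclusive coordinates converted to 0-based half-open, strand "+"
#' for arrays laid down as the G-rich class representative and "-" for
#' reverse-complement (5'-end) arrays; and \code{verdicts.json} with the
#' per-class criteria booleans and array-length statistics.
#'
#' @param arrays data.frame of detected arrays (see
#'   \code{\link{find_terminal_arrays}}).
#' @param verdicts a \code{TelomereScreen} object or NULL.
#' @param pm_lengths named numeric vector of pseudomolecule lengths, in
#'   assembly order.
#' @param out_dir output directory, created if missing.
#' @param dash range separator for the TSV (default hyphen).
#' @return invisibly, the paths written.
#' @export
write_reports <- function(arrays, verdicts, pm_lengths, out_dir, dash = "-") {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(errorCondition(sprintf("write_reports: cannot create %s", out_dir),
                        class = c("telomotif_unwritable", "error", "condition")))
  ends_path <- file.path(out_dir, "ends.tsv")
  bed_path <- file.path(out_dir, "arrays.bed")
  json_path <- file.path(out_dir, "verdicts.json")

  cell <- function(id, s) {
    hit <- arrays[arrays$pm_id == id & arrays$side == s, , drop = FALSE]
    if (nrow(hit) == 0L) return(NO_ARRAY)
    paste(mapply(format_range, hit$start, hit$end,
                 MoreArgs = list(dash = dash)), collapse = ";")
  }
  ends <- data.frame(
    accession = names(pm_lengths),
    five_prime = vapply(names(pm_lengths), cell, character(1), s = "five_prime"),
    three_prime = vapply(names(pm_lengths), cell, character(1), s = "three_prime"),
    size_bp = format(unname(pm_lengths), big.mark = ",", scientific = FALSE,
                     trim = TRUE),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(ends, ends_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (nrow(arrays) > 0L) {
    bed <- data.frame(
      chrom = arrays$pm_id,
      start = format(arrays$start - 1, scientific = FALSE, trim = TRUE),
      end = format(arrays$end, scientific = FALSE, trim = TRUE),
      name = sprintf("(%s)n", arrays$oriented_motif),
      score = round(1000 * arrays$purity),
      strand = ifelse(vapply(seq_len(nrow(arrays)), function(i)
        is_rotation_of(arrays$oriented_motif[i], arrays$motif[i]), logical(1)),
        "+", "-"),
      stringsAsFactors = FALSE
    )
  } else {
    bed <- data.frame(chrom = character(), start = character(),
                      end = character(), name = character(),
                      score = numeric(), strand = character())
  }
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  jsonlite::write_json(screen_as_list(verdicts, arrays), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(ends = ends_path, bed = bed_path, json = json_path))
}

#' Read back a BED6 written by \code{write_reports}
#' @param path path to the BED file.
#' @return data.frame with 1-based inclusive \code{start}, \code{end}.
#' @export
read_array_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(pm_id = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      strand = character()))
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed) <- c("pm_id", "start", "end", "name", "score", "strand")
  bed$start <- bed$start + 1  # back to 1-based inclusive
  bed
}
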