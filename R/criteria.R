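#' Criterion 1: strictly terminal placement
#'
#' A telomeric array must reach (or very nearly reach) the pseudomolecule
#' terminus: the outer edge of a 5' array is its start, of a 3' array its
#' end. Passes when every array's outer edge lies within \code{max_offset}
#' bp of its terminus.
#'
#' @param arrays data.frame of arrays for one motif class.
#' @param pm_lengths named numeric vector of pseudomolecule lengths.
#' @param max_offset tolerance in bp (default 100).
#' @return a \code{CriterionResult} list: \code{criterion_id}, \code{passed},
#'   \code{evidence} data.frame.
#' @export
check_terminal <- function(arrays, pm_lengths, max_offset = 100) {
  off <- ifelse(arrays$side == "five_prime",
                arrays$start - 1,
                pm_lengths[arrays$pm_id] - arrays$end)
  ev <- data.frame(pm_id = arrays$pm_id, side = arrays$side,
                   offset = unname(off), stringsAsFactors = FALSE)
  criterion_result(1L, nrow(arrays) > 0L && all(off <= max_offset), ev)
}

#' Criterion 2: minimum span
#'
#' At least one array of the class must span \code{min_span} bp. The
#' threshold is interpreted at motif level, not per array: a class qualified
#' by its long arrays keeps its short ones reportable (terminal arrays of a
#' genuine telomeric motif can be a few hundred bp where the assembly
#' truncates the telomere).
#'
#' @param arrays data.frame of arrays for one motif class.
#' @param min_span minimum span in bp (default 300, the lower bound of the
#'   300-400 bp convention for candidate telomeric repeats).
#' @return a \code{CriterionResult}.
#' @export
check_span <- function(arrays, min_span = 300) {
  ev <- data.frame(pm_id = arrays$pm_id, side = arrays$side,
                   length = arrays$length, stringsAsFactors = FALSE)
  criterion_result(2L, nrow(arrays) > 0L && any(arrays$length >= min_span), ev)
}

#' Criterion 3: identical sequence across chromosomes
#'
#' All arrays attributed to the class must carry the same repeat: one motif
#' class (guaranteed by construction) and mutually consistent oriented
#' spellings, i.e. every spelling is the same string up to rotation and
#' strand.
#'
#' @param arrays data.frame of arrays for one motif class (column
#'   \code{oriented_motif}).
#' @return a \code{CriterionResult}; evidence lists per-array spellings.
#' @export
check_identity_across_chromosomes <- function(arrays) {
  ev <- data.frame(pm_id = arrays$pm_id, side = arrays$side,
                   oriented_motif = arrays$oriented_motif,
                   motif = arrays$motif, stringsAsFactors = FALSE)
  if (nrow(arrays) == 0L) return(criterion_result(3L, FALSE, ev))
  one_class <- length(unique(arrays$motif)) == 1L
  rep0 <- arrays$motif[1L]
  consistent <- all(vapply(arrays$oriented_motif, function(m)
    is_rotation_of(m, rep0) || is_rotation_of(m, rc_string(rep0)),
    logical(1)))
  criterion_result(3L, one_class && consistent, ev)
}

#' Criterion 4: alternative motifs absent or extremely uncommon
#'
#' For each pseudomolecule end carrying an array of the candidate class,
#' computes the fraction of the terminal window covered by arrays of other
#' motif classes (detected without the terminal anchor). Passes when every
#' such fraction is at most \code{max_alt_fraction}. Ends without a candidate
#' array are not evaluated.
#'
#' @param windows list of \code{TerminalWindow}s for the assembly.
#' @param arrays data.frame of arrays of the candidate class.
#' @param params \code{\link{scan_params}}; \code{max_alt_fraction} defaults
#'   to 0.05.
#' @param all_window_arrays optional precomputed result of
#'   \code{\link{find_window_arrays}} on every window (list keyed by
#'   \code{pm_id|side}), to avoid rescanning when several classes are
#'   evaluated.
#' @return a \code{CriterionResult}; evidence gives per-end alternative
#'   coverage fractions.
#' @export
check_no_alternatives <- function(windows, arrays, params = scan_params(),
                                  all_window_arrays = NULL) {
  key <- function(w) paste(w$pm_id, w$side, sep = "|")
  ev <- data.frame(pm_id = character(), side = character(),
                   alt_fraction = numeric(), stringsAsFactors = FALSE)
  if (nrow(arrays) == 0L) return(criterion_result(4L, FALSE, ev))
  cls <- arrays$motif[1L]
  pass <- TRUE
  for (w in windows) {
    carries <- any(arrays$pm_id == w$pm_id & arrays$side == w$side)
    if (!carries) next
    wa <- if (!is.null(all_window_arrays)) all_window_arrays[[key(w)]] else
      find_window_arrays(w, params)
    alt <- wa[wa$motif != cls, , drop = FALSE]
    wlen <- w$global_end - w$global_start + 1
    frac <- if (nrow(alt) == 0L) 0 else sum(alt$length) / wlen
    ev <- rbind(ev, data.frame(pm_id = w$pm_id, side = w$side,
                               alt_fraction = frac, stringsAsFactors = FALSE))
    if (frac > params$max_alt_fraction) pass <- FALSE
  }
  criterion_result(4L, pass, ev)
}

#' Criterion 5: reverse-complementary organization at opposite ends
#'
#' On every pseudomolecule where the class occurs at both ends, the 5'
#' oriented motif must be the reverse complement (up to rotation) of the 3'
#' oriented motif -- the signature of a telomere laid down on the G-rich
#' strand running toward each terminus. Vacuously true when no pseudomolecule
#' carries the class at both ends.
#'
#' @param arrays data.frame of arrays for one motif class.
#' @return a \code{CriterionResult}; evidence lists both-end pseudomolecules
#'   and their spellings.
#' @export
check_opposite_end_orientation <- function(arrays) {
  ev <- data.frame(pm_id = character(), motif_5p = character(),
                   motif_3p = character(), revcomp_pair = logical(),
                   stringsAsFactors = FALSE)
  if (nrow(arrays) == 0L) return(criterion_result(5L, FALSE, ev))
  pass <- TRUE
  for (id in unique(arrays$pm_id)) {
    m5 <- arrays$oriented_motif[arrays$pm_id == id &
                                  arrays$side == "five_prime"]
    m3 <- arrays$oriented_motif[arrays$pm_id == id &
                                  arrays$side == "three_prime"]
    if (length(m5) == 0L || length(m3) == 0L) next
    for (a in m5) for (b in m3) {
      ok <- is_rotation_of(rc_string(a), b)
      ev <- rbind(ev, data.frame(pm_id = id, motif_5p = a, motif_3p = b,
                                 revcomp_pair = ok, stringsAsFactors = FALSE))
      if (!ok) pass <- FALSE
    }
  }
  criterion_result(5L, pass, ev)
}

criterion_result <- function(id, passed, evidence) {
  structure(list(criterion_id = id, passed = isTRUE(passed),
                 evidence = evidence),
            class = "CriterionResult")
}

#' @export
print.CriterionResult <- function(x, ...) {
  cat(sprintf("Criterion %d: %s (%d evidence record%s)\n", x$criterion_id,
              if (x$passed) "PASS" else "FAIL", nrow(x$evidence),
              if (nrow(x$evidence) == 1L) "" else "s"))
  invisible(x)
}

#' Evaluate one motif class against all five criteria
#'
#' @param arrays data.frame of terminal arrays of this class across the
#'   assembly.
#' @param windows list of \code{TerminalWindow}s for the assembly.
#' @param pm_lengths named numeric vector of pseudomolecule lengths.
#' @param params \code{\link{scan_params}}.
#' @param all_window_arrays optional precomputed unanchored scans (see
#'   \code{\link{check_no_alternatives}}).
#' @return a \code{MotifVerdict}: list with \code{motif} (class
#'   representative), \code{arrays}, \code{criteria} (list of five
#'   \code{CriterionResult}s), \code{qualified}, and \code{rank_key}
#'   (array count, total length).
#' @export
evaluate_motif <- function(arrays, windows, pm_lengths,
                           params = scan_params(),
                           all_window_arrays = NULL) {
  criteria <- list(
    check_terminal(arrays, pm_lengths, params$max_offset),
    check_span(arrays, params$min_span),
    check_identity_across_chromosomes(arrays),
    check_no_alternatives(windows, arrays, params, all_window_arrays),
    check_opposite_end_orientation(arrays)
  )
  structure(list(
    motif = if (nrow(arrays) > 0L) arrays$motif[1L] else NA_character_,
    arrays = arrays,
    criteria = criteria,
    qualified = all(vapply(criteria, `[[`, logical(1), "passed")),
    rank_key = c(n_arrays = nrow(arrays), total_length = sum(arrays$length))
  ), class = "MotifVerdict")
}

#' @export
print.MotifVerdict <- function(x, ...) {
  cat(sprintf("MotifVerdict (%s)n: %s; %d arrays, %g bp total\n", x$motif,
              if (x$qualified) "qualified" else "not qualified",
              x$rank_key[["n_arrays"]], x$rank_key[["total_length"]]))
  for (cr in x$criteria) print(cr)
  invisible(x)
}

#' Nominate the best telomeric-motif candidate
#'
#' Among qualified classes, the one with the most terminal arrays (ties
#' broken by total array length) is nominated. When no class qualifies the
#' verdict is negative; the nearest-miss class (most criteria passed, then
#' rank key) and its failed criteria are recorded.
#'
#' @param verdicts list of \code{MotifVerdict}s.
#' @return list of class \code{Nomination}: \code{nominated} (motif string or
#'   NULL), \code{qualified} (character vector), \code{negative} flag,
#'   \code{nearest_miss} (motif or NULL), \code{failed_criteria} (integer
#'   vector for the nearest miss).
#' @export
nominate <- function(verdicts) {
  if (length(verdicts) == 0L)
    return(structure(list(nominated = NULL, qualified = character(0),
                          negative = TRUE, nearest_miss = NULL,
                          failed_criteria = integer(0)),
                     class = "Nomination"))
  qual <- Filter(function(v) v$qualified, verdicts)
  if (length(qual) > 0L) {
    keys <- t(vapply(qual, `[[`, numeric(2), "rank_key"))
    best <- qual[[order(-keys[, 1L], -keys[, 2L])[1L]]]
    return(structure(list(nominated = best$motif,
                          qualified = vapply(qual, `[[`, character(1), "motif"),
                          negative = FALSE, nearest_miss = NULL,
                          failed_criteria = integer(0)),
                     class = "Nomination"))
  }
  n_pass <- vapply(verdicts, function(v)
    sum(vapply(v$criteria, `[[`, logical(1), "passed")), numeric(1))
  keys <- t(vapply(verdicts, `[[`, numeric(2), "rank_key"))
  near <- verdicts[[order(-n_pass, -keys[, 1L], -keys[, 2L])[1L]]]
  failed <- vapply(Filter(function(cr) !cr$passed, near$criteria),
                   `[[`, integer(1), "criterion_id")
  structure(list(nominated = NULL, qualified = character(0), negative = TRUE,
                 nearest_miss = near$motif, failed_criteria = failed),
            class = "Nomination")
}

#' @export
print.Nomination <- function(x, ...) {
  if (x$negative) {
    cat("Negative verdict: no motif class met all five criteria.\n")
    if (!is.null(x$nearest_miss))
      cat(sprintf("  nearest miss (%s)n, failed criteria: %s\n",
                  x$nearest_miss, paste(x$failed_criteria, collapse = ", ")))
  } else {
    cat(sprintf("Nominated telomeric motif: (%s)n\n", x$nominated))
  }
  invisible(x)
}

#' Full telomere screen of an assembly
#'
#' Runs the whole evaluation: terminal windows, anchored array scan, grouping
#' by motif class, the five criteria per class, and nomination.
#'
#' @param assembly named \code{DNAStringSet} (see \code{\link{read_assembly}}).
#' @param params \code{\link{scan_params}}.
#' @return object of class \code{TelomereScreen}: list with \code{arrays}
#'   (all detected terminal arrays), \code{verdicts} (per class),
#'   \code{nomination}, \code{pm_lengths}, \code{params}.
#' @export
screen_assembly <- function(assembly, params = scan_params()) {
  pm_lengths <- stats::setNames(as.numeric(Biostrings::width(assembly)),
                                names(assembly))
  windows <- assembly_windows(assembly, window_size = params$window_size)
  arrays <- do.call(rbind, c(list(empty_arrays()),
                             lapply(windows, find_terminal_arrays,
                                    params = params)))
  rownames(arrays) <- NULL
  # unanchored scans are shared across classes for criterion 4
  wa <- NULL
  if (nrow(arrays) > 0L) {
    need <- unique(paste(arrays$pm_id, arrays$side, sep = "|"))
    wa <- list()
    for (w in windows) {
      kk <- paste(w$pm_id, w$side, sep = "|")
      if (kk %in% need) wa[[kk]] <- find_window_arrays(w, params)
    }
  }
  verdicts <- lapply(split(arrays, arrays$motif), evaluate_motif,
                     windows = windows, pm_lengths = pm_lengths,
                     params = params, all_window_arrays = wa)
  structure(list(arrays = arrays, verdicts = unname(verdicts),
                 nomination = nominate(unname(verdicts)),
                 pm_lengths = pm_lengths, params = params),
            class = "TelomereScreen")
}

#' @export
print.TelomereScreen <- function(x, ...) {
  cat(sprintf("TelomereScreen of %d pseudomolecule(s): %d terminal array(s), %d motif class(es)\n",
              length(x$pm_lengths), nrow(x$arrays), length(x$verdicts)))
  print(x$nomination)
  invisible(x)
}

# JSON-ready representation of a TelomereScreen (or NULL).
screen_as_list <- function(screen, arrays = NULL) {
  if (is.null(screen)) {
    return(list(classes = list(),
                arrays = if (is.null(arrays)) list() else arrays,
                nomination = list(negative = TRUE)))
  }
  cls <- lapply(screen$verdicts, function(v) {
    qlens <- v$arrays$length
    list(
      motif = v$motif,
      qualified = v$qualified,
      nominated = identical(v$motif, screen$nomination$nominated),
      rank_key = as.list(v$rank_key),
      criteria = lapply(v$criteria, function(cr)
        list(id = cr$criterion_id, passed = cr$passed,
             evidence = cr$evidence)),
      statistics = tryCatch(unclass(summarize_lengths(qlens)),
                            error = function(e) NULL)
    )
  })
  list(classes = cls, arrays = screen$arrays,
       nomination = list(
         negative = screen$nomination$negative,
         nominated = screen$nomination$nominated,
         nearest_miss = screen$nomination$nearest_miss,
         failed_criteria = screen$nomination$failed_criteria))
}
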