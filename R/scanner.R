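#' Scan parameters for terminal tandem-array detection
#'
#' @param k_min,k_max motif length range in bp searched (default 2-25, the
#'   motif-size range profiled by short-read telomere pipelines).
#' @param min_purity minimum fraction of array positions matching the
#'   phase-aligned ideal repeat (default 0.90).
#' @param min_copies minimum motif copy number for a reportable array
#'   (default 10).
#' @param max_offset maximum distance in bp between an array's outer edge and
#'   the pseudomolecule terminus for the "strictly terminal" criterion
#'   (default 100).
#' @param seed_region bp at the outer end of each window from which candidate
#'   motifs are enumerated (default 200); a telomeric array must reach the
#'   terminus, so its motif must appear terminally.
#' @param max_interruption_factor an array ends when more than
#'   \code{max_interruption_factor * k} consecutive bases mismatch the ideal
#'   repeat (default 2).
#' @param min_span minimum span in bp at least one array of a class must reach
#'   for the class to qualify (default 300).
#' @param max_alt_fraction maximum fraction of a terminal window that arrays
#'   of other motif classes may cover (default 0.05).
#' @param window_size terminal window length in bp (default 50000).
#' @return a list of class \code{scan_params}.
#' @export
scan_params <- function(k_min = 2L, k_max = 25L, min_purity = 0.90,
                        min_copies = 10L, max_offset = 100L,
                        seed_region = 200L, max_interruption_factor = 2L,
                        min_span = 300L, max_alt_fraction = 0.05,
                        window_size = 50000L) {
  stopifnot(k_min >= 2L, k_max <= 25L, k_min <= k_max,
            min_purity > 0, min_purity <= 1, min_copies >= 2L,
            max_offset >= 0L, seed_region >= 1L, min_span >= 1L,
            max_alt_fraction >= 0, max_alt_fraction <= 1, window_size >= 1L)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 min_purity = min_purity, min_copies = as.integer(min_copies),
                 max_offset = as.integer(max_offset),
                 seed_region = as.integer(seed_region),
                 max_interruption_factor = max_interruption_factor,
                 min_span = as.integer(min_span),
                 max_alt_fraction = max_alt_fraction,
                 window_size = as.integer(window_size)),
            class = "scan_params")
}

#' Purity of a segment against a motif
#'
#' Fraction of positions equal to the phase-aligned infinite repetition of
#' \code{oriented_motif}, maximized over the k possible phases. \code{N}
#' never matches.
#'
#' @param segment DNA string.
#' @param oriented_motif DNA motif as laid down 5'->3' on the same strand.
#' @return purity in [0, 1].
#' @export
#' @examples
#' array_purity("TTAGGTTAGG", "TTAGG")  # 1.0
#' array_purity("TTAGGTTCGG", "TTAGG")  # 0.9
array_purity <- function(segment, oriented_motif) {
  if (nchar(segment) == 0L || nchar(oriented_motif) == 0L)
    stop("array_purity: empty input")
  if (nchar(segment) < nchar(oriented_motif))
    stop("array_purity: segment shorter than motif")
  chars <- strsplit(toupper(segment), "", fixed = TRUE)[[1]]
  m <- strsplit(toupper(oriented_motif), "", fixed = TRUE)[[1]]
  k <- length(m)
  n <- length(chars)
  best <- 0
  for (p in 0:(k - 1L)) {
    ideal <- m[((seq_len(n) - 1L + p) %% k) + 1L]
    best <- max(best, mean(chars == ideal))
  }
  best
}

# Left-rotate motif string by j positions.
rot <- function(m, j) {
  k <- nchar(m)
  j <- j %% k
  if (j == 0L) return(m)
  paste0(substr(m, j + 1L, k), substr(m, 1L, j))
}

# Boolean match vector of chars against motif m tiled from position 1 with
# phase p (i.e. position i is compared with m[(i-1+p) mod k + 1]). N never
# matches because motifs contain only A/C/G/T.
match_vector <- function(chars, m_chars, p) {
  k <- length(m_chars)
  chars == m_chars[((seq_along(chars) - 1L + p) %% k) + 1L]
}

# Candidate motif classes seeded from exact tandem duplications.
#
# A k-mer starting at i is a seed when it is immediately followed by an exact
# copy of itself, i.e. the lag-k self-match vector holds a run of >= k TRUEs
# at i. Non-primitive k-mers and k-mers containing N are skipped. Each seed
# pins down the tiling it belongs to -- the strand spelling and the phase of
# the ideal repeat -- so the scan only needs to test the tilings actually
# observed, not all 2k of them. Returns a list of
# list(class = MotifClass, tilings = data.frame(strand, shift)).
tandem_seed_classes <- function(seq_string, chars, params,
                                region_end = length(chars)) {
  n <- length(chars)
  found <- list()
  for (k in params$k_min:params$k_max) {
    if (2L * k > n) break
    lim <- min(region_end + 2L * k, n)
    eq <- chars[seq_len(lim - k)] == chars[(k + 1L):lim]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= k)
    if (length(hit) == 0L) next
    pos <- starts[hit]
    pos <- pos[pos <= region_end]
    if (length(pos) == 0L) next
    kmers <- substring(seq_string, pos, pos + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    kmers <- kmers[ok]
    pos <- pos[ok]
    for (km in unique(kmers)) {
      if (!is_primitive(km)) next
      cl <- canonical_class(km)
      rep0 <- cl$representative
      idx <- match(km, rotations(rep0))
      if (!is.na(idx)) {
        strand <- "+"
        rr <- idx - 1L
      } else {
        strand <- "-"
        rr <- match(km, rotations(rc_string(rep0))) - 1L
      }
      # phase p of the tiling ideal[i] = spell[(i - 1 + p) %% k + 1] that
      # lays km down at seed position pos: p = (rr - pos + 1) mod k
      shifts <- unique((rr - pos[kmers == km] + 1L) %% k)
      ent <- found[[rep0]]
      if (is.null(ent))
        ent <- list(class = cl,
                    tilings = data.frame(strand = character(),
                                         shift = integer(),
                                         stringsAsFactors = FALSE))
      for (sh in shifts) {
        if (nrow(ent$tilings) >= 8L) break
        if (!any(ent$tilings$strand == strand & ent$tilings$shift == sh))
          ent$tilings <- rbind(ent$tilings,
                               data.frame(strand = strand, shift = sh,
                                          stringsAsFactors = FALSE))
      }
      found[[rep0]] <- ent
    }
  }
  unname(found)
}

# Greedy boundary walk used to forgive isolated mismatches at an array
# edge: from position `from`, step through matches, and cross a single
# mismatch only when at least two matches follow it; stop at two consecutive
# mismatches, at `from + limit`, or at the end of the vector.
boundary_extend <- function(vv, from, limit) {
  n <- length(vv)
  j <- from
  lim <- from + limit
  while (j < min(n, lim)) {
    if (vv[j + 1L]) {
      j <- j + 1L
    } else if (j + 3L <= n && vv[j + 2L] && vv[j + 3L]) {
      j <- j + 3L
    } else {
      break
    }
  }
  j
}

# Mismatch penalty of the boundary walk, on a +1-per-match scale. Motivated
# by the likelihood ratio between in-array positions (~0.9+ match) and
# background positions (~0.25 match): log(0.95/0.25) / log(0.75/0.05) ~ 1:2.
BOUNDARY_MISMATCH_PENALTY <- 2

# All qualifying runs of one tiling (motif spelling m, phase p) in a match
# vector. Runs are delimited by mismatch stretches longer than max_run and
# trimmed to matching boundaries. Each boundary is then refined by a scoring
# walk (match +1, mismatch -2): the end is the furthest position maximizing
# the cumulative score among positions that terminate at least two
# consecutive matches, so an array cannot leak into background that matches
# the tiling only by chance; the start is refined symmetrically. Finally the
# end is pulled back, if needed, to the furthest position keeping overall
# purity >= min_purity.
#
# anchor_limit, when finite, skips segments starting beyond that offset
# (terminus-anchored scans only need the outermost segment).
scan_phase_runs <- function(v, k, params, anchor_limit = Inf) {
  n <- length(v)
  max_run <- ceiling(params$max_interruption_factor * k)
  min_len <- params$min_copies * k
  r <- rle(v)
  rends <- cumsum(r$lengths)
  rstarts <- rends - r$lengths + 1L
  gap <- which(!r$values & r$lengths > max_run)
  seg_starts <- c(1L, rends[gap] + 1L)
  seg_ends <- c(rstarts[gap] - 1L, n)
  # cheap vectorized prefilter: a qualifying run needs min_len positions of
  # which at least min_purity are matches
  cs0 <- c(0, cumsum(v))
  keep <- (seg_ends - seg_starts + 1L) >= min_len &
    (cs0[seg_ends + 1L] - cs0[seg_starts]) >= params$min_purity * min_len &
    seg_starts <= anchor_limit + 1L
  out <- list()
  pen <- BOUNDARY_MISMATCH_PENALTY
  for (s in which(keep)) {
    a <- seg_starts[s]; b <- seg_ends[s]
    vv <- v[a:b]
    tr <- which(vv)
    if (length(tr) < params$min_purity * min_len) next
    a2 <- a + tr[1L] - 1L
    b2 <- a + tr[length(tr)] - 1L
    if (b2 - a2 + 1L < min_len) next
    if (a2 > anchor_limit + 1L) next
    vv <- v[a2:b2]
    m <- length(vv)
    csv <- cumsum(vv)
    sc <- csv * (1 + pen) - pen * seq_len(m)  # match +1, mismatch -pen
    pair <- vv & c(TRUE, vv[-m])              # >= 2 trailing matches
    pair[1L] <- vv[1L]
    cand_e <- which(pair)
    cand_s <- which(vv & c(vv[-1L], TRUE))    # >= 2 leading matches
    if (length(cand_e) == 0L || length(cand_s) == 0L) next
    e_local <- cand_e[max(which(sc[cand_e] == max(sc[cand_e])))]
    # start walk: same rule on the reversed vector
    rsc <- (csv[m] - c(0, csv[-m])) * (1 + pen) -
      pen * (m - seq_len(m) + 1L)
    s_local <- cand_s[min(which(rsc[cand_s] == max(rsc[cand_s])))]
    if (s_local > e_local || e_local - s_local + 1L < min_len) next
    # furthest end keeping overall purity above threshold
    cand <- cand_e[cand_e >= s_local + min_len - 1L & cand_e <= e_local]
    if (length(cand) == 0L) next
    base <- if (s_local > 1L) csv[s_local - 1L] else 0
    pur <- (csv[cand] - base) / (cand - s_local + 1L)
    ok <- cand[pur >= params$min_purity]
    if (length(ok) == 0L) next
    e_local <- max(ok)
    # forgive isolated mismatches at the boundaries: cross a single
    # mismatch when two matches follow, up to 2k bases. A degraded array
    # tail of scattered substitutions is recovered; a region of two or
    # more consecutive mismatches still terminates the array.
    e_ext <- boundary_extend(vv, e_local, 2L * k)
    s_ext <- m + 1L - boundary_extend(rev(vv), m + 1L - s_local, 2L * k)
    base2 <- if (s_ext > 1L) csv[s_ext - 1L] else 0
    pur2 <- (csv[e_ext] - base2) / (e_ext - s_ext + 1L)
    if (pur2 >= params$min_purity) {
      e_local <- e_ext
      s_local <- s_ext
    }
    base <- if (s_local > 1L) csv[s_local - 1L] else 0
    out[[length(out) + 1L]] <- c(
      start = a2 + s_local - 1L,
      end = a2 + e_local - 1L,
      purity = (csv[e_local] - base) / (e_local - s_local + 1L))
  }
  out
}

# Runs of one class for the tilings its seeds pin down. Each tiling's match
# vector is pre-screened with a rolling sum (a qualifying run must contain a
# min_len window at min_purity) and the expensive segment analysis is
# restricted to the neighbourhood of the dense region. Returns a list of
# list(start, end, purity, spell, p).
scan_class_tilings <- function(chars, cl, tilings, params,
                               anchor_limit = Inf) {
  k <- cl$k
  min_len <- params$min_copies * k
  n <- length(chars)
  if (n < min_len) return(list())
  res <- list()
  for (t in seq_len(nrow(tilings))) {
    spell <- if (tilings$strand[t] == "+") cl$representative else
      rc_string(cl$representative)
    p <- tilings$shift[t]
    v <- match_vector(chars, strsplit(spell, "", fixed = TRUE)[[1]], p)
    cs0 <- c(0, cumsum(v))
    roll <- cs0[(min_len + 1L):(n + 1L)] - cs0[seq_len(n - min_len + 1L)]
    hit <- which(roll >= params$min_purity * min_len)
    if (length(hit) == 0L) next
    if (hit[1L] > anchor_limit + min_len) next
    lo <- max(1L, hit[1L] - 2L * min_len)
    hi <- min(n, hit[length(hit)] + 3L * min_len)
    runs <- scan_phase_runs(v[lo:hi], k, params,
                            anchor_limit = if (is.finite(anchor_limit))
                              anchor_limit - (lo - 1L) else Inf)
    for (run in runs)
      res[[length(res) + 1L]] <- list(
        start = unname(run[["start"]]) + lo - 1L,
        end = unname(run[["end"]]) + lo - 1L,
        purity = unname(run[["purity"]]), spell = spell, p = p)
  }
  res
}

# Best terminus-anchored run for one class in scan space (terminus at
# position 1): longest span, ties broken by purity. Returns NULL or
# list(start, end, purity, oriented) where oriented is the ideal motif
# rotation laid down at the run start.
scan_class_anchored <- function(chars, cl, tilings, params) {
  best <- NULL
  for (run in scan_class_tilings(chars, cl, tilings, params,
                                 anchor_limit = params$seed_region)) {
    if (run$start - 1L > params$seed_region) next
    if (is.null(best) ||
        (run$end - run$start) > (best$end - best$start) ||
        ((run$end - run$start) == (best$end - best$start) &&
         run$purity > best$purity)) {
      best <- list(start = run$start, end = run$end, purity = run$purity,
                   oriented = rot(run$spell, (run$start - 1L + run$p) %% cl$k))
    }
  }
  best
}

# All qualifying runs of one class anywhere in scan space, merged across
# tilings into non-overlapping intervals.
scan_class_all <- function(chars, cl, tilings, params) {
  ivs <- matrix(numeric(0), ncol = 2)
  for (run in scan_class_tilings(chars, cl, tilings, params))
    ivs <- rbind(ivs, c(run$start, run$end))
  if (nrow(ivs) == 0L) return(ivs)
  ivs <- ivs[order(ivs[, 1L], ivs[, 2L]), , drop = FALSE]
  merged <- ivs[1L, , drop = FALSE]
  if (nrow(ivs) > 1L) for (i in 2L:nrow(ivs)) {
    last <- nrow(merged)
    if (ivs[i, 1L] <= merged[last, 2L] + 1L) {
      merged[last, 2L] <- max(merged[last, 2L], ivs[i, 2L])
    } else {
      merged <- rbind(merged, ivs[i, , drop = FALSE])
    }
  }
  merged
}

empty_arrays <- function() {
  data.frame(pm_id = character(), side = character(), start = numeric(),
             end = numeric(), length = numeric(), motif = character(),
             k = integer(), oriented_motif = character(), purity = numeric(),
             copy_number = numeric(), stringsAsFactors = FALSE)
}

# Map a run found in scan space back to the pseudomolecule frame.
scan_to_global <- function(window, run_start, run_end, oriented) {
  L <- nchar(window$sequence)
  if (window$side == "five_prime") {
    list(start = window$global_start + run_start - 1,
         end = window$global_start + run_end - 1,
         oriented = oriented)
  } else {
    list(start = window$global_start + (L - run_end + 1) - 1,
         end = window$global_start + (L - run_start + 1) - 1,
         oriented = rc_string(oriented))
  }
}

#' Detect tandem-repeat arrays anchored at a window's outer terminus
#'
#' Candidate motifs are seeded from exact tandem duplications in the
#' outermost \code{seed_region} bp of the window (a telomeric array must
#' reach the terminus), grouped into rotation/reverse-complement classes, and
#' each class is extended inward for as long as overall purity stays at or
#' above \code{min_purity} and no mismatch interruption exceeds
#' \code{max_interruption_factor * k} bases. Three-prime windows are scanned
#' on the reverse-complement strand so both ends are treated symmetrically;
#' coordinates are mapped back to the forward strand.
#'
#' Overlapping detections of different motif length explaining the same span
#' are resolved in favour of the smaller k, then the higher purity.
#'
#' @param window a \code{TerminalWindow} (see \code{\link{terminal_windows}}).
#' @param params a \code{\link{scan_params}} object.
#' @return data.frame with one row per detected array: \code{pm_id},
#'   \code{side}, 1-based inclusive \code{start}/\code{end} in the
#'   pseudomolecule frame, \code{length}, \code{motif} (canonical class
#'   representative), \code{k}, \code{oriented_motif} (forward-strand
#'   spelling), \code{purity}, \code{copy_number}.
#' @export
find_terminal_arrays <- function(window, params = scan_params()) {
  seq_scan <- if (window$side == "five_prime") window$sequence else
    rc_string(window$sequence)
  chars <- strsplit(seq_scan, "", fixed = TRUE)[[1]]
  classes <- tandem_seed_classes(seq_scan, chars, params,
                                 region_end = min(params$seed_region,
                                                  length(chars)))
  rows <- empty_arrays()
  for (ent in classes) {
    cl <- ent$class
    hit <- scan_class_anchored(chars, cl, ent$tilings, params)
    if (is.null(hit)) next
    g <- scan_to_global(window, hit$start, hit$end, hit$oriented)
    rows <- rbind(rows, data.frame(
      pm_id = window$pm_id, side = window$side,
      start = g$start, end = g$end, length = g$end - g$start + 1,
      motif = cl$representative, k = cl$k, oriented_motif = g$oriented,
      purity = hit$purity, copy_number = (g$end - g$start + 1) / cl$k,
      stringsAsFactors = FALSE))
  }
  resolve_overlaps(rows)
}

#' Detect tandem-repeat arrays anywhere in a window
#'
#' Unanchored variant used to quantify alternative-motif coverage: seeds are
#' taken from the whole window and every qualifying run is reported, merged
#' per class into non-overlapping intervals.
#'
#' @inheritParams find_terminal_arrays
#' @return data.frame as in \code{\link{find_terminal_arrays}} (without
#'   \code{oriented_motif} resolution beyond the class spelling used).
#' @export
find_window_arrays <- function(window, params = scan_params()) {
  seq_scan <- if (window$side == "five_prime") window$sequence else
    rc_string(window$sequence)
  chars <- strsplit(seq_scan, "", fixed = TRUE)[[1]]
  classes <- tandem_seed_classes(seq_scan, chars, params)
  rows <- empty_arrays()
  for (ent in classes) {
    cl <- ent$class
    ivs <- scan_class_all(chars, cl, ent$tilings, params)
    if (nrow(ivs) == 0L) next
    for (i in seq_len(nrow(ivs))) {
      seg <- substr(seq_scan, ivs[i, 1L], ivs[i, 2L])
      pur <- max(array_purity(seg, cl$representative),
                 array_purity(seg, rc_string(cl$representative)))
      g <- scan_to_global(window, ivs[i, 1L], ivs[i, 2L], cl$representative)
      rows <- rbind(rows, data.frame(
        pm_id = window$pm_id, side = window$side,
        start = g$start, end = g$end, length = g$end - g$start + 1,
        motif = cl$representative, k = cl$k,
        oriented_motif = g$oriented, purity = pur,
        copy_number = (g$end - g$start + 1) / cl$k,
        stringsAsFactors = FALSE))
    }
  }
  resolve_overlaps(rows)
}

# Overlap resolution: among arrays at the same end overlapping more than half
# of the shorter one, keep the smaller motif (primitive parsimony), then the
# higher purity, then the longer span.
resolve_overlaps <- function(arrays) {
  if (nrow(arrays) <= 1L) return(arrays)
  ord <- order(arrays$k, -arrays$purity, -arrays$length)
  arrays <- arrays[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(arrays))
  for (i in seq_len(nrow(arrays) - 1L)) {
    if (!keep[i]) next
    for (j in (i + 1L):nrow(arrays)) {
      if (!keep[j]) next
      if (arrays$pm_id[j] != arrays$pm_id[i] ||
          arrays$side[j] != arrays$side[i]) next
      if (arrays$motif[j] == arrays$motif[i]) next
      ov <- min(arrays$end[i], arrays$end[j]) -
        max(arrays$start[i], arrays$start[j]) + 1
      if (ov > 0.5 * min(arrays$length[i], arrays$length[j])) keep[j] <- FALSE
    }
  }
  out <- arrays[keep, , drop = FALSE]
  out <- out[order(out$pm_id, out$side, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan every terminal window of an assembly
#' @param assembly named \code{DNAStringSet}.
#' @param params a \code{\link{scan_params}} object.
#' @return data.frame of all detected terminal arrays.
#' @export
scan_assembly <- function(assembly, params = scan_params()) {
  windows <- assembly_windows(assembly, window_size = params$window_size)
  rows <- lapply(windows, find_terminal_arrays, params = params)
  out <- do.call(rbind, c(list(empty_arrays()), rows))
  rownames(out) <- NULL
  out
}
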