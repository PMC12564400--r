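#' Reverse complement of a plain DNA string
#'
#' Thin wrapper used throughout the package for short motifs and templates.
#' `N` complements to `N`.
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' rc_string("TTGGG")  # "CCCAA"
rc_string <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' All cyclic rotations of a string
#' @param m a single string.
#' @return character vector of length \code{nchar(m)}; element j is m rotated
#'   left by j-1 positions.
#' @export
rotations <- function(m) {
  k <- nchar(m)
  doubled <- paste0(m, m)
  vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L), character(1))
}

#' Is a motif primitive (not a power of a shorter string)?
#'
#' A motif such as "ATAT" is a power of "AT" and does not define its own
#' repeat class; only primitive motifs are admitted.
#'
#' @param m a single string.
#' @return logical.
#' @export
is_primitive <- function(m) {
  k <- nchar(m)
  if (k <= 1L) return(k == 1L)
  for (d in seq_len(k %/% 2L)) {
    if (k %% d == 0L) {
      unit <- substr(m, 1L, d)
      if (paste(rep(unit, k %/% d), collapse = "") == m) return(FALSE)
    }
  }
  TRUE
}

#' Canonical motif class under rotation and reverse complement
#'
#' Telomeric repeats are read off an assembly in an arbitrary phase and on an
#' arbitrary strand: the same telomere surfaces as (TTGGG)n at 3' ends and
#' (CCCAA)n at 5' ends. All 2k spellings (k rotations on each strand) of a
#' k-bp motif therefore form one equivalence class, with one deterministic
#' representative. The representative is chosen on the G-richer strand (the
#' strand running 5'->3' toward the chromosome terminus in a telomere), taking
#' the lexicographically greatest rotation; this reproduces the conventional
#' spellings TTGGG and TTAGG. When both strands have equal G content the
#' greatest rotation over all 2k spellings is used.
#'
#' @param motif a single DNA string, 2-25 bp, characters in A/C/G/T, primitive.
#' @return an object of class \code{MotifClass}: list with elements
#'   \code{representative}, \code{k}, and \code{members} (all 2k spellings).
#' @export
#' @examples
#' canonical_class("CCCAA")$representative  # "TTGGG"
#' canonical_class("CCTAA")$representative  # "TTAGG"
canonical_class <- function(motif) {
  if (length(motif) != 1L || is.na(motif)) stop("motif must be a single string")
  motif <- toupper(motif)
  k <- nchar(motif)
  if (k < 2L || k > 25L)
    stop(errorCondition(sprintf("motif length %d outside the 2-25 bp range", k),
                        class = c("telomotif_bad_motif", "error", "condition")))
  if (grepl("[^ACGT]", motif))
    stop(errorCondition(sprintf("motif '%s' contains characters outside A/C/G/T", motif),
                        class = c("telomotif_bad_motif", "error", "condition")))
  if (!is_primitive(motif))
    stop(errorCondition(sprintf("motif '%s' is a power of a shorter motif", motif),
                        class = c("telomotif_nonprimitive", "error", "condition")))
  fwd <- rotations(motif)
  rev <- rotations(rc_string(motif))
  g_fwd <- sum(strsplit(motif, "")[[1]] == "G")
  g_rev <- sum(strsplit(rc_string(motif), "")[[1]] == "G")
  if (g_fwd > g_rev) {
    pool <- fwd
  } else if (g_rev > g_fwd) {
    pool <- rev
  } else {
    pool <- c(fwd, rev)
  }
  structure(
    list(representative = max(pool), k = k, members = unique(c(fwd, rev))),
    class = "MotifClass"
  )
}

#' @export
print.MotifClass <- function(x, ...) {
  cat(sprintf("MotifClass (%s)n  [k = %d, %d spellings]\n",
              x$representative, x$k, length(x$members)))
  invisible(x)
}

#' Do two motifs belong to the same rotation/reverse-complement class?
#' @param a,b DNA motif strings.
#' @return logical.
#' @export
same_motif_class <- function(a, b) {
  canonical_class(a)$representative == canonical_class(b)$representative
}

# Spellings of `motif` up to rotation only (same strand).
is_rotation_of <- function(a, b) {
  nchar(a) == nchar(b) && a %in% rotations(b)
}
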