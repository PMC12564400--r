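# Junction search templates for the telomere-targeting non-LTR
# retrotransposon families TRAS and SART, as used for screening canonical
# (TTAGG)n telomeres. TRAS inserts with its poly(A) tail against the
# C-rich strand, SART against the G-rich strand; the diagnostic strings are
# the junctions between a 10-base homopolymer tract and two telomeric
# repeat units. Note the second TRAS string carries 9 T's, not the 10
# implied by exact reverse complementarity; it is kept byte-for-byte.
TRAS_LITERAL <- c("AAAAAAAAAACCTAACCTAA", "TTAGGTTAGGTTTTTTTTT")
SART_LITERAL <- c("CCTAACCTAACCTTTTTTTTTT", "AAAAAAAAAAGGTTAGGTTAGG")

#' Build SART/TRAS junction search templates
#'
#' Two modes. \code{"literal"} returns the four published query strings for
#' the canonical (TTAGG)n motif byte-for-byte, including the asymmetric 9-T
#' homopolymer in the second TRAS string. \code{"motif_adjusted"} applies the
#' systematic construction to any telomeric motif class m (G-rich
#' representative): TRAS queries are polyA(10) + rc(m)^2 and m^2 + polyT(10);
#' SART queries are rc(m)^2 + polyT(10) and polyA(10) + m^2. Within each
#' family the two adjusted queries are exact reverse complements, so forward-
#' strand search covers both orientations.
#'
#' @param motif_class a \code{MotifClass} (see \code{\link{canonical_class}})
#'   or a motif string.
#' @param mode "motif_adjusted" (default) or "literal".
#' @return data.frame with columns \code{family}, \code{query},
#'   \code{provenance}.
#' @export
#' @examples
#' build_templates("TTGGG")$query[1]  # "AAAAAAAAAACCCAACCCAA"
build_templates <- function(motif_class,
                            mode = c("motif_adjusted", "literal")) {
  mode <- match.arg(mode)
  if (is.character(motif_class)) motif_class <- canonical_class(motif_class)
  m <- motif_class$representative
  if (mode == "literal") {
    if (m != "TTAGG")
      stop(errorCondition(
        sprintf("literal templates exist only for the canonical (TTAGG)n class, not (%s)n; use mode = 'motif_adjusted'", m),
        class = c("telomotif_no_literal_template", "error", "condition")))
    return(data.frame(
      family = c("TRAS", "TRAS", "SART", "SART"),
      query = c(TRAS_LITERAL, SART_LITERAL),
      provenance = "literal", stringsAsFactors = FALSE))
  }
  polyA <- strrep("A", 10L)
  polyT <- strrep("T", 10L)
  m2 <- strrep(m, 2L)
  rcm2 <- strrep(rc_string(m), 2L)
  data.frame(
    family = c("TRAS", "TRAS", "SART", "SART"),
    query = c(paste0(polyA, rcm2), paste0(m2, polyT),
              paste0(rcm2, polyT), paste0(polyA, m2)),
    provenance = "motif_adjusted", stringsAsFactors = FALSE)
}

#' Exact-match search of junction templates in an assembly
#'
#' Finds every exact occurrence of every query on the forward strand (the
#' template pairs already cover both orientations). No mismatches are
#' tolerated.
#'
#' @param assembly named \code{DNAStringSet}, or a single DNA string.
#' @param templates data.frame from \code{\link{build_templates}}.
#' @return data.frame with one row per hit: \code{pm_id}, \code{position}
#'   (1-based match start), \code{family}, \code{query}, \code{provenance}.
#' @export
search_exact <- function(assembly, templates) {
  if (is.character(assembly))
    assembly <- Biostrings::DNAStringSet(stats::setNames(assembly,
      if (is.null(names(assembly))) paste0("seq", seq_along(assembly))
      else names(assembly)))
  out <- data.frame(pm_id = character(), position = numeric(),
                    family = character(), query = character(),
                    provenance = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(templates))) {
    q <- templates$query[i]
    if (any(nchar(q) <= Biostrings::width(assembly))) {
      hits <- Biostrings::vmatchPattern(q, assembly)
      for (j in seq_along(hits)) {
        st <- IRanges::start(hits[[j]])
        if (length(st) == 0L) next
        out <- rbind(out, data.frame(
          pm_id = names(assembly)[j], position = as.numeric(st),
          family = templates$family[i], query = q,
          provenance = templates$provenance[i], stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(out$pm_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a retrotransposon hit table
#' @param hits data.frame from \code{\link{search_exact}}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_retro_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
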