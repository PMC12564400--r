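#' Run the full telomere screen on an assembly file
#'
#' End-to-end pipeline: read the assembly, extract terminal windows, detect
#' terminal tandem arrays, evaluate every motif class against the five
#' telomere criteria, search for SART/TRAS junction templates (adjusted to
#' the nominated motif when one exists, otherwise the canonical class), and
#' write the reports.
#'
#' @param input path to an assembly FASTA (plain or gzip).
#' @param out_dir report directory, created if missing; NULL to skip writing.
#' @param params \code{\link{scan_params}}.
#' @param retro_mode "motif_adjusted" (default) or "literal" (only valid when
#'   the motif searched is the canonical (TTAGG)n class).
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the \code{TelomereScreen}, the
#'   \code{retro_hits} data.frame and the report \code{paths} (or NULL).
#' @export
run_scan <- function(input, out_dir = NULL, params = scan_params(),
                     retro_mode = c("motif_adjusted", "literal"),
                     quiet = FALSE) {
  retro_mode <- match.arg(retro_mode)
  say <- function(...) if (!quiet) message(sprintf(...))
  say("[read_assembly] %s", input)
  assembly <- read_assembly(input)
  say("[read_assembly] %d pseudomolecule(s), %s bp total",
      length(assembly),
      format(sum(as.numeric(Biostrings::width(assembly))), big.mark = ","))
  say("[screen_assembly] window %d bp, k %d-%d, purity >= %.2f, >= %d copies",
      params$window_size, params$k_min, params$k_max, params$min_purity,
      params$min_copies)
  screen <- screen_assembly(assembly, params)
  say("[screen_assembly] %d terminal array(s), %d motif class(es)",
      nrow(screen$arrays), length(screen$verdicts))
  if (screen$nomination$negative) {
    say("[criteria] negative verdict: no class met all five criteria")
  } else {
    say("[criteria] nominated telomeric motif: (%s)n",
        screen$nomination$nominated)
  }
  retro_class <- screen$nomination$nominated %||% "TTAGG"
  templates <- build_templates(retro_class, mode = retro_mode)
  hits <- search_exact(assembly, templates)
  say("[retro_search] %d template(s) for (%s)n: %d hit(s)",
      nrow(templates), retro_class, nrow(hits))
  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_reports(screen$arrays, screen, screen$pm_lengths, out_dir)
    paths <- c(paths, retro = write_retro_hits(
      hits, file.path(out_dir, "retro_hits.tsv")))
    say("[write_reports] %s", out_dir)
  }
  invisible(list(screen = screen, retro_hits = hits, paths = paths))
}

#' Generate a synthetic assembly to disk
#'
#' Convenience wrapper around \code{\link{generate_assembly}} and
#' \code{\link{write_synthetic}}: writes the FASTA, the truth tables and the
#' spec actually used (seed included) for provenance.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param out_dir output directory.
#' @param quiet suppress messages.
#' @return invisibly, named vector of written paths.
#' @export
run_generate <- function(spec, out_dir, quiet = FALSE) {
  gen <- generate_assembly(spec)
  paths <- write_synthetic(gen, spec, out_dir)
  if (!quiet)
    message(sprintf("[generate] %d chromosome(s), %d planted array(s), %d insertion(s) -> %s",
                    length(gen$assembly), nrow(gen$truth),
                    nrow(gen$insertions), out_dir))
  invisible(paths)
}
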