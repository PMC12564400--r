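#!/usr/bin/env Rscript

# SART/TRAS retrotransposon junction search. Junction templates join a
# 10-base homopolymer tract to two telomeric repeat units; the literal
# template set is the published one for (TTAGG)n, and the motif-adjusted
# construction generalizes it to any motif class (here (TTGGG)n). Searches
# are exact, forward strand only -- each template pair covers both
# orientations. A positive-control assembly carries two planted junctions.

suppressPackageStartupMessages(library(telomotif))

dir.create("results/retro", showWarnings = FALSE, recursive = TRUE)

show_templates <- function(tm, label) {
  message(label, ":")
  for (i in seq_len(nrow(tm)))
    message(sprintf("  %-4s %s", tm$family[i], tm$query[i]))
  tm
}
tm_ttagg <- show_templates(build_templates("TTAGG", mode = "literal"),
                           "literal (TTAGG)n templates")
tm_ttggg <- show_templates(build_templates("TTGGG"),
                           "motif-adjusted (TTGGG)n templates")

search_one <- function(name, templates) {
  fa <- file.path("results/synthetic", name, "assembly.fa")
  if (!file.exists(fa))
    stop("missing ", fa, " -- run analysis/01_generate_assemblies.R first")
  hits <- search_exact(read_assembly(fa), templates)
  write_retro_hits(hits, file.path("results/retro",
                                   paste0(name, "_hits.tsv")))
  message(sprintf("%s: %d junction hit(s)", name, nrow(hits)))
  hits
}

search_one("flava_like", tm_ttggg)
search_one("capitata_like", rbind(tm_ttagg,
                                  build_templates("TTAGG")))

# positive control: junctions planted into background away from the telomere
gen <- generate_assembly(synthetic_spec(777, list(
  list(length = 1e5, three_prime = planted_array("TTAGG", 1500),
       retro_insertions = list(list(family = "TRAS", position = 25000),
                               list(family = "SART", position = 60000))))))
hits <- search_exact(gen$assembly, build_templates("TTAGG"))
write_retro_hits(hits, "results/retro/positive_control_hits.tsv")
message(sprintf("positive control: %d/%d planted junctions recovered",
                nrow(merge(gen$insertions, hits,
                           by = c("pm_id", "position"))),
                nrow(gen$insertions)))
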