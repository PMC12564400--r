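#!/usr/bin/env Rscript

# Build the three synthetic study assemblies used throughout the analysis:
#   flava_like    - seven ~1 Mb chromosomes, seven (TTGGG)n terminal arrays
#                   with the span pattern reported for N. flava (8005, 4018,
#                   4545, 3300, 228, 7554 and 1225 bp; two chromosomes with
#                   arrays at both ends, two with none)
#   capitata_like - eight chromosomes, four (TTAGG)n arrays (2378, 2488,
#                   2316, 3808 bp), three at 3' ends and one at a 5' end
#   control_like  - six chromosomes with no planted arrays, mimicking
#                   assemblies in which no motif satisfies the criteria
# Each directory gets the FASTA, the planted ground truth and the spec used.

suppressPackageStartupMessages(library(telomotif))

seed <- 101L
out_root <- "results/synthetic"

specs <- list(
  flava_like = flava_like_spec(seed, chrom_length = 1e6),
  capitata_like = capitata_like_spec(seed + 1L, chrom_length = 1e6),
  control_like = negative_spec(seed + 2L, n_chromosomes = 6,
                               chrom_length = 5e5)
)

for (name in names(specs)) {
  paths <- run_generate(specs[[name]], file.path(out_root, name))
  truth <- utils::read.table(paths[["truth"]], header = TRUE, sep = "\t")
  message(sprintf("%s: %d planted array(s)", name, nrow(truth)))
}
message("synthetic assemblies written under ", out_root)
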