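#' Specification of a planted telomeric array
#'
#' @param motif telomeric motif, given as its G-rich spelling (e.g. "TTGGG");
#'   the generator lays it down forward at 3' ends and as its reverse
#'   complement at 5' ends, the orientation real telomeres show.
#' @param array_length total array span in bp.
#' @param degradation_max maximum substitution probability, reached at the
#'   array's inner edge. Substitution probability ramps linearly from 0 at
#'   the terminus to \code{degradation_max} inward, emulating the increase of
#'   nucleotide variation away from chromosome termini (default 0.05).
#' @param offset bp between the terminus and the array's outer edge
#'   (default 0).
#' @return list of class \code{PlantedArray}.
#' @export
planted_array <- function(motif, array_length, degradation_max = 0.05,
                          offset = 0L) {
  stopifnot(array_length >= nchar(motif), degradation_max >= 0,
            degradation_max < 0.5, offset >= 0)
  cl <- canonical_class(motif)  # validates the motif
  structure(list(motif = toupper(motif), motif_class = cl$representative,
                 array_length = as.integer(array_length),
                 degradation_max = degradation_max,
                 offset = as.integer(offset)),
            class = "PlantedArray")
}

#' Specification of a synthetic assembly
#'
#' @param seed integer seed; identical seeds give byte-identical assemblies.
#' @param chromosomes list of chromosome specs, each a list with fields
#'   \code{length} (bp), optional \code{five_prime} / \code{three_prime}
#'   (\code{\link{planted_array}}), optional \code{retro_insertions} (list of
#'   \code{list(family = "TRAS"|"SART", position = bp)}), optional \code{id}.
#' @param background_gc GC fraction of the i.i.d. background (default 0.35,
#'   typical of insect genomes).
#' @return list of class \code{SyntheticSpec}.
#' @export
synthetic_spec <- function(seed, chromosomes, background_gc = 0.35) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            background_gc > 0, background_gc < 1, length(chromosomes) >= 1L)
  for (i in seq_along(chromosomes)) {
    ch <- chromosomes[[i]]
    stopifnot(!is.null(ch$length), ch$length >= 1)
    if (is.null(ch$id)) chromosomes[[i]]$id <- sprintf("synth_chr%02d", i)
    for (side in c("five_prime", "three_prime")) {
      pa <- ch[[side]]
      if (is.null(pa)) next
      if (!inherits(pa, "PlantedArray"))
        stop("five_prime/three_prime must be planted_array() objects")
      if (pa$array_length + pa$offset > ch$length / 2)
        stop(errorCondition(
          sprintf("chromosome %d: planted array (%d bp + offset %d) exceeds half the chromosome length %d",
                  i, pa$array_length, pa$offset, as.integer(ch$length)),
          class = c("telomotif_infeasible_spec", "error", "condition")))
    }
  }
  structure(list(seed = as.integer(seed), chromosomes = chromosomes,
                 background_gc = background_gc),
            class = "SyntheticSpec")
}

# Tile a motif to exactly `len` bases (partial copy at the end allowed).
tile_motif <- function(motif, len) {
  substr(strrep(motif, ceiling(len / nchar(motif))), 1L, len)
}

#' Generate a synthetic assembly with planted telomeric architecture
#'
#' The background is i.i.d. with the spec's GC content. Each planted array is
#' its motif tiled to \code{array_length}, laid down forward at 3' ends and
#' reverse-complemented at 5' ends, placed \code{offset} bp from the
#' terminus. Array base number d (counting from the outer edge, 1-based) is
#' substituted with probability \code{degradation_max * (d - 1) /
#' array_length} -- a linear ramp increasing inward; substitutions draw
#' uniformly from the three alternative bases. The two background bases
#' immediately inward of each array are drawn to differ from the motif
#' continuation, modelling the telomere-subtelomere transition (real
#' subtelomeric sequence is not a chance extension of the repeat), so the
#' planted boundary is well defined. Retro insertions overwrite the
#' background in place with the family's motif-adjusted junction string
#' (first query of the family), so all truth coordinates stay valid;
#' insertions overlapping a planted array are rejected.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{assembly} (named \code{DNAStringSet}),
#'   \code{truth} (data.frame: \code{pm_id}, \code{side}, \code{start},
#'   \code{end}, \code{motif} (class representative), \code{oriented_motif},
#'   \code{realized_purity}, \code{n_substitutions}) and \code{insertions}
#'   (data.frame: \code{pm_id}, \code{position}, \code{family},
#'   \code{query}).
#' @export
generate_assembly <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  gc <- spec$background_gc
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  truth <- data.frame(pm_id = character(), side = character(),
                      start = numeric(), end = numeric(), motif = character(),
                      oriented_motif = character(),
                      realized_purity = numeric(),
                      n_substitutions = integer(), stringsAsFactors = FALSE)
  ins_tab <- data.frame(pm_id = character(), position = numeric(),
                        family = character(), query = character(),
                        stringsAsFactors = FALSE)
  seqs <- character(length(spec$chromosomes))
  ids <- character(length(spec$chromosomes))
  for (i in seq_along(spec$chromosomes)) {
    ch <- spec$chromosomes[[i]]
    len <- as.integer(ch$length)
    chars <- sample(names(base_prob), len, replace = TRUE, prob = base_prob)
    occupied <- matrix(numeric(0), ncol = 2)
    for (side in c("five_prime", "three_prime")) {
      pa <- ch[[side]]
      if (is.null(pa)) next
      alen <- pa$array_length
      oriented <- if (side == "five_prime") rc_string(pa$motif) else pa$motif
      if (side == "five_prime") {
        start <- 1L + pa$offset
        end <- start + alen - 1L
        # tile so the motif phase is anchored at the outer (left) edge
        arr <- strsplit(tile_motif(oriented, alen), "", fixed = TRUE)[[1]]
        d <- seq_len(alen)               # distance from outer edge
      } else {
        end <- len - pa$offset
        start <- end - alen + 1L
        # anchor the phase at the outer (right) edge: tile the reverse
        # complement left-anchored, then flip back
        arr <- strsplit(rc_string(tile_motif(rc_string(oriented), alen)),
                        "", fixed = TRUE)[[1]]
        d <- rev(seq_len(alen))
      }
      p_sub <- pa$degradation_max * (d - 1) / alen
      hit <- stats::runif(alen) < p_sub
      if (any(hit)) {
        arr[hit] <- vapply(arr[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      }
      chars[start:end] <- arr
      # sharp inner edge: the two bases inward of the array are drawn to
      # differ from the motif continuation, as a subtelomeric transition
      # rather than a chance extension of the repeat
      m_chars <- strsplit(oriented, "", fixed = TRUE)[[1]]
      inner <- if (side == "five_prime") {
        p <- intersect((end + 1L):(end + 2L), seq_len(len))
        stats::setNames(p, m_chars[((p - start) %% nchar(pa$motif)) + 1L])
      } else {
        p <- intersect((start - 2L):(start - 1L), seq_len(len))
        stats::setNames(p, m_chars[((p - end - 1L) %% nchar(pa$motif)) + 1L])
      }
      for (ii in seq_along(inner)) {
        chars[inner[ii]] <- sample(setdiff(c("A", "C", "G", "T"),
                                           names(inner)[ii]), 1L)
      }
      occupied <- rbind(occupied, c(max(1L, start - 2L), min(len, end + 2L)))
      truth <- rbind(truth, data.frame(
        pm_id = ch$id, side = side, start = start, end = end,
        motif = canonical_class(pa$motif)$representative,
        oriented_motif = oriented,
        realized_purity = 1 - sum(hit) / alen,
        n_substitutions = sum(hit), stringsAsFactors = FALSE))
    }
    for (ins in ch$retro_insertions) {
      tmpl <- build_templates(ch[["three_prime"]]$motif %||%
                                ch[["five_prime"]]$motif %||% "TTAGG")
      q <- tmpl$query[tmpl$family == ins$family][1L]
      if (is.na(q)) stop(sprintf("unknown retro family '%s'", ins$family))
      a <- as.integer(ins$position)
      b <- a + nchar(q) - 1L
      if (a < 1L || b > len)
        stop(errorCondition("retro insertion outside chromosome",
                            class = c("telomotif_infeasible_spec", "error",
                                      "condition")))
      if (nrow(occupied) > 0L &&
          any(a <= occupied[, 2L] & b >= occupied[, 1L]))
        stop(errorCondition("retro insertion overlaps a planted array",
                            class = c("telomotif_infeasible_spec", "error",
                                      "condition")))
      chars[a:b] <- strsplit(q, "", fixed = TRUE)[[1]]
      ins_tab <- rbind(ins_tab, data.frame(
        pm_id = ch$id, position = a, family = ins$family, query = q,
        stringsAsFactors = FALSE))
    }
    seqs[i] <- paste(chars, collapse = "")
    ids[i] <- ch$id
  }
  assembly <- Biostrings::DNAStringSet(seqs)
  names(assembly) <- ids
  list(assembly = assembly, truth = truth, insertions = ins_tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic assembly, its truth table and its spec to disk
#'
#' @param gen result of \code{\link{generate_assembly}}.
#' @param spec the \code{\link{synthetic_spec}} used (recorded for
#'   provenance, seed included).
#' @param out_dir output directory.
#' @return invisibly, named vector of written paths (\code{fasta},
#'   \code{truth}, \code{insertions}, \code{spec}).
#' @export
write_synthetic <- function(gen, spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(out_dir, "assembly.fa")
  Biostrings::writeXStringSet(gen$assembly, fasta)
  truth <- file.path(out_dir, "truth.tsv")
  utils::write.table(gen$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ins <- file.path(out_dir, "insertions.tsv")
  utils::write.table(gen$insertions, ins, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spec_path <- file.path(out_dir, "spec.json")
  jsonlite::write_json(spec_to_list(spec), spec_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(fasta = fasta, truth = truth, insertions = ins,
              spec = spec_path))
}

spec_to_list <- function(spec) {
  list(seed = spec$seed, background_gc = spec$background_gc,
       chromosomes = lapply(spec$chromosomes, function(ch) {
         out <- list(id = ch$id, length = ch$length)
         for (side in c("five_prime", "three_prime"))
           if (!is.null(ch[[side]])) out[[side]] <- unclass(ch[[side]])
         if (!is.null(ch$retro_insertions))
           out$retro_insertions <- ch$retro_insertions
         out
       }))
}

#' Synthetic assembly mimicking the published (TTGGG)n telomere geometry
#'
#' Seven chromosomes; five carry (TTGGG)n terminal arrays with the published
#' span pattern -- two chromosomes with arrays at both ends (8005/4018 bp and
#' 7554/1225 bp, the second 3' array ending 2 bp short of the terminus on one
#' chromosome), one 5'-only (3300 bp), two 3'-only (4545 and 228 bp), two
#' bare. Chromosome lengths are scaled to \code{chrom_length} so the fixture
#' stays small; lengths enter only through coordinates.
#'
#' @param seed integer seed.
#' @param chrom_length chromosome length in bp (default 1e6).
#' @param degradation_max inner-edge substitution ceiling (default 0.05).
#' @return a \code{\link{synthetic_spec}}.
#' @export
flava_like_spec <- function(seed, chrom_length = 1e6, degradation_max = 0.05) {
  pa <- function(len, off = 0L) planted_array("TTGGG", len,
                                              degradation_max, off)
  synthetic_spec(seed, list(
    list(length = chrom_length, five_prime = pa(8005),
         three_prime = pa(4018)),
    list(length = chrom_length, three_prime = pa(4545, off = 2L)),
    list(length = chrom_length, five_prime = pa(3300)),
    list(length = chrom_length, three_prime = pa(228)),
    list(length = chrom_length, five_prime = pa(7554),
         three_prime = pa(1225)),
    list(length = chrom_length),
    list(length = chrom_length)
  ))
}

#' Synthetic assembly mimicking the published (TTAGG)n telomere geometry
#'
#' Eight chromosomes, four with a single (TTAGG)n terminal array (2378, 2488
#' and 3808 bp at 3' ends; 2316 bp at a 5' end), four bare.
#'
#' @inheritParams flava_like_spec
#' @return a \code{\link{synthetic_spec}}.
#' @export
capitata_like_spec <- function(seed, chrom_length = 1e6,
                               degradation_max = 0.05) {
  pa <- function(len) planted_array("TTAGG", len, degradation_max)
  synthetic_spec(seed, list(
    list(length = chrom_length, three_prime = pa(2378)),
    list(length = chrom_length, three_prime = pa(2488)),
    list(length = chrom_length, five_prime = pa(2316)),
    list(length = chrom_length),
    list(length = chrom_length, three_prime = pa(3808)),
    list(length = chrom_length),
    list(length = chrom_length),
    list(length = chrom_length)
  ))
}

#' Negative-control synthetic assembly (no planted arrays)
#'
#' Mimics assemblies in which no motif meets the telomere criteria: pure
#' i.i.d. background on every chromosome.
#'
#' @param seed integer seed.
#' @param n_chromosomes number of chromosomes (default 6).
#' @param chrom_length chromosome length in bp (default 1e5).
#' @return a \code{\link{synthetic_spec}}.
#' @export
negative_spec <- function(seed, n_chromosomes = 6L, chrom_length = 1e5) {
  synthetic_spec(seed, lapply(seq_len(n_chromosomes), function(i)
    list(length = chrom_length)))
}
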