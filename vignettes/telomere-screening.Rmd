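---
title: "Screening assembly termini for telomeric motifs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening assembly termini for telomeric motifs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomotif)
```

## The screening model

In species with telomerase-maintained telomeres, chromosome ends carry
tandem arrays of a short motif (2–25 bp in insects), G-rich strand running
5′→3′ toward the terminus. In a chromosome-level assembly this architecture
is directly observable: a pseudomolecule that captures the telomere ends in
such an array, spelled as the G-rich motif at the 3′ end and as its reverse
complement at the 5′ end. `telomotif` formalizes the visual inspection of
assembly termini as: terminal-window extraction, tandem-array detection,
motif canonicalization, and a five-criteria qualification step that separates
genuine telomeric repeats from incidental terminal repeats.

The package treats coordinates as 1-based inclusive throughout — the
convention of published end-coordinate tables, where an array "1–8005" has
length 8005 — and converts to 0-based half-open only at the BED boundary.

### Motif equivalence classes

A repeat read off an assembly has an arbitrary phase and strand: CCCAA,
CCAAC and TTGGG all describe one telomere. All 2k spellings (k rotations ×
2 strands) form one class with a deterministic canonical representative:
among the rotations of the G-richer strand (of both strands when G content
ties), the lexicographically greatest. This choice reproduces the
conventional spellings — the TTGGG/CCCAA class canonicalizes to TTGGG, the
TTAGG/CCTAA class to TTAGG — where the lexicographically *smallest* rotation
would give GGGTT and AGGTT. Only primitive motifs (not powers of a shorter
string) define classes; ATAT is a phase of (AT)n, not a 4-mer repeat.

### Array detection

Each pseudomolecule end contributes a terminal window (default
`window_size = 50000` bp — the unexamined quantity in end-table studies; a
50 kb window holds the longest arrays such tables report, ~8 kb, with an
order-of-magnitude margin). Detection proceeds per window:

1. **Seeding.** Candidate motifs are the primitive k-mers (k = 2–25, the
   range short-read telomere profilers use) that occur as an exact
   head-to-tail duplication within the outermost 200 bp
   (`seed_region`) — a telomeric array must reach the terminus, so its motif
   must appear terminally. Each seed also pins down the tiling it belongs to
   (strand and phase of the ideal repeat), so only observed tilings are
   scanned rather than all 2k.
2. **Extension.** For each tiling, the window is compared position-by-
   position against the phase-aligned infinite repeat (`N` never matches).
   Candidate segments are delimited by mismatch runs longer than
   `max_interruption_factor × k` (default 2k bases, the interruption
   tolerance) and must reach `min_copies = 10` copies at overall purity
   `min_purity = 0.90`.
3. **Boundary refinement.** Within a segment, each boundary is placed by a
   scoring walk (match +1, mismatch −2 — the rounded log-likelihood ratio
   between array-like positions, ~95% match under mild degradation, and
   background positions, ~25% match), taken at its furthest maximum among
   positions terminating two consecutive matches, then extended across
   *isolated* mismatches (a single mismatch followed by two matches, up to
   2k bases). Two consecutive mismatches never extend a boundary on their
   own; interruptions up to 2k bases are crossed only when the score
   recovers. Finally the end is pulled back, if needed, to keep overall
   purity ≥ `min_purity`.
4. **Tie-breaks.** Overlapping detections of different motif length
   explaining the same span (> 50% mutual overlap) resolve to the smaller k
   (primitive parsimony), then higher purity, then longer span.

Three-prime windows are scanned on the reverse-complement strand, so both
ends are handled by one code path and strand symmetry holds by construction:
reverse-complementing a pseudomolecule swaps 5′/3′ arrays with coordinates
mapped by `pos → length − pos + 1` (a property the test suite checks
exactly).

The per-window scan is O(window × observed tilings) with vectorized
comparisons; a rolling-sum pre-screen discards tilings that cannot contain a
qualifying run before any segment analysis.

### The five criteria

Per motif class, across the assembly:

1. **Strictly terminal** — every array's outer edge within
   `max_offset = 100` bp of its terminus. The studies this models say
   "strictly terminal" without a number; their own arrays end 0–2 bp from
   the terminus, so 100 bp is generous but still excludes anything
   subtelomeric.
2. **Minimum span** — at least one array ≥ `min_span = 300` bp (the lower
   bound of the 300–400 bp convention for candidate telomeric repeats).
   Interpreted at *motif* level, not per array: end tables that report a
   motif keep its shorter arrays (e.g. a 228 bp array alongside 3–8 kb
   ones), which is only coherent if the threshold qualifies the motif and
   short arrays then remain reportable.
3. **Identity across chromosomes** — one class and mutually consistent
   oriented spellings (equal up to rotation and strand) wherever detected.
4. **No alternatives** — at each end carrying a candidate array, arrays of
   *other* classes (detected without the terminal anchor) may cover at most
   `max_alt_fraction = 5%` of the window; "extremely uncommon" made
   quantitative.
5. **Opposite-end orientation** — where the class occupies both ends of a
   pseudomolecule, the 5′ spelling must be the reverse complement (up to
   rotation) of the 3′ spelling; vacuously true otherwise.

Qualified classes are ranked by array count, then total array length; with
none, the verdict is negative and names the nearest-miss class with its
failed criteria. The negative path is a first-class outcome: two of the four
assemblies this design models produced exactly that.

### Junction templates

Telomere-targeting non-LTR retrotransposons of the TRAS and SART families
leave diagnostic junctions between a poly(A)/poly(T) tract and the telomeric
repeat. The literal template set for (TTAGG)n is reproduced byte-for-byte,
including its 9-T second TRAS string, which is *not* the exact reverse
complement of the 20-base first string — whether that is a typo in the
source or the genuine query is unknowable, so the literal mode preserves it
and the motif-adjusted mode builds the self-consistent generalization
(TRAS: polyA(10)+rc(m)², m²+polyT(10); SART: rc(m)²+polyT(10), polyA(10)+m²,
with m the G-rich representative doubled), whose within-family pairs are
exact reverse complements. Searches are exact and forward-strand only — each
pair already covers both orientations.

### Statistics

Array length is `end − start + 1`; dispersion is the sample (n−1) standard
deviation — the convention is forced, since only n−1 reproduces both
published values (2923 and 710.6 bp) from the corresponding tables, while
the population form gives ~2706 and ~615. Printed precision follows the
mean: integer statistics when the mean is integral, one decimal otherwise.

## The synthetic generator

`generate_assembly()` emulates what the screen consumes: i.i.d. background
at `background_gc = 0.35` (typical insect genome-wide GC), planted arrays
tiled to the requested span — reverse complement at 5′ ends, forward at 3′
ends, phase anchored at the outer edge — and substitution probability
ramping linearly from 0 at the terminus to `degradation_max` (default 0.05)
at the array's inner edge, the simplest model of nucleotide variation
increasing away from termini. Substitutions draw uniformly from the three
alternative bases; there are no indels in this version (the scanner's
interruption tolerance is exercised with explicit spacer constructions in
the tests instead). The two background bases immediately inward of each
array are drawn to differ from the motif continuation: real subtelomeric
sequence is not a chance extension of the telomeric repeat, and this makes
the planted boundary well defined. Junction insertions overwrite background
in place (coordinates elsewhere stay valid); overlaps with planted arrays
are rejected. Identical seeds give byte-identical assemblies.

Fixture builders mirror the study geometries: `flava_like_spec()` plants the
seven reported (TTGGG)n spans (8005, 4018, 4545, 3300, 228, 7554, 1225 bp,
including one array ending 2 bp short of its terminus) on five of seven
chromosomes; `capitata_like_spec()` plants four (TTAGG)n arrays (2378, 2488,
2316, 3808 bp), three at 3′ ends and one at a 5′ end; `negative_spec()`
plants nothing. Chromosomes are ~1 Mb in the analysis scripts and ~0.1 Mb in
the test suite (with 15–25 kb windows): length enters only through
coordinates, so fixtures are scaled for speed without changing behaviour.

What passing on synthetics does *not* show: real subtelomeres are
structured (satellite blocks, rDNA, transposons), assemblies contain gaps
and scaffolding artifacts at termini, and telomere-adjacent variation is not
an i.i.d. substitution ramp. Recovery on these fixtures validates the
machinery — coordinates, orientation handling, criteria logic, statistics —
not performance on any real genome.

## Numerical choices and edge cases

- **Boundary ambiguity.** With i.i.d. background, roughly one inner
  boundary in a few hundred is genuinely ambiguous: the background continues
  the motif past the planted edge by chance, or a double substitution
  adjacent to the edge is indistinguishable from a repeat interruption, and
  no estimator can place the planted coordinate there. The recovery tests
  therefore assert boundaries within ±k bp *or* a deviation of at most 3k
  whose own sequence matches the motif at above 60% purity (the realized
  array genuinely extends); deviations into non-repeat background still
  fail. The acceptance script reports the within-±k fraction as a rate
  rather than asserting perfection.
- **Degenerate inputs.** Records shorter than the window yield two
  whole-record windows; a query longer than its subject yields no hits;
  single-length summaries report an absent SD; empty scan results are valid
  (and produce all-"no short repeat array" reports).
- **N handling.** N is tolerated in input and never matches any motif
  position — it can sit inside an interruption but cannot extend an array.
- **Soft-masking** is ignored (input upper-cased): telomeric repeats are
  routinely soft-masked by assembly pipelines, and masking them out would
  hide exactly the signal sought.
- **Determinism.** The screen contains no randomness; the generator's only
  randomness is its seed.

## Limitations

- Motif length is capped at 25 bp; the long (up to ~381 bp) repeats of some
  dipteran telomeres are out of scope by design.
- The mismatch model is substitution-only with bounded interruptions;
  indel-rich arrays would shift phase and be truncated at the first long
  interruption rather than re-phased.
- Junction search is exact; diverged retrotransposon copies require
  profile-based methods outside this package's scope.
- The criteria thresholds (100 bp offset, 300 bp span, 5% alternatives) are
  parameterized judgment calls where the source conventions give no number;
  all are configurable in `scan_params()`.
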