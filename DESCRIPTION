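Package: telomotif
Title: Telomeric Motif Discovery at the Termini of Chromosome-Level Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects candidate telomeric repeat motifs at the ends of
    chromosome pseudomolecules in chromosome-level genome assemblies.
    Scans terminal windows for short (2-25 bp) tandem-repeat arrays,
    normalizes motifs into rotation/reverse-complement equivalence
    classes, evaluates every motif class against five telomere
    qualification criteria (strictly terminal placement, minimum span,
    cross-chromosome identity, absence of alternative motifs, and
    reverse-complementary organization at opposite ends), searches for
    SART/TRAS retrotransposon junction templates, and reports
    array-length statistics. Includes a seeded synthetic-assembly
    generator with planted telomeric architecture and ground truth so
    the whole pipeline is testable without downloading assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
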