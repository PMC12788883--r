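Package: adatseq
Title: Quantifying ADAT-Dependent tRNA Wobble Editing and Codon-Biased
    Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the consequences of ADAT2/3-mediated
    adenosine-to-inosine (A-to-I) editing at the tRNA wobble position
    (position 34) on mRNA translation. The package builds an
    anticodon-to-codon wobble-decoding table and classifies every sense
    codon by its dependence on inosine-34 tRNAs, quantifies wobble-position
    editing rates and steady-state tRNA abundance from small-RNA-seq
    alignments, computes translation efficiency from ribosome-profiling and
    input RNA count tables with differential-translation calls, aggregates
    SILAC peptide ratios into differential protein calls, and tests gene
    sets for enrichment of ADAT-sensitive codons. A seeded synthetic-data
    generator emulates the full study design (tRNA reads with planted
    editing rates, ORFs with controlled strict-codon content, negative
    binomial RPF/RNA counts with a codon-composition-dependent knockdown
    effect, and SILAC peptide tables) so every stage and the end-to-end
    pipeline are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
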