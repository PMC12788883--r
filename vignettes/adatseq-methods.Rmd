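---
title: "Methods: quantifying ADAT-dependent wobble editing and codon-biased translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ADAT-dependent wobble editing and codon-biased translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adatseq)
```

## The biological model

The ADAT2/3 deaminase converts adenosine to inosine at position 34 — the
wobble position — of eight eukaryotic tRNA isoacceptor families (Ala-AGC,
Arg-ACG, Ile-AAT, Leu-AAG, Pro-AGG, Ser-AGA, Thr-AGT, Val-AAC).  An
unedited A34 pairs only with U in the third codon position, while inosine
pairs with A, U and C.  Because the human genome carries essentially no
G34 tRNA genes for these boxes, their C-ending (NNC) codons have *no*
decoder without editing: they are **strictly** dependent on ADAT activity.
T-ending codons of the same boxes can be read both by the unedited A34
tRNA and by the edited one (**dual** dependence), and all remaining codons
are **independent**.  Partial loss of ADAT activity should therefore
depress the translation of mRNAs in proportion to their content of
strictly dependent codons — the central, testable prediction this package
operationalises.

`adatseq` covers four analysis stages plus a generator:

1. **decoding model** — enumerate anticodon→codon wobble pairings and
   classify the 61 sense codons (`build_decoding_table()`);
2. **tRNA editing** — filter small-RNA-seq alignments, pile up bases at
   the wobble position, and estimate per-family editing rates and
   steady-state abundance (`editing_rate()`, `trna_abundance()`);
3. **translatome** — translation efficiency (TE) from ribosome-profiling
   (RPF) and input RNA counts, differential TE, and a SILAC branch for
   protein-level calls (`differential_te()`, `differential_protein()`);
4. **codon usage** — per-ORF codon frequencies and rank tests for
   ADAT-sensitive codon enrichment in gene sets (`gene_set_report()`);
5. **synthetic data** — a seeded generator emulating all of the above
   (`sim_config()`, `simulate_study()`), and `run_pipeline()` to tie the
   stages together.

Throughout, sequences use the DNA alphabet (T for U), matching the
FASTA/SAM inputs the package reads; inosine is observed as G by reverse
transcription, which is what makes editing measurable in sequencing data.

## The decoding table

`build_decoding_table()` pairs anticodon positions 35/36 with codon
positions 2/1 by strict Watson–Crick complementarity and lets only
position 34 wobble, according to a pairing-rule table
(`default_pairing_rules()`): A34→{T}, I34→{A,T,C}, G34→{C,T}, C34→{G},
T34→{A,G}.  The rule table is data, not code, so superwobble variants
(e.g. a hypothetical I34:G pairing) can be explored without touching the
implementation.  Two further choices matter:

* A family is only credited with codons of its own amino acid.  This
  suppresses chemically conceivable but biologically silenced pairings —
  the classic case is the Ile-TAT tRNA, whose unmodified U34 would
  formally read the Met codon ATG; in vivo, position-34 modification
  restricts it to ATA.  The restriction does not change any dependency
  class of interest.
* Stop codons are excluded outright: they have no tRNA decoders.

Whether I34 can pair with G is genuinely unsettled; the default rules
forbid it, so NNG codons are never credited to edited tRNAs.  Users who
wish to relax this can add `"G"` to the `I` rule.

With the shipped family table (8 edited + 37 standard unedited human
isoacceptors), the strict set is exactly the 8 NNC codons of the edited
boxes (GCC, CGC, ATC, CTC, CCC, TCC, ACC, GTC) and the ADAT-sensitive set
(any codon with an I34 decoder) has 24 members.

## Editing quantification

Reads aligned to mature tRNA references are filtered as in standard
tRNA-seq practice: at most 2 mismatches, at most 50 reported mappings,
and no pre-tRNA evidence (5' leader, 3' trailer, or intronic sequence).
In SAM input, leader/trailer evidence is read off soft clips that abut
the reference ends, with the post-transcriptional CCA tail exempted (a
3' soft clip equal to a prefix of CCA is not genomic trailer sequence),
and a retained intron appears as an insertion.  Exclusion reasons are
tallied with fixed precedence (pre-tRNA > mismatches > multimapping) so
that retained + excluded always equals the input count — a conservation
property the tests assert.

The wobble position is taken from per-family `anticodon_start` metadata,
never from a hardcoded "34": variable-length D-loops shift the anticodon
within the mature sequence, and the synthetic references deliberately
vary the coordinate (33–35) to keep the code honest.

The editing rate is the G fraction at the wobble position.  By default
the denominator is total coverage (G/(A+C+G+T)), treating C/T calls as
sequencing error but keeping them in the denominator; `ag_only`
(G/(A+G)) is available because the definition is ambiguous in common
usage.  Multimapping reads contribute 1/n_mappings per mapping
(`fractional` weighting, the default) to avoid double counting.  A
Wilson score interval — closed-form, valid at the extreme rates (0, 1)
common at this position, and tolerant of fractional counts — accompanies
every estimate.  Families under 20× coverage (configurable) are flagged
rather than estimated.

## Translation efficiency and differential calls

TE is the CPM-scale ratio of RPF to input RNA signal with a pseudocount
of 0.5 applied at the ratio step only: CPM columns still sum to exactly
1e6, RNA-zero genes get a finite TE, and the log2 fold change is
invariant to library depth.  Differential TE uses a pooled-variance
Student's t on per-replicate log2 TE — transparent and defensible at
n = 2 per condition — with a label-permutation alternative; classes
require jointly `p < 0.05` and a 1.5-fold change (as |log2fc| ≥
log2 1.5).  Genes below 1 RNA CPM in either condition are excluded from
testing, because a ratio of near-zero quantities is noise.  With only
two replicates per group the t test has 2 degrees of freedom; it is
calibrated (the null false-positive rate is ~5%, asserted by test) but
deliberately conservative — a caveat to remember when comparing call
counts across datasets.

The SILAC branch averages peptide H/L ratios per protein and replicate
(the arithmetic mean of ratios, not the ratio of means), then tests the
mean log2 ratio against zero with limma's one-sample moderated t by
default — variance moderation is the standard remedy at n = 3 technical
replicates — and classifies with BH-adjusted p < 0.05 and |log2| ≥ 0.5.

## Codon-usage enrichment

Per-gene codon usage is the relative frequency of each of the 61 sense
codons over the ORF (terminal stop dropped; internal stops are an
error).  This is per-gene relative frequency, *not* relative synonymous
codon usage: the gene-set comparisons ask whether genes devote more of
their coding length to a codon, not how they choose among synonyms.
Group comparisons use a two-sided Mann–Whitney test per codon — exact
for groups of ≤ 20 genes without ties, otherwise the tie-corrected
normal approximation — with BH correction across the 61 codons; both raw
p and q are reported.  Usage changes are log2 ratios of group mean
frequencies, stabilised by a 1e-4 frequency pseudocount; the statistic
is antisymmetric under group exchange.  `gene_set_report()` runs the two
standard comparisons — down- vs up-regulated, and down vs "all other"
(everything except the down and up sets) — and summarises mean usage
change per dependency class.  The choice of log2-ratio-of-means as the
"usage change" axis is a package decision; a difference-of-means variant
would order codons nearly identically but lacks the scale-free reading.

## The synthetic-data generator

The generator exists so that every stage — and the pipeline end to end —
can be tested against planted truth without any external download.  Its
defaults define the emulated study conditions and were fixed once:

| parameter | default | what it emulates |
|---|---|---|
| editing rates | 0.85 (6 families), 0.40, 0.10 | heterogeneous control editing across isodecoder families |
| `kd_editing_factor` | 0.25 | partial knockdown retaining ~¼ of editing (a ~4-fold drop) |
| `seq_error` | 0.001 | Illumina-scale substitution error |
| `coverage` | 5 000 reads/family | deep small-RNA-seq |
| `n_genes` | 2 000 | a downscaled transcriptome |
| `strict_fraction_range` | 0.05–0.45 | per-gene strict-codon content; deliberately wider than the ~8–25% seen in real human ORFs so the cohort spans weak-to-strong ADAT dependence |
| `beta` | 2 | log2 TE decrement per unit strict-fraction × editing deficit |
| `sigma_log2te` | 0.25 | replicate-level TE measurement noise |
| `dispersion` | 0.01 | NB dispersion, i.e. a 10% biological CV — the canonical value for isogenic cell-line replicates |
| `n_reps` | 2 | the ribosome-profiling design |

Counts are negative binomial around lognormal expression levels; the
knockdown lowers a gene's TE by `beta × strict_fraction ×
(1 − kd_editing_factor)` log2 units, and the per-replicate noise term is
applied to each RPF library so that `beta = 0` is an *exact* null (no
gene has a true shift).  On dispersion: a value of 0.1 — a 32% CV,
typical of cross-subject human tissue — swamps a 2-replicate design with
count noise and makes differential calls essentially random; 0.01
matches the cell-line replicate setting the design emulates and leaves
the planted effect detectable but far from trivial (~30 down calls out
of 2 000 genes).  Both are one keystroke away in `sim_config()`.

tRNA reads are emitted directly as alignments (SAM with NM/NH tags)
rather than raw FASTQ, because alignment itself is upstream of this
package's scope.  Planted filter violations (pre-tRNA soft
clips/insertions, 3-mismatch reads, 51-mapping reads) exercise the
filters with exactly known counts.

What the generator does **not** model — and hence what green tests do
not certify about real data: positional sequencing-error profiles and
base-quality structure, tRNA modification-induced misincorporation at
positions other than 34 (the real motivation for AlkB treatment),
fragment-length and ligation biases, isodecoder heterogeneity within a
family, correlated codon usage (real genes' GC content couples codon
frequencies), and any transcriptional response to the knockdown.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulations use the generator at
its default scale: 2 000 genes × 4 libraries per run, 20 seeds for the
calibration and recovery properties, 200 seeds × 3 families × 5 000
reads for editing-rate recovery — sizes chosen so the full suite
completes in a few minutes on one core while leaving the assertions
well-powered.  Ties in the Wilcoxon tests fall back to the corrected
normal approximation; zero-variance genes/proteins yield no p-value and
are conservatively classed "unchanged"; weighted (fractional) pileup
counts feed the Wilson interval directly, which is well-defined for
non-integer counts.

## Known limitations

* The wobble model is combinatorial, not thermodynamic: no position-34
  modifications other than inosine (mcm5s2U, queuosine), no
  superwobble energetics, no codon-context effects.
* Editing rates are per isodecoder family; isodecoders within a family
  are aggregated before rate computation.
* The TE test treats replicates as exchangeable measurements of log2 TE;
  it does not model counts directly, so very low-count genes rely on the
  expression floor for protection.
* `run_pipeline()` requires gene identifiers to match between count
  tables and CDS FASTA (and protein ids to match gene ids for the
  proteomics codon report); no identifier mapping is attempted.
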