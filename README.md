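# adatseq

Tools for analysing the translational consequences of **ADAT2/3-mediated
A-to-I tRNA editing**. The ADAT2/3 deaminase converts adenosine to inosine
at the wobble position (position 34) of eight human tRNA isoacceptor
families. Since I34 pairs with A, U and C while the unedited A34 pairs U
only — and the human genome lacks G34 tRNA genes for these boxes — the
C-ending (NNC) codons of the edited boxes can *only* be decoded through
editing. Losing ADAT activity is therefore predicted to depress the
translation of mRNAs in proportion to their strict-codon content.

`adatseq` implements the full quantitative workflow behind that
prediction, for anyone working with tRNA-seq, ribosome profiling and
SILAC proteomics data in an editing-perturbation design:

- **Decoding model** — `build_decoding_table()` enumerates
  anticodon→codon wobble pairings (positions 35/36 Watson–Crick, position
  34 by a configurable rule table with I34→{A,U,C}) and classifies every
  sense codon as `strict` / `dual` / `independent` in its dependence on
  editing; `adat_sensitive_codons()` returns the codons read by I34 tRNAs.
- **Editing quantification** — `read_sam_alignments()`,
  `filter_alignments()` (≤2 mismatches, ≤50 mappings, no pre-tRNA
  leader/trailer/intron evidence), `pileup_at_wobble()` and
  `editing_rate()` estimate the per-family G fraction at position 34
  (inosine reads as G) with a Wilson 95% interval;
  `trna_abundance()` gives steady-state RPM.
- **Translatome** — `translation_efficiency()` computes TE = RPF/RNA on
  CPM scale; `differential_te()` calls up/down/unchanged at p < 0.05 and
  1.5-fold; `aggregate_silac()` + `differential_protein()` handle the
  proteomics branch (peptide-ratio means, moderated t, BH).
- **Codon enrichment** — `codon_usage_matrix()` and `gene_set_report()`
  test the 61 sense codons for differential usage between gene classes
  (Mann–Whitney + BH), annotated with ADAT-dependency classes.
- **Synthetic data** — `sim_config()` / `simulate_study()` generate the
  entire study design with planted truth (editing rates, strict-codon
  content, TE effects, protein ratios), and `run_pipeline()` drives
  everything from files to a machine-readable report.

## Worked example

Simulate a knockdown study retaining 25% of editing activity, then walk
the stages:

```r
library(adatseq)

build_decoding_table()
#> Wobble-decoding table: 61 sense codons
#>   strict (I34-only): 8   dual: 16   independent: 37
#>   strict codons: ACC ATC CCC CGC CTC GCC GTC TCC

cfg <- sim_config(seed = 42, coverage = 1000)
study <- simulate_study(cfg)
refs <- study$references

flt <- filter_alignments(study$trna_knockdown$reads)
editing_rate(pileup_at_wobble(flt, refs))
#> A-to-I editing estimates (position 34) for 8 families
#>     family_id coverage  rate             ci flag
#>  tRNA-Ala-AGC      925 0.217 [0.192, 0.245]
#>  tRNA-Arg-ACG      924 0.202 [0.177, 0.229]
#>  tRNA-Ile-AAT      925 0.026 [0.017, 0.038]
#>  ...
```

Control-condition rates for the same families sit at ~0.85 (e.g.
Ala-AGC 0.835 [0.809, 0.857]), so the knockdown shows the expected
~4-fold editing drop. Downstream, translation efficiency and the codon
report:

```r
rna_cpm <- normalize_cpm(study$counts$rna)
te <- translation_efficiency(normalize_cpm(study$counts$rpf), rna_cpm)
res <- differential_te(te, study$counts$condition, rna_cpm = rna_cpm)
res
#> Differential translation efficiency: 2000 genes (alpha = 0.05, fold-change cut = 1.5)
#>   up: 21   down: 34   unchanged: 1945   untested: 0

cls <- setNames(res$te_class, res$gene_id)
gene_set_report(cls, codon_usage_matrix(study$transcriptome$sequences))
#> Gene-set codon enrichment: 34 down, 21 up, 1945 other genes
#> -- down vs up --
#> Codon enrichment test ( 61 codons )
#>   enriched at q < 0.05 : CCC(strict) GCC(strict) ATC(strict) CTC(strict)
#>                          TCC(strict) CGC(strict) ACC(strict) GTC(strict)
#> ...
#> -- mean log2 usage change by dependency class --
#>   comparison  dependency n_codons mean_delta n_sig_enriched
#>   down_vs_up        dual       16 -0.3682348              0
#>   down_vs_up independent       37 -0.5061185              0
#>   down_vs_up      strict        8  1.5383460              8
```

All eight strictly editing-dependent NNC codons — and only those — come
out enriched in the translationally down-regulated genes, with the dual
(NNT/NNA) codons showing no enrichment: exactly the codon-biased
translation signature the editing model predicts.

The same stages run from files via `run_pipeline()` (YAML config listing
FASTA/SAM/TSV inputs) or the CLI wrapper in `inst/cli/adatseq-pipeline.R`
(`simulate` and `run` subcommands).

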