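# epitoflow

Quantitative analyses for mapping isoform-specific antibody epitopes on
the myeloid receptor **CD300f** in acute myeloid leukemia (AML).
Alternative splicing produces two surface forms of CD300f — the
canonical form lacking exon 4 (CD300f^C) and a splice form carrying the
exon-4-encoded Ser/Thr-rich insert (CD300f^SI4) — and antibodies
directed against the receptor can bind the two forms very differently.
epitoflow is for researchers characterising such antibody panels: it
implements the flow-cytometry, cross-blocking, RNA-seq and qPCR
statistics behind that characterisation, together with a mechanistic
synthetic-data generator so every stage runs and is testable without
patient material.

## What it computes

**Cytometry.** Hierarchical gating with explicit single-channel gates
(`gate_node()`, `apply_gates()`), median fluorescence intensity (MFI),
and positivity by the MFI-ratio rule

> MFI ratio = MFI(population) / MFI(isotype control), positive if ≥ 3.

**Cross-blocking / epitope binning.** For a saturating primary antibody
and a subsaturating labelled test antibody,

> percent binding = 100 × (MFI_test|primary − background_primary) /
> (MFI_test|isotype − background_isotype)

so 0 % means complete epitope overlap, 100 % independent epitopes, and
values above 100 % conformational enhancement (the DCR-2 → UP-D2
effect). `epitope_overlap_matrix()` assembles pairwise results into an
epitope-bin matrix; `enhancement_index()` quantifies enhancement.

**Exon-level isoform quantification.** Reads overlapping the exon-3
(chr17:74,704,478–74,704,517; 40 nt) and exon-4
(chr17:74,703,100–74,703,141; 42 nt = 14 codons) windows on GRCh38 are
counted (`count_overlapping_reads()`) and normalised as

> RPKM = (target reads / (total reads / 10^6)) / (target length in kb),

with one-way ANOVA + Tukey HSD group comparison (`exon_usage_compare()`)
and exon-4 transcript-fraction estimation
(`estimate_exon4_fraction()`).

**qPCR.** Isoform-specific primers (`assign_amplicon()`,
`cd300f_primers()`) and relative quantification by ΔΔCT:

> ΔCT = CT_target − CT_HPRT, ΔΔCT = ΔCT_sample − ΔCT_calibrator,
> fold change = 2^−ΔΔCT.

**Synthetic data with ground truth.** `simulate_event_table()`,
`simulate_blocking_experiment()`, `simulate_reads()` and
`simulate_qpcr()` generate every input from a mechanistic model
(log-normal fluorescence, per-cell surface copy numbers in the
10^1–10^4 range, epitope occlusion and enhancement, uniform read
placement over a two-transcript exon model, exponential amplification).
All generators are deterministic under a seed.

## Worked example

Simulate the DCR-2 → UP-D2 cross-blocking experiment on
cell-line-like target cells and summarise it:

```r
library(epitoflow)
panel <- default_antibody_panel()
sim <- simulate_blocking_experiment(panel[["DCR-2"]], panel[["UP-D2"]],
                                    isoform_profile(4000, 6000),
                                    n = 10000, seed = 1)
blocking_result(sim)
#>   primary  test mfi_test_given_primary mfi_background_primary_condition
#> 1   DCR-2 UP-D2               16869.33                         50.21217
#>   mfi_test_given_isotype mfi_background_isotype_condition percent_binding
#> 1               7495.579                         50.08867        225.8967
#>   fraction_bound low_signal
#> 1       2.258967      FALSE
```

UP-D2 binding after DCR-2 preincubation is 226 % of its unblocked level
— far above 100 %, so DCR-2 does not block UP-D2 but *enhances* it, the
signature of a conformational epitope exposed by DCR-2 binding.

The full pipeline (gating → positivity → cross-blocking matrix →
enhancement contrast → exon quantification → qPCR):

```r
run_pipeline(pipeline_config(seed = 1))
#> epitoflow pipeline report
#>   - Positive populations (MFI ratio >= 3): 10 of 15 calls
#>   - Cross-blocking: 4 distinct epitope groups; 1 enhanced pair(s)
#>   - Enhancement (DCR-2 -> UP-D2) flagged in: monocytic_aml
#>   - Exon-level ANOVA p-values: exon3 = 0.887, exon4 = 3.04e-11 *
#>   - qPCR class contrasts: CD300f_C p = 0.737, CD300f_SI4 p = 2.1e-08 *
```

Reading the summary: the antibody panel resolves four distinct epitope
groups with one enhanced pair; DCR-2 → UP-D2 enhancement is detected on
the SI4-rich monocytic-AML-like profile but not the SI4-poor HSPC-like
profile; and across the simulated RNA-seq and qPCR cohorts only the
exon-4 (splice-form) signal differs between groups — the canonical-form
signal does not. Set `out_dir` in `pipeline_config()` to write the
TSV/JSON/Markdown report bundle.

See the methods vignette (`vignettes/epitoflow-methods.Rmd`) for the
underlying models, parameter defaults and design choices.

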