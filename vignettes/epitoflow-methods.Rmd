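---
title: "Methods: models and design choices behind epitoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices behind epitoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitoflow)
```

# Scope

CD300f is a myeloid immunoregulatory receptor expressed on acute myeloid
leukemia (AML) blasts. Alternative splicing produces two surface forms
that matter for antibody targeting: the canonical form (`C`), which lacks
exon 4, and a splice form (`SI4`) that carries a 14-residue Ser/Thr-rich
insert encoded by exon 4. epitoflow implements the quantitative analyses
needed to characterise a panel of CD300f antibodies against these two
forms:

* hierarchical flow-cytometry gating and MFI-ratio positivity calls;
* antibody cross-blocking ("epitope binning") with the percent-binding
  statistic, including conformational enhancement;
* exon-level isoform quantification from aligned RNA-seq reads (exon 3
  vs exon 4 RPKM);
* isoform-specific qPCR relative quantification (ΔΔCT);
* the shared group-comparison statistics (Welch t, one-way ANOVA with
  post hoc comparisons) and an end-to-end pipeline runner.

Patient samples and public RNA-seq accessions are outside the package's
scope; instead, a mechanistic synthetic-data generator produces every
input with known ground truth, so each statistic can be validated
against the closed form of the generating model.

# The cytometry signal model

Each simulated cell carries `n_C` and `n_SI4` surface copies of the two
forms. An antibody `a` has per-isoform epitope accessibilities
`acc_C(a)` and `acc_SI4(a)` in [0, 1], and its detector channel reads

```
intensity = AF + gain * (n_C * acc_C + n_SI4 * acc_SI4) * m
```

where `AF` is log-normal autofluorescence and `m` a mean-one log-normal
measurement factor with coefficient of variation `cv`. Both noise terms
are multiplicative and log-normal — the standard shape for cytometry
intensities — which keeps channel medians well defined and positive.
Isotype-control channels have zero accessibility and therefore carry
autofluorescence only. Defaults (`noise_spec()`): median
autofluorescence 50 intensity units (`af_meanlog = log(50)`,
`af_sdlog = 0.4`), `gain = 1`, `cv = 0.2`.

Surface copy numbers are the quantity reported for AML blasts by
bead-calibrated cytometry, spanning roughly 10^1–10^4 molecules per
cell; default population profiles sit inside that range and sampled
totals are capped at 10^4 (both forms scaled proportionally).
`noiseless = TRUE` pins autofluorescence at its median, copy numbers at
the profile medians and `m = 1`, making every derived MFI statistic an
exact function of the model parameters — this is how the closed-form
tests are driven.

# Cross-blocking and enhancement

A cross-blocking experiment has four arms: cells saturated with the
primary antibody (occupancy 1) or its isotype, each then stained with a
subsaturating labelled test antibody or the test isotype. The model has
two interaction parameters per ordered pair:

* `omega(primary -> test)` in [0, 1]: the fraction of the test
  antibody's accessible epitopes occluded by the bound primary;
* `e_C, e_SI4 >= 1`: conformational-enhancement factors multiplying the
  test antibody's accessibility per isoform while the primary is bound.

The test-specific signal under primary preincubation is therefore
`gain * sum_i n_i * acc_i * (1 - omega) * e_i`. Occlusion and
enhancement compose multiplicatively and independently — the data the
model emulates report both effects but not their interaction, so the
simplest composition is used. "Saturating" is interpreted as epitope
occupancy exactly 1; the subsaturating test antibody binds
proportionally to free accessible epitopes.

The percent-binding statistic is

```
100 * (MFI_test|primary - background_primary) /
      (MFI_test|isotype - background_isotype)
```

On noiseless simulations this equals `100 * (1 - omega) * e` exactly
(with `e` the profile-weighted enhancement), giving the scale endpoints:
fraction bound 0 at complete overlap, 1 at independent epitopes, above 1
under enhancement. The published formula names its four MFIs ambiguously
("MFI Primary isotype", "MFI Primary Antibody"); the mapping implemented
here — test-after-primary, background in the primary arm,
test-after-isotype, background in the isotype arm — is the one that
pins the statistic to those endpoints, and the four arguments of
`percent_binding()` make the mapping explicit and overridable. Negative
values (blocked arm below background) are reported as-is with a
`low_signal` flag rather than clamped.

The cross-blocking matrix categorises each ordered pair as `blocked`
(< 30%), `independent`, or `enhanced` (> 130%). The underlying statistic
is continuous and the source analyses never binarise it; the default
thresholds are generous margins around 0% and 100% and are configurable
arguments, not tuned values.

## Enhancement defaults

The default panel models the DCR-2 -> UP-D2 conformational enhancement
as specific to the SI4 form (`e_C = 1`, `e_SI4 = 3`). Enhancement of
UP-D2 has also been observed on canonical-form transfectants; the
package models the effect as SI4-driven because (i) no magnitude is
published for either form, and (ii) the group-level contrast the
pipeline reproduces — enhancement detectable on SI4-rich monocytic-AML
profiles but not on SI4-poor HSPC profiles — is a property of SI4-driven
enhancement. Users who want a canonical-form component can set
`default_antibody_panel(e_C = ...)`; the enhancement-monotonicity
property (index nondecreasing in the SI4 fraction) holds for any
`e_C < e_SI4`.

Similarly, the HSPC-like enhancement profile defaults to essentially no
surface SI4 (`isoform_profile(1000, 0)`): healthy HSPC express
predominantly the canonical transcript, and a strictly positive surface
SI4 fraction combined with `e_SI4 > 1` would make enhancement a
mathematical certainty in every group, erasing the contrast the model
is meant to expose.

# Gating

Gate trees are explicit: one single-channel predicate per node (`gt`,
`lt`, `between`), fixed numeric thresholds from configuration, events in
a node satisfying the conjunction from the root down. No automated
valley-finding or clustering is attempted — fixed thresholds are
reproducible and directly testable against the generator's truth
labels. The default tree mirrors the standard strategy: viable
(PI-negative) cells split into CD45-high lymphocytes/monocytes
(separated on CD14) and CD45dim/SSClow blasts. On the default cohort the
leaf assignments agree with the generating labels for more than 95% of
events; the misassigned remainder are genuine distribution-tail events,
as in real manual gating.

MFI is the channel median (even counts: midpoint convention); a
geometric-mean option exists because some instruments report it, but the
median is canonical throughout. Positivity is MFI ratio >= 3 versus the
isotype control, inclusive.

# Exon-level isoform quantification

The two quantification windows are the printed GRCh38 coordinates:
exon 3 at chr17:74,704,478–74,704,517 and exon 4 at
chr17:74,703,100–74,703,141. Coordinates are interpreted as 1-based
inclusive, under which exon 4 spans exactly 42 nt = 14 codons —
matching the 14 inserted residues — and exon 3 spans 40 nt. Whether the
windows are full exons or mappability sub-windows is immaterial here;
they are treated as opaque counting targets. A read counts if it shares
at least one base with the window (configurable), strand-agnostic; BED
input is converted from 0-based half-open on read. RPKM follows the
printed formula `[(target reads) / (total reads / 1e6)] / (length in
kb)` with "total reads" supplied as library metadata.

## The read simulator

The simulator uses a minimal two-transcript model: both transcripts
share an upstream body block, the exon-3 window and a downstream body
block (canonical length 2 kb); the splice-form transcript additionally
contains the exon-4 window (2,042 nt). The flanking body blocks are
synthetic stand-ins for the remaining exons. Reads are placed uniformly
over the pooled start positions of a transcript mixture with molecule
abundances `(1 - f, f)`, where `f` is the group's exon-4 transcript
fraction. A read spanning a block junction is emitted as the single
segment containing the read midpoint, clipped to that block; this makes
the expected count in a window proportional to window length, so the
length-normalised count ratio `(count4 / 42) / (count3 / 40)` estimates
`f` without bias (`estimate_exon4_fraction()`), and at the default
library size the estimate is within 10% relative using 20 samples.

`library_size` (default 10^6) is the total aligned library used as the
RPKM denominator; the number of emitted locus reads is
`library_size * expression`, with `expression` the CD300f locus's share
of the library (default 0.002, a strongly expressed gene) jittered
per-sample by a log-normal with CV 0.15 to emulate biological
expression variability. That jitter is what gives exon-3 RPKM a
realistic within-group spread; without it the locus-restricted
simulation would make exon-3 RPKM nearly deterministic.

Default RNA-seq groups (`default_read_spec()`): HSPC-like `f = 0.05`,
monocytic-AML-like `f = 0.5`, nonmonocytic-AML-like `f = 0.1`, six
libraries per group, equal mean expression — so exon 4, and only
exon 4, separates the groups, reproducing the expected pattern
(monocytic AML high, exon 3 flat).

# qPCR

The CT model is `CT = CT_ref - log(x / x_ref) / log(1 + E)` plus
Gaussian replicate noise (default SD 0.2 cycles, duplicates); `E` in
(0, 1] is the amplification efficiency. Zero-abundance templates, and
any CT reaching 40 cycles, are censored. The analysis side averages
replicate CTs arithmetically, normalises against the endogenous
reference gene (HPRT), expresses ΔΔCT against a calibrator sample and
reports `2^-ΔΔCT`; the calibrator's fold change is exactly 1 by
construction, and adding a constant to all of a sample's CTs (a plate
shift) cancels. The estimator assumes efficiency 1, as the plain
`2^-ΔΔCT` formula does; primer efficiencies for this assay are above
0.98, where the approximation error is below the replicate noise. The
primer-to-isoform map is fixed reference data: the SI4-specific forward
primer detects the exon-4-containing isoforms 4 and 6, the canonical
forward primer the exon-4-lacking isoforms 1, 2, 3, 5 and 7.

# Statistics

Single-group comparisons use the Welch t-test (unequal variances,
Welch–Satterthwaite df, two-sided). Multi-group comparisons use one-way
ANOVA with Tukey HSD post hoc by default — the conventional reading of
"one-way ANOVA with multiple comparisons" — with Holm-corrected
pairwise Welch tests as an alternative. α = 0.05 throughout,
configurable. The pipeline's enhancement contrast uses a one-sample t
on log enhancement indices across replicate experiments (unpaired
arms; whether the original experiments were paired is not stated, and
the unpaired choice is conservative here).

# Determinism and numerics

Every stochastic operation takes one integer seed and evaluates under a
saved-and-restored RNG state, so identical specs and seeds give
byte-identical outputs and no call disturbs the caller's RNG. The
pipeline derives stage seeds as small fixed offsets from its master
seed. Degenerate inputs are defined rather than accidental: zero events
give an empty, schema-complete table; empty gate subsets propagate
without error; an empty MFI subset, a nonpositive isotype MFI, a
nonpositive percent-binding denominator and a censored CT are all
explicit error or flag paths.

# Problem sizes used in validation

The test suite validates at these scales: noiseless blocking closed
forms over the full `omega` × enhancement grid; noisy percent binding
at 10^4 events per arm across 100 seeds (deviations stay within ±5
percentage points); overlap counting against a brute-force oracle on
500 random instances; Welch type-I error on 10^4 null replicates and
ANOVA type-I error on 10^3 (both inside [0.04, 0.06]); gate recovery on
10^4-event cohorts; exon-4 fraction recovery at library size 10^6 with
20 samples; the qPCR round trip across 100 seeds; and the end-to-end
pipeline at its default configuration.

# What passing tests do and do not show

The generator emulates log-normal fluorescence, antigen-density ranges,
epitope occlusion/enhancement, uniform read placement and exponential
qPCR amplification. It does not emulate spectral spillover or
compensation, doublets and debris, antibody binding kinetics or
avidity, positional read bias, GC bias or mappability, primer-dimer and
melt-curve artefacts, or patient-to-patient biological heterogeneity
beyond simple log-normal scatter. Passing tests therefore demonstrate
that the statistics are implemented correctly and recover the
parameters of this mechanistic model — not that the biological
conclusions would replicate in patient cohorts, which would require the
original accession data and is deliberately out of scope.
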