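---
title: "Methods: diDO-IPTL quantification and proteorhodopsin physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diDO-IPTL quantification and proteorhodopsin physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iptlquant)
library(dplyr)
```

`iptlquant` analyses quantitative proteomics and growth physiology of a
proteorhodopsin (PR)-bearing marine *Vibrio* grown into stationary phase
under defined carbon or nitrogen limitation. This vignette documents the
models the package implements, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices that were genuinely open.

## The labeling model

diDO-IPTL (dimethylation-deuteration and oxygen-exchange isobaric peptide
terminal labeling) quantifies two samples in one MS run by giving them
near-isobaric terminal labels that separate in the fragment series:

* channel A: d4-dimethylation of the peptide N terminus
  (+32.056407 Da) and an unlabeled C terminus;
* channel B: light dimethylation (+28.031300 Da) and complete double
  ¹⁸O exchange at the C terminus (+4.008490 Da).

All deltas are computed from monoisotopic atomic masses in
`label_masses()`. Precursors of the two channels differ by only
4×(D−H) − 2×(¹⁸O−¹⁶O) ≈ 0.0166 Da and co-isolate; b ions separate the
channels by 4.025107 Da, y ions by 4.008490 Da in the opposite direction.
Membrane-fraction samples carry channel A with a pooled internal standard
on channel B; cytosolic fractions are labeled conversely
(`label_scheme()`). Lysine side-chain dimethylation is not modeled — the
labels are purely N-terminal — and ¹⁸O exchange is treated as complete;
partial exchange would appear as an intermediate isotopologue the current
matcher does not generate.

## Spectrum quantification

For each peptide-spectrum match, every fragment (b or y, index i) whose
theoretical m/z is observed within the fragment tolerance in **both**
channels yields a pair ratio I_sample/I_standard. The spectrum-level
log2 ratio is the **median** of the per-pair log2 ratios: a single
interfered fragment then perturbs the estimate by at most its rank, not
its magnitude. A summed-intensity mode (`method = "sum"` in
`quantify_spectrum()`) is available for comparison; on clean synthetic
spectra the two agree, and the median is the default throughout.

The fragment tolerance defaults to 0.01 Da. The two channels are 4.008 Da
apart at the closest, so this tolerance cleanly separates them while
absorbing centroiding error; it is configurable wherever it appears.

Identification uses a deliberately minimal matcher: the score of a
candidate is the number of its theoretical fragment m/z values (either
channel) present in the spectrum, decoys are full-sequence-reversed
proteins digested like targets, and ties break lexicographically by
peptide then target-before-decoy so results are order-invariant.
Spectrum-level false discovery is controlled by target-decoy q-values:
FDR(s) = #decoys ≥ s / #targets ≥ s, monotonised so q is non-increasing
in score, and only targets with q < 0.001 (0.1% spectrum-level FDR) are
quantified. This matcher is not a replacement for a production search
engine — no PTMs, charge-1 fragments only, no intensity weighting — but
on the closed world of a toy proteome it identifies essentially every
simulated spectrum and rejects essentially every pure-noise spectrum,
which is what the downstream statistics need.

## Expression tables

Protein × sample values are built in the order:

1. **Evidence filter**: within a protein × LC-MS sample, peptides with
   fewer than two quantified spectra are discarded; a protein with no
   surviving spectra is *absent* from that sample, never zero.
2. **Aggregation**: protein log2 abundance = mean of surviving spectrum
   log2 ratios, SE = sd/√n.
3. **Normalization**: the median of all protein log2 ratios in each
   LC-MS sample (fraction × condition × light × replicate × timepoint) is
   set to zero, putting values on a per-amount-total-protein basis.
   Normalization precedes fraction assignment, so proteins later dropped
   from a fraction still inform that sample's median.
4. **Fraction assignment**: proteins quantified in both membrane and
   cytosolic fractions keep the fraction with more total spectra; ties go
   to the cytosolic fraction (the better-behaved matrix in practice).
5. **Replicate consolidation**: mean across biological replicates with
   combined error sqrt(σ_x² + μ_SE²), where σ_x is the between-replicate
   standard deviation (n−1 denominator, the standard choice for
   triplicates) and μ_SE the mean per-replicate SE. The combined error
   therefore dominates both of its components. A single surviving
   replicate passes through flagged `low_confidence`.

Timepoints map to growth phases 3/4/2 (exponential/transition/stationary)
for the canonical nine-point design; other counts split proportionally
with at least one timepoint per phase.

## Differential expression

Contrasts (light vs dark; C vs N limitation) are tested per phase and
across all phases, pooling replicate × timepoint values within a phase as
exchangeable observations. Consolidation is deliberately *not* applied on
this path: replicate-level values keep the residual variance estimable.
Per protein, the effect is the difference of group means and the residual
variance the pooled two-group variance with n_A + n_B − 2 df. Variances
are shrunk toward a global prior by an empirical-Bayes method-of-moments
fit on the log-variance distribution (prior df d₀ from the excess
variance of log s² over the χ² expectation via an inverse-trigamma
solve; prior variance s₀² from its mean). The moderated t uses d₀ + d_g
df. Degenerate inputs: identical observed variances are a fixed point of
the shrinkage map (d₀ = ∞, s₀² equal to the common value); all-zero
variances fall back to ordinary t with a warning; d₀ → 0 recovers the
unmoderated t exactly. The implementation agrees numerically with
limma's `squeezeVar` on scattered-variance data (verified in the test
suite), but is self-contained.

Significance is Benjamini–Hochberg adjusted p < 0.05; the threshold and
the q-value gate are arguments, not constants.

## Absolute PR quantification

PR is quantified against synthetic heavy-lysine standard peptides
(LWETQGVAK and NLADVVNK) spiked at 0.5 pmol/µL × 0.75 µL = 0.375 pmol
per analyzed mix into 7.25 µL of sample. Native amount = (native area /
standard area) × 0.375 pmol, averaged over the two peptides; the injected
share of the mix is identical for native and standard species and cancels.
XIC areas are integrated by the trapezoid rule (`integrate_peak()`);
cells analyzed come from an ordinary least-squares OD-to-cells/mL
calibration times the 4.5 mL harvest volume; copies/cell = moles ×
Avogadro / cells. The stationary-phase C/N fold change is the ratio of
stationary-timepoint means on a per-cell basis — proportional to the
per-mg-protein basis under the generator's constant-protein-per-cell
assumption, and insensitive to the post-stationary OD decline of the
C-limited cultures, which a raw per-sample-amount ratio would not be.
Its error is first-order propagation of the replicate standard
deviations.

## Growth, survival and qPCR analytics

The growth model is a saturating exponential: OD rises exactly
exponentially at µ_max from OD₀ until it reaches OD_max, holds, and then
follows the condition's post-stationary behaviour (exponential OD decline
with retained cultivability when carbon-limited; maintained OD with CFU
collapse to zero by ~100 h when nitrogen-limited). A logistic curve was
considered and rejected: its ln-OD slope never equals µ_max at any
sampled OD, whereas the analysis contract (and the growth-rate
estimator's exactness test) requires a window where ln OD is linear with
slope µ_max.

µ_max is estimated as the maximum over 3-point sliding windows of the
least-squares slope of ln OD vs time, skipping windows with non-positive
OD. With multiplicative noise this max-statistic carries a small upward
bias (≈5–10% at the default 2% OD noise) that users should keep in mind
when comparing window sizes; the window is an argument. qPCR relative
expression is efficiency-corrected and calibrator-free,
E_t^(−Ct_t) / E_r^(−Ct_r) against the recA reference. Significant
expression peaks are timepoints that exceed both neighbours' means
(boundary points use their single neighbour), exceed the mid-exponential
reference level at t = 9 h, and pass a two-sided Welch t-test against the
reference replicates at p < 0.05; Welch was chosen because replicate
variances at different timepoints have no reason to be equal.

## The synthetic-data generator

Every analysis input is generated with known ground truth; all outputs
are pure functions of (scenario, seed). The default scenario
`scenario_caim519()` encodes the study conditions: triplicate C- and
N-limited cultures under continuous light and dark; proteomic sampling at
7.5–75.5 h (nine timepoints, phases 3/4/2); µ_max 0.14/0.15 h⁻¹ and
OD_max 0.72/0.83; C-limited OD decline after ~50 h with slow CFU loss;
N-limited CFU collapse at 99.5 h with ~10% terminal viability; a PR
protein trajectory rising to a stationary plateau with maximum
5606 copies/cell and a stationary plateau 4.4-fold higher under C than N
limitation; PR/rpoS transcripts peaking at the transition, blh with
transition and late-stationary peaks, constant recA; and expression truth
with ~60% null, ~30% nutrient-responsive and ~10% light-responsive
proteins whose effects are phase-amplified.

Where the study design fixes no value, defaults were chosen once at
field-realistic levels and documented here: lognormal fragment-intensity
noise sd 0.25 (natural log), MS1 area noise sd 0.1, multiplicative OD
noise 2%, Ct noise 0.15 cycles, calibration count noise 5%; 1 + Poisson
(mean 1.7) spectra per peptide so most peptides clear the two-spectra
rule; 10% pure-noise spectra as decoy fodder; cell density 10⁹
cells/mL/OD. Multiplicative lognormal noise is the standard error model
for MS intensities; spectra-per-peptide and the intensity scale are free
parameters of the acquisition that the analysis never relies on.

The generator has two layers. The **spectrum layer**
(`simulate_iptl_run()`) emits full two-channel MGF spectra —
fraction-appropriate digests (chymotrypsin + trypsin for membrane,
trypsin for cytosolic, cleavage after K/R resp. F/W/Y/L/M but not before
proline, products ≥5 residues), b/y series of both channels, per-fragment
lognormal noise around the true channel ratio — and is used to validate
the identification/quantification chain end to end, including an exact
noiseless round trip. The **expression layer** (`simulate_expression()`)
draws replicate-level log2 tables directly from the same truth and is
used to exercise consolidation and differential expression at full design
size, where simulating and matching hundreds of MGF runs would add cost
but no information. Both layers share the truth tables, so conclusions
transfer.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: chromatographic retention time and
co-elution interference, isotope envelopes and charge states above 2,
partial ¹⁸O exchange and label impurity, peptide-specific ionisation
efficiency, missing-at-random protein dropout, ion-statistics
(intensity-dependent) noise, and real decoy score distributions from
large search spaces. The matcher's perfect identification rate on the toy
proteome in particular says nothing about FDR calibration on a real
proteome.

## Problem sizes and determinism

Simulations in the test suite use toy proteomes of 4–8 proteins, one or
two LC-MS samples per fraction for the spectrum layer, and the full
2 × 2 × 3 × 9 design for tabular layers; the scenario-recovery checks
average 10 scenario realisations. These sizes were chosen so the whole
suite exercises every code path in a few minutes while leaving the
recovery statistics comfortably estimable. Every stochastic step takes an
explicit seed, child seeds are derived per stream (so adding a generator
call never perturbs another stream), and rerunning any pipeline with the
same scenario and seed is byte-identical.

## Known limitations

* The minimal matcher is a stand-in appropriate for a closed toy
  proteome, not a search engine.
* Fraction assignment resolves dual-fraction proteins by spectrum count
  only; no topology-aware membrane annotation is used.
* The stationary fold change assumes constant protein content per cell
  when converting to a per-amount-protein basis.
* Contrasts treat within-phase timepoints as exchangeable replicates;
  time-course modeling (splines, autocorrelation) is out of scope.
* qPCR quantification is calibrator-free and reports ratios to recA only.
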