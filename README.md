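# iptlquant

Quantitative proteomics and growth physiology of a proteorhodopsin-bearing
marine *Vibrio* under carbon and nitrogen limitation.

Proteorhodopsin (PR) is a light-driven proton pump carried by many marine
bacteria, yet carrying the gene does not guarantee a measurable
photoheterotrophic benefit. Testing that requires quantifying PR and the
rest of the proteome — absolutely, per cell, across growth phases, in
light and dark, under defined nutrient limitation — together with the
growth, survival and transcript measurements that give those numbers
context. `iptlquant` implements that entire analysis as a tidyverse-native
R package, driven by a synthetic-data generator with known ground truth so
every stage can be validated without any external data download.

## What it implements

* **diDO-IPTL ratio quantification.** Two-channel isobaric peptide
  terminal labeling: channel A = d4-dimethylated N terminus
  (+32.056407 Da), channel B = light dimethyl (+28.031300 Da) plus double
  ¹⁸O C-terminal exchange (+4.008490 Da). Channels co-isolate (precursor
  gap ≈ 0.0166 Da) and resolve in the fragment series; for each spectrum
  the sample/standard log2 ratio is the median over fragment pairs of
  log2(I_sample/I_standard). Identification is target-decoy controlled at
  spectrum-level q < 0.001, with FDR(s) = #decoys≥s / #targets≥s,
  monotonised.
* **Expression tables.** Per-sample median-zero normalization, the
  ≥2-spectra-per-peptide evidence rule, membrane/cytosolic fraction
  assignment by spectrum count, growth-phase designation (3/4/2 over the
  nine standard timepoints), and replicate consolidation with combined
  error `sqrt(sigma_x^2 + mu_SE^2)`.
* **Moderated differential expression.** Pairwise contrasts (light vs
  dark, C vs N) pooling samples within a growth phase; empirical-Bayes
  variance shrinkage s̃²_g = (d₀s₀² + d_g s_g²)/(d₀ + d_g) with
  method-of-moments hyperparameters and Benjamini–Hochberg control.
* **Absolute PR quantification.** Heavy-lysine standard peptides
  (LWETQGVAK, NLADVVNK; 0.5 pmol/µL stock, 0.75 µL spike = 0.375 pmol),
  trapezoidal peak areas, OD→cell-density calibration, copies/cell =
  mol × N_A / cells, and the stationary-phase C/N fold change.
* **Physiology.** µ_max as the max sliding-window slope of ln OD, OD_max,
  CFU from spot plating, efficiency-corrected qPCR relative expression
  (E_t^(−Ct_t)/E_r^(−Ct_r), recA reference), significant-peak detection
  (local maximum + Welch t vs the t = 9 h reference, p < 0.05), and
  survival summaries separating the two starvation phenotypes.
* **Synthetic data.** `scenario_caim519()` encodes the study conditions
  (triplicates, 9 proteomic timepoints, µ_max 0.14/0.15 h⁻¹, OD_max
  0.72/0.83, PR plateau 4.4-fold higher under C limitation, max
  5606 copies/cell, CFU collapse at ~100 h under N limitation) and all
  `simulate_*` functions are pure functions of (scenario, seed): MGF
  spectra, FASTA proteome, growth/qPCR/peak-area tables.

## Worked example

```r
library(iptlquant)
library(dplyr)

vibrio_media()
#>   condition maltose_mM nh4cl_mM cn_ratio
#> 1 C_limited       2.78        2     16.7
#> 2 N_limited       8.33        1    100.0

sc <- scenario_caim519(n_proteins = 30, seed = 1)
curves <- simulate_growth_all(sc)
growth_summary(curves) |>
  group_by(condition) |>
  summarise(mu_max = mean(mu_max), od_max = mean(od_max))
#>   condition mu_max od_max
#> 1 C_limited  0.156  0.725
#> 2 N_limited  0.161  0.856

calibration <- fit_od_calibration(simulate_od_calibration(sc))
areas <- simulate_pr_standard_areas(sc)
od_tab <- curves |>
  filter(time_h %in% sc$timepoints_h) |>
  select(condition, light, replicate, time_h, od)
pr <- pr_quantify(areas, od_tab, calibration, sc$spike, sc$harvest_volume_ml)
condition_fold_change(pr)
#>   fold_change    se numerator_mean denominator_mean ...
#> 1        4.25 0.164          5443.            1282.

expr <- simulate_expression(sc)
fit <- ebayes_moderate(fit_contrast(expr, make_contrast(
  "C_vs_N_stationary",
  group_a = list(condition = "C_limited", phase = "stationary"),
  group_b = list(condition = "N_limited", phase = "stationary"))))
fit
#> <moderated_fit> contrast: C_vs_N_stationary
#>   30 proteins; prior df d0 = 1.722, prior variance s0^2 = 0.01457
#>   significant (BH < 0.05): 9
```

The media table reproduces the defined media's C/N molar ratios (16.68:1
and 99.96:1) from the maltose (12 C per molecule) and NH₄Cl
concentrations. The growth summary recovers the scenario's true rates and
yields from noisy triplicate curves; the PR section runs the complete
absolute-quantification chain (area ratios → pmol → cells from OD →
copies/cell) and recovers the 4.4-fold stationary C/N plateau ratio
within noise; the moderated fit shrinks 30 per-protein variances toward a
common prior and calls the truly nutrient-responsive proteins at
BH < 0.05. `tidy()`, `glance()` and `autoplot()` work on fitted objects,
and `plot_growth_curves()`, `plot_pr_copies()`, `plot_qpcr()` cover the
main result types. `run_pipeline(scenario, outdir, seed)` executes every
stage (spectra → PSMs → ratios → tables → contrasts → PR → physiology)
and writes CSVs plus a machine-readable `summary.json`.

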