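# circaBP

Circadian blood-pressure (BP) phenotyping for acute stroke monitoring.

In the first 72 hours after an ischemic stroke, continuously monitored
patients show profound disruption of the normal 24-h BP rhythm: blunted
amplitude, elevated nocturnal pressure, and loss of the physiological
nocturnal "dip". These early trajectories are not uniform — data-driven
analyses of stroke-unit monitoring separate reproducible phenotypes
(persistently elevated *Steady-High*, low-amplitude *Disrupted-Rhythmicity*,
and *Partial-Recovery* with dipping that returns across nights) that carry
prognostic information for early deterioration, hemorrhage, functional
outcome and cardiovascular events. circaBP provides the full analysis chain
for this kind of study, for clinical researchers working with stroke-unit or
ambulatory BP monitoring exports.

The core quantities come from single-component cosinor regression per
admission-aligned 24-h cycle,

    y(t) = M + A·cos(2π(t − φ)/24) + ε,

with MESOR `M` (rhythm-adjusted mean, mmHg), amplitude `A` (mmHg) and
acrophase `φ` (clock time of the fitted peak). Nocturnal decline is
`100·(day − night)/day` on the fitted curve, classified as
reverse-dipper (< 0%), non-dipper [0, 10%), dipper [10, 20%) and
extreme-dipper (≥ 20%). The pipeline around it:

- **QC / ingest** — artifact editing (physiologic bounds, pressure
  inversion, spike rule), measurement density against the source's nominal
  schedule, eligibility rules (≥ 48 h monitored, ≤ 20% missing after
  imputation, ≥ 12 h covered per monitoring cycle).
- **Imputation** — per-patient maximum-likelihood local-level state-space
  model on the irregular time grid; RTS (Kalman) smoothing fills gaps of at
  most 30 min, longer gaps stay missing.
- **Features** — cosinor parameters per cycle, nightly declines,
  dispersion metrics (SD, CV, ARV, range) on a harmonised 30-min grid,
  sample entropy, recovery slope.
- **Phenotyping** — Gaussian-mixture clustering (mclust) of the z-scored
  features; cluster number over k = 2–6 by near-max silhouette gated BIC;
  clusterwise bootstrap Jaccard stability; semantic labels from centroid
  evidence.
- **Associations** — χ²/Fisher selection by expected counts, Bonferroni
  and Benjamini–Hochberg corrections, Hosmer–Lemeshow calibration, VIF,
  Cohen's h, two-proportion Z, Kaplan–Meier/log-rank, adjusted
  logistic/Cox models with Partial-Recovery as reference.
- **Synthetic cohorts** — a fully parameterised generator that emulates
  the monitoring design (1-min invasive / 15–30-min cuff schedules, gap and
  artifact processes calibrated to ~82% median density) and the phenotype
  effect structure, with hidden truth tables for validation.

## Worked example

```r
library(circaBP)

sim <- generate_cohort(cohort_config(n_patients = 120, seed = 42))
sim
#> <bp_cohort> 120 patients, 72434 readings (12.5% invasive)
#> Disrupted-Rhythmicity      Partial-Recovery           Steady-High
#>                    42                    38                    40

fx <- process_bp_series(sim$series)   # QC -> impute -> cosinor -> dipping -> features
sum(fx$qc$eligible)
#> [1] 91

summarize_cohort_rhythm(fx$fits, n_boot = 200, seed = 1)
#>    n mean_mesor mesor_lo mesor_hi mean_amplitude amplitude_lo amplitude_hi
#> 1 91     135.96   133.82    138.1           6.66         5.96         7.35
```

91 of 120 simulated patients survive the eligibility rules (the others
mimic real exclusions for inadequate monitoring density). The cohort mean
MESOR of 136 mmHg (95% CI 134–138) and mean amplitude of 6.7 mmHg
(6.0–7.4) recover the generator's configured mixture (137 mmHg, 6.4 mmHg)
within their confidence intervals — the blunted-amplitude, elevated-MESOR
signature of the acute-stroke setting.

```r
ph <- derive_phenotypes(fx$features, k = 3, seed = 1)
ph$labeling$evidence
#>   cluster mesor amplitude recovery_slope label
#> 1       1  126.      5.59        -0.101  Disrupted-Rhythmicity
#> 2       2  147.      6.04        -0.059  Steady-High
#> 3       3  134.     11.2          0.232  Partial-Recovery

dp <- dipping_results(fx$fits, collapse_extreme = TRUE)
dipping_prevalence(dp$category[dp$night_index == 1])
#>   category           n   prop   pct
#> 1 dipper             8 0.0879   8.8
#> 2 non-dipper        56 0.615   61.5
#> 3 reverse-dipper    27 0.297   29.7
```

The three clusters are labelled from their centroid evidence (highest
MESOR → Steady-High; lowest remaining amplitude → Disrupted-Rhythmicity),
and night-1 dipping is dominated by non- and reverse-dipping, as expected
acutely after stroke.

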