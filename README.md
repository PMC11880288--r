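# mmgtorque

Estimation of elbow-flexion torque from mechanomyography (MMG) recorded
during neuromuscular electrical stimulation (NMES), with joint wrapper
feature selection and random-forest hyperparameter tuning by the
Equilibrium Optimizer (EO) and its General Learning variant (GLEO).

## Who this is for

Researchers in neuromuscular biomechanics and biosignal processing who want
a complete, reproducible reference pipeline from raw synchronized
MMG/torque traces to an optimized torque-estimation model — and a clean,
tested implementation of EO/GLEO wrapper optimization that works on any
tabular regression problem with the same 12-feature layout.

## What it computes

1. **Signal conditioning** — zero-phase 4th-order Butterworth filters (MMG
   band-pass 5–100 Hz, torque low-pass 5 Hz) and 6 s head/tail transient
   trimming.
2. **Features** — per 100 ms window (50% overlap): RMS, zero-crossing rate,
   Hjorth mobility, mean power frequency (MPF), median frequency (MDF),
   spectral centroid/spread/flatness/flux, and the 5–12 / 12–40 / 40–100 Hz
   band-energy fractions; target = windowed torque RMS.
3. **Normalization** — pooled Z-scores with row censoring at |z| > 3, then
   min-max to [0, 1]; grey relational screening of feature relevance.
4. **Split** — histogram-binned stratified 70/30 (50 bins of width 0.02 on
   the target).
5. **Model** — random-forest regression with four tunable hyperparameters:
   `Ntrees` (200–1500), `mTrees` (1–12), `MinLeafSize` (1–10), `Nsplits`
   (split cap, 100–200); metrics RMSE, R², calibration slope.
6. **Optimization** — EO or GLEO over a `[0,1]^D` encoding (12 feature
   flags > 0.5 ⇒ selected, 4 hyperparameter genes linearly mapped), fitness
   = inner-validation RMSE on the training subset, elitist equilibrium pool
   of the 4 best solutions + their mean, 100 iterations by default. Modes:
   feature selection (FS), hyperparameter tuning (HT), or joint (FS-HT),
   plus grid-search and untuned baselines.

A seeded synthetic generator (ramp–plateau–release torque with
amplitude- and spectrum-coupled band-limited MMG, plus a tabular generator
with known informative features) stands in for laboratory recordings and
gives every claim a testable ground truth.

## Worked example

```r
library(mmgtorque)

# a tabular dataset where only RMS, HighBand, LowerBand and SPFlx carry
# information about the target
ds <- make_feature_dataset(400, informative_idx = c(1, 2, 3, 5),
                           noise_sd = 0.1, seed = 2)

run <- run_optimizer(ds$table, algorithm = "GLEO", mode = "FS_HT",
                     n_pop = 5, max_iter = 5, seed = 3)
print(run)
#> <GLEO-RFR-FS-HT run> 5 iterations, best validation RMSE 0.0661
#>   selected features (4/12): RMS, HighBand, SPFlx, SPC
#>   config: Ntrees=852 mTrees=3 MinLeafSize=4 Nsplits=137
#>   test: RMSE=0.0748 R2=0.8447 slope=0.8333 (n=115)
```

In five iterations the run kept three of the four informative features
(dropping `LowerBand` for a spurious `SPC`), tuned the forest, and explains
~84% of held-out target variance; a calibration slope below 1 indicates the
usual mild compression towards the mean. Longer runs (the default is 100
iterations) recover the informative set more reliably, as the selection
tests show. `tidy(run)` returns the per-iteration best-fitness trace,
`glance(run)` a one-row summary, `ggplot2::autoplot(run)` the convergence
plot, and `plot_calibration(run, ds$table)` the measured-vs-predicted
scatter.

The full signal pipeline runs the same way from recordings:

```r
cfg <- synth_config(n_trials = 3, seed = 1)
man <- pipeline_simulate(cfg, "recordings")
ext <- pipeline_extract(file.path("recordings", man$files))
run <- pipeline_optimize(ext$table, algorithm = "GLEO", mode = "FS_HT",
                         n_pop = 6, max_iter = 8, seed = 1)
```

A thin command-line wrapper with `simulate` / `extract` / `optimize` /
`report` subcommands is installed at
`system.file("cli", "mmgtorque.R", package = "mmgtorque")`.

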