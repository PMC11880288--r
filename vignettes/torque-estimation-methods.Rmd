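---
title: "Methods: MMG-based torque estimation with equilibrium-optimizer model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MMG-based torque estimation with equilibrium-optimizer model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmgtorque)
```

## The estimation problem

Mechanomyography (MMG) records the lateral oscillation of muscle fibres with
a skin-mounted accelerometer; during neuromuscular electrical stimulation
(NMES) of the biceps brachii its amplitude and spectral content track the
evoked elbow-flexion torque. `mmgtorque` implements the full estimation
chain: zero-phase Butterworth filtering of synchronized MMG/torque
recordings, sliding-window extraction of twelve MMG features, normalization
and outlier censoring, a histogram-binned stratified train/test split, a
random-forest regression (RFR) torque model, and wrapper optimization of the
model with the Equilibrium Optimizer (EO) and its general-learning variant
(GLEO). The optimizer can select features (FS), tune the forest's four
hyperparameters (HT), or do both jointly (FS-HT).

## Signal conditioning

MMG is band-passed 5–100 Hz (the physiological MMG band) and torque
low-passed at 5 Hz, both with fourth-order Butterworth filters applied
forward and backward. Zero-phase filtering is deliberate: windowed features
must stay time-aligned with the torque target, and a causal filter would
shift the two channels differently. The forward-backward pass uses
odd-reflection edge padding (1000 samples) because slow filters ring for
hundreds of samples when started from zero initial conditions.

The first and last 6 s of every trial are trimmed before windowing; they
contain the torque development and relaxation transients, so a 30 s trial
contributes 18 s of quasi-steady data — at the default 100 ms windows with
50% overlap, exactly 359 windows.

## Features

Each 100 ms MMG window yields twelve features; the target is the RMS of the
filtered torque over the same window.

* Time domain: `RMS` (motor-unit activity), `ZCR` (strict sign changes per
  second; zeros inherit the previous sign), and Hjorth `Mobility`
  (`sqrt(var(diff)/var) * fs`, a dominant-frequency proxy).
* Spectral: all spectral features share one estimator — a Hann-tapered
  periodogram zero-padded to 256 points (~3.9 Hz grid at 1 kHz) and
  restricted to 5–100 Hz. `MPF` and `MDF` are the mean and median of the
  power spectrum; `SPC` and `SPsp` are the centroid and spread of the
  magnitude spectrum. Using power for MPF and magnitude for SPC is the
  conventional split, and it keeps the two features genuinely distinct.
  `SPFlt` is spectral flatness (geometric over arithmetic mean of power);
  `SPFlx` is the L2 distance between L1-normalized magnitude spectra of
  consecutive windows, so flux measures shape change while amplitude change
  is RMS's job; the first window of a trial gets flux 0.
* Band energies: fractions of 5–100 Hz power in the tremor (5–12 Hz),
  slow-twitch (12–40 Hz) and fast-twitch (40–100 Hz) bands. Being
  fractions, the three always sum to one. All-zero windows return 0 from
  every spectral operator rather than NaN.

## Normalization, censoring and the split

Features and target are pooled across trials, Z-scored, and any *row* with
|z| > 3 in any column is dropped — one aberrant feature marks the whole
window as artifactual. The survivors are min-max scaled to [0, 1]. Grey
relational analysis (distinguishing coefficient ζ = 0.5, the universal
default) provides a binned relevance profile of each feature against the
target.

The train/test split stratifies on the target: rows are binned into 50
half-open bins of width 0.02 (the last bin closed), and within every bin
round-half-up 70% go to training, remainder to test, seeded. Single-row
bins go to training. This equalizes the torque distribution between the two
subsets, which matters because the target distribution of a
ramp-plateau-release protocol is strongly bimodal.

## The forest and its hyperparameters

The RFR exposes four tunable hyperparameters:

| parameter | meaning | default | search range |
|---|---|---|---|
| `n_trees` | trees in the forest | 500 | 200–1500 |
| `m_trees` | predictors tried per split | 4 (one third of 12) | 1–12 |
| `min_leaf_size` | minimum leaf occupancy | 5 | 1–10 |
| `n_splits` | split cap per tree | unlimited | 100–200 |

The split cap is mapped to a terminal-node cap (`maxnodes = n_splits + 1`),
the binary-tree equivalence, because regression-forest libraries expose
leaf caps rather than split caps. The default search range for the cap is
narrow; it is deliberately config-overridable (`hp_ranges`) because useful
optima can lie far above it — with a few hundred training rows the cap
rarely binds at all. `m_trees` larger than the number of selected features
is clipped, not rejected, so the optimizer explores freely. One backend
quirk is documented in the tests: the forest always performs at least one
root split, so the fully degenerate single-leaf tree is approximated by a
two-leaf tree.

Metrics are RMSE, R² (`1 − SS_res/SS_tot`), and the calibration slope — the
OLS slope of predicted on measured torque, 1 for unbiased calibration.

## EO and GLEO

Solutions are vectors in `[0,1]^D`: 12 feature flags (selected iff the gene
is strictly greater than 0.5), 4 hyperparameter genes (linearly mapped and
rounded onto their integer ranges), or both (D = 16). The equilibrium pool
holds the four best solutions *ever seen* plus their elementwise mean. The
elitist (memory) pool, rather than a per-iteration pool, guarantees the
non-increasing best-fitness traces the convergence plots rely on.

Each iteration every solution `C` relaxes towards a pool candidate `Ceq`
with the canonical update (constants a1 = 2, a2 = 1, GP = 0.5, V = 1):

```
t   = (1 - iter/max_iter)^(a2 * iter/max_iter)
F   = a1 * sign(r - 0.5) * (exp(-lambda * t) - 1)
GCP = 0.5 * r1  if r2 >= GP  else 0
G   = GCP * (Ceq - lambda * C) * F
C'  = Ceq + (C - Ceq) * F + G/(lambda * V) * (1 - F)
```

with `lambda`, `r` uniform per dimension and `r1`, `r2` uniform per
solution, positions clipped to [0, 1]. At the final iteration `t = 0`
forces `F = G = 0`, so the update collapses exactly onto the pool — full
exploitation. The RNG draw order (pool index, λ, r, r1, r2) is fixed and
documented so an independent oracle can replay an update bit-for-bit.

GLEO replaces the single pool candidate by a per-solution, per-dimension
*exemplar*: with probability `Pl_i` a dimension's gene comes from the
winner of a two-way tournament between two distinct random population
members, otherwise from a random pool candidate; if no dimension drew a
tournament gene one is forced, so every exemplar carries peer information.
The learning probabilities follow the exponential comprehensive-learning
ramp `Pl_i = 0.05 + 0.45 * (exp(10(i-1)/(N-1)) - 1)/(e^10 - 1)`: early
solutions exploit the pool, late ones learn broadly. The published
description of the general-learning strategy is qualitative; this
per-dimension tournament construction is our interpretation of its cited
source, and is validated behaviourally (it must match EO distributionally
when the ramp degenerates, and it must not lose elitism).

**Fitness.** A candidate is decoded, its forest trained on a run-fixed
inner 80/20 split of the *training* subset, and the inner-validation RMSE
returned. Raw training RMSE would reward overfitting and make feature
selection meaningless; a run-fixed inner split keeps fitness deterministic
given the candidate. An empty feature mask returns a penalty of 1e9 rather
than being repaired — simple, and it preserves the search dynamics.
Population size defaults to N = 10.

A grid-search baseline (`grid_search_ht()`) evaluates a Cartesian grid with
exactly the same fitness, and `baseline_rfr()` provides the untuned
default-configuration row the optimized modes are compared against.

## The synthetic generator

No public NMES-MMG/torque corpus accompanies this problem, so the package
ships a seeded generator used by every end-to-end test.

* **Torque** is a smooth trapezoid: raised-cosine 6 s rise and release
  (matching the trimming convention) around a plateau at `torque_max`
  (default 8 N·m, a realistic evoked elbow-flexion torque at modest
  stimulation). The plateau carries a slow (< 0.5 Hz, 8% sd)
  potentiation/fatigue drift plus a smaller (< 1 Hz, 2%) jitter — sustained
  stimulation trains do not hold torque constant, and a perfectly flat
  plateau would make the within-plateau torque ranking pure noise, which no
  amplitude-coupled signal could track.
* **MMG** is a sum of three band-limited Gaussian components (5–12, 12–40,
  40–100 Hz). The carrier is normalized by its own local (< 12 Hz) RMS so
  that the instantaneous standard deviation *equals* the envelope
  `noise_sd * (1 + coupling_gain * torque/torque_max)` — that equality is
  the generator's contract; without the normalization the windowed RMS of a
  Gaussian carrier wanders around the envelope with ~20% estimator noise at
  100 ms windows. The 40–100 Hz component's weight grows with torque as
  `1 + spectral_shift_gain * torque/torque_max`, shifting spectral mass
  upward at high effort, as fast-twitch recruitment does.
* Defaults: `coupling_gain = 2` and `spectral_shift_gain = 1` give the
  strong but imperfect feature-torque coupling typical of evoked
  recordings; `noise_sd = 0.02` (accelerometer units) is arbitrary since
  every downstream step is scale-free after normalization.
* **Graded trials.** `pipeline_simulate()` simulates its trials at evenly
  spaced plateau levels (default 1/3 to 1 of `torque_max`), with the MMG
  coupling always referenced to absolute torque. This emulates pooling
  recordings across stimulation intensities and joint configurations, and
  it is what makes the pooled feature table span the full torque scale —
  trials at a single level would leave only the within-plateau drift to
  predict.

The generator targets *statistical*, not morphological, fidelity: no
twitch shapes, no stimulation artifacts, no inter-subject variability, one
informative axis. Passing tests therefore demonstrate that the pipeline
recovers known structure under realistic coupling and noise — not that it
reproduces any particular laboratory's numbers.

The tabular generator (`make_feature_dataset()`) bypasses the signal layer:
12 named feature columns of which only a chosen subset drives the target
(weighted monotone transforms plus one interaction, additive Gaussian
noise, min-max scaled), the rest independent noise. The first listed
informative index receives the largest weight, so placing `RMS` first makes
it the dominant predictor — giving selection tests an unambiguous
ground truth.

## Problem sizes and numerical choices

The test and acceptance workloads are scaled for a single desk-class CPU:
sphere benchmark at dimension 16, N = 10, 100 iterations over 20 seeds;
selection recovery on 2000-row tables with a 60-tree fitness forest, N = 6,
12 iterations over 10 seeds; mode-ordering comparisons on 300-row tables
with N = 5, 5 iterations over 10–20 paired seeds. These budgets are small
against the defaults (N = 10, 100 iterations) but large enough that every
qualitative claim — recovery, elitism, FS-HT ≤ HT ≤ default, GLEO ≤ EO —
is decided by the method rather than by chance, as the paired-seed design
keeps the comparisons exact.

Other numerical choices: bin ties at bin edges go to the lower half-open
bin; per-bin train counts use round-half-up with the remainder to test;
degenerate single-row bins go to training; zero-power spectra floor their
bins at machine-epsilon scale before the flatness logarithm; the grey
relational degree of identical series is defined as 1 even though the
formula is 0/0 there.

## Limitations

* Synthetic validation only: the generator defines the study conditions,
  and real NMES-MMG adds crosstalk, electrode artifacts, inter-subject
  anatomy and fatigue dynamics the generator does not emulate.
* The pooled normalization (across trials before splitting) is a
  documented choice; per-subject normalization would change the censoring
  geometry.
* The forest backend's root-split floor means extreme `min_leaf_size`
  configurations are approximated, not exact.
* EO/GLEO are stochastic; all guarantees in the test suite are elitism
  (deterministic) or median-over-seeds claims, not per-run bounds.
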