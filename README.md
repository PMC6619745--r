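# cmjfatigue

Monitoring athlete fatigue from countermovement-jump (CMJ) force-plate
recordings, for sport scientists and biostatisticians working with
repeated-measures training studies.

After a training session, force-generating capacity is depressed by two
processes with different time courses: **metabolic fatigue**, which largely
dissipates within ~3 h, and **neuromuscular fatigue**, which can persist for
48 h or more. This package implements an analysis chain that separates the
two from CMJ force-time signatures recorded before a session and at 0, 0.5,
1, 3, 6, 24 and 48 h afterwards:

* **Concentric-phase extraction** from raw vertical ground-reaction-force
  traces (impulse–momentum integration, velocity zero-crossing onset,
  takeoff detection) and four scalar features per jump: peak force and peak
  power relative to bodyweight (relPeakF, relPeakP), concentric duration,
  and time to peak force.
* **Stratified PCA**: the 4 features × 8 measurement occasions = 32-variable
  matrix (one row per jump repetition, paired by order across occasions),
  centred and scaled, decomposed with `stats::prcomp`.
* **Multivariate functional PCA** of the concentric force curves: penalised
  cubic b-spline smoothing (roughness penalty `λ∫(f″)²`, GCV-selected),
  joint eigendecomposition over the eight occasions under the concatenated
  L² inner product, and Ward clustering of per-occasion score
  contributions.
* **Random-intercept mixed models** (profiled maximum likelihood, written
  for this package and oracle-tested) predicting relPeakF at 6 h and 48 h
  from PC1/PC2 scores, with leave-one-athlete-out cross-validation, R², and
  likelihood-ratio comparisons across eight model configurations
  (horizon × score source × baseline/practical information window). The
  model for a new athlete is

  y<sub>ij</sub> = β₀ + β₁·PC1<sub>ij</sub> + β₂·PC2<sub>ij</sub> + b<sub>i</sub> + ε<sub>ij</sub>,  b<sub>i</sub> ~ N(0, σ²_b), ε ~ N(0, σ²_e).

* **A seeded synthetic-cohort generator** (10 athletes × 3 workloads ×
  8 occasions × 5 jumps at 600 Hz) with a two-compartment fatigue model —
  exponential metabolic decay plus an alpha-function neuromuscular
  component — athlete random baselines, athlete-specific susceptibilities,
  and jump-level noise, so the whole chain runs and is tested without any
  participant data.

## Worked example

```r
library(cmjfatigue)

study    <- simulate_study(seed = 42)          # 1200 force traces
features <- extract_study_features(study)      # long feature table
pca      <- run_pca(build_feature_matrix(features))
curves   <- study_curves(study)                # time-normalised curves
fpca     <- run_fpca(curves)
report   <- run_fatigue_models(features, curves)
```

`print(pca)` shows how much of the feature variance the leading components
carry (here the athlete-identity plane dominates):

```
Stratified PCA: 150 samples, 32 variables
Proportion of variance (first 6 PCs): 81.0  4.1  1.8  1.5  1.4  1.3 %
Cumulative: 81.0 85.0 86.8 88.4 89.8 91.1 %
```

Clustering the per-occasion fPCA scores recovers the planted fatigue
physiology — the 3-cluster cut groups the pre/early occasions (metabolic
window) apart from 24 h and 48 h (neuromuscular window):

```r
cluster_scores(fpca, pc = 2)$time_clusters
#> PRE   0 0.5   1   3   6  24  48
#>   1   1   1   1   1   2   3   3
```

`print(report)` gives the model-fit and model-comparison summary; the practical
models (scores from pre, 0 and 0.5 h only — what a coach can actually
collect before the athlete leaves) trail the full-information baselines
only slightly in cross-validated MSE:

```
                name mse_cv    r2 loglik
   6 h fPCA Baseline  0.002 0.968  251.0
  6 h fPCA Practical  0.014 0.947  196.7
 48 h fPCA Baseline   0.002 0.970  249.1
 48 h fPCA Practical  0.010 0.949  191.2
...
```

An MSE of 0.014 in squared bodyweight multiples means the 6-h relPeakF of
an unseen athlete is predicted to about ±0.12 BW from half an hour of
post-session jumps, with the athlete random intercept absorbing stable
between-athlete differences.

`reproduce_study(seed, out_dir)` runs the whole chain at study scale and
writes all tables plus a reproducibility manifest;
`reproduce_from_deposit(path, mapping)` adapts an externally deposited feature
table via a configurable column mapping, and reports the analysis as not
evaluable if the file holds only session-level summaries.

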