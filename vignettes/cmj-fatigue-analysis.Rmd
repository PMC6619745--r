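---
title: "Distinguishing metabolic from neuromuscular fatigue in countermovement-jump force signatures"
author: "cmjfatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing metabolic from neuromuscular fatigue in countermovement-jump force signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmjfatigue)
```

## The monitoring problem

After a training session an athlete's capacity to produce force is reduced by
two overlapping processes. *Metabolic* fatigue — force loss from exercise that
outstrips ATP resynthesis — begins to resolve within minutes and has largely
dissipated by about 3 h. *Neuromuscular* fatigue — a prolonged decrement with
central and peripheral components — can persist for 48 h or more. Coaches who
plan a second session 6 h later, or the next session after a weekend, need to
anticipate each component separately.

The countermovement jump (CMJ) on a force plate is the field's standard
non-invasive probe of lower-body neuromuscular function. This package
implements a complete analysis chain for CMJ-based fatigue monitoring in a
repeated-measures design — athletes tested before a session and at 0, 0.5, 1,
3, 6, 24 and 48 h afterwards, with a set of five jumps at each occasion and
three session workloads (low/moderate/high):

1. **Signal processing** — from the raw 600 Hz vertical ground-reaction-force
   trace to the concentric phase and four scalar features.
2. **Stratified PCA** — the four features stratified by the eight measurement
   occasions (32 variables) with centred, unit-variance PCA.
3. **Multivariate functional PCA** — penalised b-spline smoothing of the
   concentric force curves and a joint eigendecomposition across the eight
   occasions, plus hierarchical clustering of the per-occasion scores.
4. **Prediction** — random-intercept linear mixed models that forecast
   relative peak force at 6 h (metabolic window) and 48 h (neuromuscular
   window) from PC1/PC2 scores, cross-validated by leaving one athlete out.
5. **A seeded synthetic-cohort generator** that emulates the study design, so
   the whole chain is testable without access to any participant data.

## Signal processing

A trial is expected to begin with quiet standing. Bodyweight is the mean
force over the initial window (default 0.5 s); the window's standard
deviation guards against drift (error above `max(10 N, 2% of BW)`). Velocity
and displacement come from impulse–momentum integration,
$a(t) = F(t)/m - g$ with $g = 9.81\,\mathrm{m\,s^{-2}}$, by cumulative
trapezoids from rest; power is $F(t)\,v(t)$. No filtering is applied by
default: at 600 Hz with modern plates the trapezoid error is far below the
feature tolerances, and any low-pass step would have to be documented as a
methodological choice of its own.

The concentric phase is the portion of the jump before takeoff in which the
change in displacement is positive. Its onset is located at the last upward
zero-crossing of velocity before takeoff — the moment the centre of mass
reverses direction. The frequently quoted "force about 10% below standing
bodyweight" landmark is treated as a descriptive approximation and used only
as a fallback for pathological traces with no real countermovement (velocity
never below 0.05 m/s); such segments carry a `fallback` flag. Takeoff is the
first sample after the propulsion peak below `max(10 N, 2% of BW)`; the peak
itself is searched only before the first sub-threshold sample so that a
landing impact can never masquerade as propulsion. Segments are half-open
`[onset, takeoff)`, ties in maxima resolve to the earliest sample, and the
four features are

* `rel_peak_force` — peak concentric force / bodyweight (unitless),
* `rel_peak_power` — peak concentric power / body mass (W/kg),
* `t_con` — concentric duration (s),
* `t_peak_force` — onset to peak force (s).

`count_propulsion_peaks()` counts force maxima above bodyweight with
topographic prominence of at least 5% of bodyweight, flagging the
double-peak technique artefact.

## Stratified PCA

`build_feature_matrix()` spreads the long feature table into samples x
(feature x occasion) columns. The sample unit is the *jump repetition paired
by order* — jump k before training is matched with jump k at every later
occasion — because 10 athletes x 3 workloads x 5 jumps = 150 samples is the
only pairing consistent with per-jump analysis of this design;
`pairing = "session_mean"` (30 rows) is available as an option. Rows missing
any cell are dropped and counted; there is no imputation. `run_pca()`
centres and scales every column (a correlation-structure PCA via
`stats::prcomp`) and fixes each eigenvector's sign so its largest-magnitude
loading is positive — eigenvector signs are otherwise arbitrary and would
flip between runs.

On cohorts of this shape the PC1–PC2 plane is dominated by athlete identity
(who you are explains more than what you did), which `capability_map()`
summarises as per-group centroids and dispersions for squad-level profiling.
Workload separation is a *relative* statement: the share of variance on a
standardised PC pair attributable to workload within athlete is higher on
the later fatigue axes than on PC1–PC2, not larger in raw score units — raw
units on PC1 dwarf everything else by construction.

## Functional PCA

Each concentric curve is linearly rescaled to $[0,1]$ (duration kept as
metadata) and interpolated onto a common grid (default 101 points). Curves
are expressed in bodyweight multiples so that body-mass differences do not
masquerade as curve-shape variance. Each curve is expanded in a cubic
b-spline basis (default 20 basis functions, equally spaced interior knots)
by penalised least squares,
$\min_c \|y - Bc\|^2 + \lambda \int (c^\top B'')^2,$
with the curvature penalty assembled exactly (Simpson per knot interval —
the second derivative of a cubic spline is piecewise linear) and the Gram
matrix by 4-point Gauss–Legendre per interval (exact for the degree-6
integrand). $\lambda$ is chosen by generalised cross-validation per curve,
and the median of the per-curve minimisers is applied to all curves so every
sample carries the same amount of smoothing.

The eight occasion curves of one sample form one observation of a
*multivariate* functional datum. The concatenated, centred coefficient
vectors are whitened slot-wise with $G^{1/2}$ and decomposed by SVD, which
is the eigendecomposition of the sample covariance under the concatenated
$L^2$ inner product (block-diagonal Gram). Components are therefore vectors
of eight eigenfunctions; orthonormality holds under that inner product
(verified to 1e-6 in the tests), and with an interpolating basis and zero
penalty the explained proportions coincide with discrete PCA of the gridded
values (the package's oracle equivalence test). Signs are fixed so the
integral of a component's mean slot function is positive.

`fpca_slot_scores()` restricts each sample's score to one occasion (the
slot-wise inner product; rows sum to the total score), and
`cluster_scores()` applies agglomerative clustering (Euclidean distance,
Ward linkage by default) to those per-occasion columns and to the samples.
A useful identity: adding a constant to every column (an athlete-baseline
offset carried by a component) cancels in between-column distances, so even
a baseline-dominated component clusters occasions by their fatigue time
course. On the default synthetic cohort, a 3-cluster cut of either of the
two leading components separates {pre, 0, 0.5, 1 h} from {24, 48 h} — the
early/metabolic window against the late/neuromuscular window, with {3, 6 h}
in between — in well over 70% of replicates.

## Mixed-effects prediction

Relative peak force at 6 h and at 48 h is regressed on PC1 and PC2 scores
with a random intercept per athlete:
$y_{ij} = \beta_0 + \beta_1 \mathrm{PC1}_{ij} + \beta_2 \mathrm{PC2}_{ij} + b_i + \varepsilon_{ij}$,
$b_i \sim N(0, \sigma^2_b)$, $\varepsilon \sim N(0, \sigma^2_e)$,
estimated by maximum likelihood (not REML, so that likelihood-ratio
comparisons across fixed-effect sets are meaningful). `fit_lme()` profiles
the likelihood over the variance ratio $\lambda = \sigma^2_b/\sigma^2_e$:
for fixed $\lambda$ the GLS fixed effects and $\hat\sigma^2_e$ are closed
form (the grouped Woodbury identity makes each evaluation O(n)), and the
one-dimensional profile is maximised over $\log\lambda$ with an explicit
check of the $\lambda = 0$ boundary (where the fit is ordinary least
squares). The tests pin this optimiser against a brute-force grid over
$(\sigma^2_b, \sigma^2_e)$ and against an independent mixed-model
implementation.

Eight model configurations are fitted: each horizon (6 h, 48 h) by each
score source (PCA, fPCA) by each information window. *Baseline* windows use
all eight occasions; *practical* windows use only pre, 0 and 0.5 h — the
measurements actually obtainable before the athlete leaves the facility.
Practical-window scores are recomputed by running PCA (12 variables) or
fPCA (3 slots) on the restricted window, never by projecting onto
full-window components: the configuration qualifies the PC computation
itself.

Validation is leave-one-athlete-out: the held-out athlete's responses are
predicted from fixed effects only, since an unseen athlete has no estimable
intercept, and squared errors are pooled. $R^2$ is reported as the squared
Pearson correlation between observed responses and fitted values
conditional on the predicted random intercepts (the definition is stated
because several inequivalent mixed-model $R^2$s are in circulation;
marginal and conditional pseudo-$R^2$ appear in `summary()` for
transparency). Likelihood-ratio statistics are $2|\Delta\ell|$ with
$\chi^2$ reference on the difference in fixed-effect counts; for same-size
non-nested pairs (fPCA vs PCA) the raw LR is reported with an `NA` p-value
and an explicit non-nested warning rather than an invented reference
distribution.

## The synthetic cohort

The generator produces what the analysis assumes and nothing more. Its
fatigue model is a two-compartment relative decrement
$$D(t) = d_w\left[\alpha\, m_i\, e^{-t/\tau_m} + (1-\alpha)\, n_i\,
\frac{t}{\tau_p} e^{1 - t/\tau_p}\right],$$
zero at the pre-training baseline by definition. Defaults, chosen once for
the package's study conditions:

| parameter | default | meaning |
|---|---|---|
| `d_w` | 0.05 / 0.10 / 0.15 | decrement scale for low/moderate/high workload |
| `alpha` | 0.45 | metabolic fraction |
| `tau_m` | 1 h | metabolic decay constant (≈95% dissipated by 3 h) |
| `tau_p` | 30 h | neuromuscular peak time (≈equal burden at 24 h and 48 h, persisting past 48 h) |
| `m_i, n_i` | lognormal, SD 0.2 / 1.0 | athlete susceptibility multipliers |
| baseline | 2.3 BW, SD 0.15 | un-fatigued relative peak force |
| jump noise | 0.05 BW | jump-to-jump peak variability |
| plate noise | 4 N | white measurement noise |
| `kappa` | 0.5 | concentric-time dilation per unit decrement |

Two of these deserve their rationale spelled out. `tau_p = 30` places the
neuromuscular nadir between the 24 h and 48 h occasions, giving the two
late measurements nearly equal fatigue burden — consistent with
delayed-onset force loss that is still fully present at 48 h. The
susceptibility SDs are deliberately asymmetric: the immediate metabolic
response is fairly uniform across trained humans, while the prolonged
response is notoriously variable between individuals ("responders" versus
"non-responders"). Both choices matter statistically: with a common
susceptibility spread the metabolic and neuromuscular coefficient vectors
are nearly collinear across samples (both scale with baseline x `d_w`), no
principal component isolates the late time course, and the occasion
clustering that motivates the whole analysis cannot emerge. Heterogeneous
prolonged susceptibility decorrelates the compartments, which is exactly
the structure the stratified analyses are designed to detect.

Traces are built directly in force space:
$F(t) = BW\,(1 - \mathrm{dip}(t) + A\,p(t))\,w(t)$ — quiet standing
(0.8 s), a Gaussian unweighting dip below bodyweight, a Gaussian propulsion
pulse whose amplitude $A$ is calibrated iteratively so the peak force
equals the athlete's target exactly, and a smooth cosine decay to zero at
takeoff, followed by a zero-force flight of duration $2 v_{to}/g$ and a
landing transient. Building force directly (rather than prescribing
kinematics) guarantees realistic anatomy while leaving the integration
pipeline something non-trivial to do; the flight phase is generated from
the simulator's own integrated takeoff velocity, which is why jump height
from $v^2/2g$ and from $g t_f^2/8$ agree to within 2% and serve as an
internal consistency check. The unweighting dip attenuates with fatigue and
with low force reserve — athletes counter-move less aggressively when they
cannot generate force above bodyweight — without which deep decrements
produce traces with no physical takeoff. The double-peak artefact is a
narrow Gaussian notch carved into the propulsion pulse (Bernoulli per jump,
athlete-specific propensity): a genuine two-Gaussian mixture narrow enough
to show two peaks 80 ms apart would also remove most of the propulsion
impulse, whereas the notch keeps the impulse and yields two prominent peaks
~90 ms apart. Fatigue also dilates all movement durations by
$1 + \kappa D$, so the time features respond to fatigue as well as the
force features. The modelled decrement is capped at 0.35 — larger
peak-force losses are not observed after repeated-sprint training and leave
no viable jump.

All randomness flows from one integer seed; per-trial substreams are
derived deterministically, so a study is byte-reproducible. A fast path,
`simulate_features()`, draws the four features directly from the same
athlete/fatigue model for statistical Monte-Carlo work; there, athlete
traits load on a common athletic-ability factor so that athlete identity
spans few feature-space dimensions, as in real squads.

**What the generator does not emulate:** arm-swing and bar-load effects,
bilateral asymmetry, eccentric-phase realism beyond what phase detection
needs, inter-session learning or pacing effects, and any physiological
marker outside the force trace. Passing tests on this cohort therefore
demonstrate that the *machinery* recovers planted structure of realistic
shape and size — not that any particular real squad will show it.

## Numerical choices and degenerate inputs

* Integration: cumulative trapezoids; features change by <0.5% when the
  sample rate doubles (peak *times* are additionally subject to ±dt/2
  argmax quantisation).
* Penalised smoothing: closed-form solve of $(B^\top B + \lambda P)$;
  a singular system reports "try a lower n_basis".
* GCV on pure noise selects the largest penalties in the modal case; on
  noise-free in-span curves it selects the grid minimum.
* PCA: constant columns are an error naming the column; permutation of
  rows and pre-standardisation are no-ops (tested).
* fPCA on identical samples: zero total variance is flagged
  (`degenerate = TRUE`, proportions `NA`) rather than silently normalised.
* LME: one observation per group flags non-identifiability; rank-deficient
  designs error; a perfectly fitted (noise-free) response is handled by
  flooring $\hat\sigma^2_e$ inside the log only.
* The `PRE` occasion is a category, never a negative hour in arithmetic.
* Problem sizes in the shipped tests: the default cohort (1200 traces) is
  simulated once and shared across tests; Monte-Carlo properties use 50
  replicates at full scale for the clustering and workload-share checks,
  200 replicates for Wald coverage, and reduced designs elsewhere. A full
  `reproduce_study()` takes well under a minute on a single core.

## Known limitations

* The LOOCV unit is the athlete; observation-level LOOCV is not offered.
* No curve registration beyond linear time rescaling; landmark alignment
  of the propulsion peak would change the fPCA decomposition.
* The LRT between non-nested equal-size models is descriptive only.
* The practical/baseline comparison assumes the horizon measurement exists
  for every sample; partially missing horizons drop samples rather than
  being imputed.
* Session-level deposited summaries cannot support the jump-level sample
  unit; the deposited-data adapter reports such files as not evaluable instead of
  silently switching designs.
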