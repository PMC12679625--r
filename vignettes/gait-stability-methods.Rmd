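---
title: "Lyapunov–Floquet gait stability: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lyapunov-Floquet gait stability: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitlf)
```

## The dynamical model

`gaitlf` treats the medio-lateral (M/L) sway of the centre of mass (CoM)
relative to the centre of pressure (CoP) during walking as a periodically
forced oscillator: standing still is the equilibrium, each step delivers a
lateral push, and walking is a limit cycle around the equilibrium. Stability
of that limit cycle is what separates a gait that absorbs perturbations from
one that amplifies them.

Two surrogate signals stand in for quantities that would otherwise need
force plates or a full-body model:

* **CoM surrogate** — per-frame mean of the four pelvis markers (RPSI,
  LPSI, RASI, LASI) along the M/L axis. The pelvis centroid tracks the
  body's CoM closely in the frontal plane.
* **CoP surrogate** — per-frame mean of the two heel markers (RHEE, LHEE).

The analysed signal is `y(t) = CoM_ML(t) − CoP_ML(t)`. Per trial the
boundary strides are trimmed (gait initiation/termination), the trial mean
is subtracted, the trials are concatenated, and the stitched record is
low-pass filtered, giving `Y(t)`. The phase state is `m(t) = [Y, dY/dt]`
and the delay embedding `M(t) = [m(t), m(t+τ), …, m(t+nτ)]`.

Three stability metrics are computed per participant:

| metric | definition | stable when |
|---|---|---|
| mean FM | mean modulus of the eigenvalues of the one-stride monodromy matrix Φ(T) | all \|FM\| ≤ 1 |
| max LE_L | largest real part of the Floquet exponents log(FM)/T (1/s) | ≤ 0 |
| max LE_S | slope of the Rosenstein mean-log-divergence curve over half a gait cycle (1/s) | ≤ 0 |

Both stability criteria are inclusive at the boundary.

## Pipeline order and its assumptions

The per-trial order is fixed: surrogates → events → trim → mean-normalize →
stitch → filter → differentiate → embed → estimate. Two points deserve
comment.

* **Trim before normalize.** The trial mean is computed after the
  initiation/termination strides are removed, so transients cannot bias the
  normalization. `trim_strides` (default 2 per end) is configurable.
* **Stitching.** Concatenating short overground trials creates artificial
  junctions. No blending is applied; instead every junction index is carried
  through the pipeline and *all* neighbour searches, divergence horizons and
  stride-pair selections exclude windows that span a junction. Stitched-data
  Lyapunov analysis is an accepted practice for short walkway protocols
  provided the junctions are masked this way.

Gait events are detected kinematically: the heel strike is the positive
peak of the heel marker's antero-posterior position relative to the pelvis
centroid — the heel is maximally ahead of the advancing pelvis at foot
contact. Parameters: `events$min_stride_s` (default 1 s, the shortest
credible stride for the target populations) and `events$prominence_m`
(default 0.05 m, about a tenth of a typical step length). Cadence is the
merged step count over elapsed time; the stride period `T` is the median of
same-side strike intervals. A constant (standing) record produces no peaks
and a typed insufficient-data error.

## The monodromy estimator

The monodromy matrix maps deviations from the limit cycle across one
period: `δ(t+T) = Φ δ(t)` on a Poincaré section at a fixed gait phase. With
anchors at the left heel strikes, the textbook `Φ = M(T) M(0)⁻¹` is
under-determined in practice (one noisy pair per stride), so the estimator
makes three documented extensions, each of which reduces to the textbook
form in the ideal case:

1. **Pooled least squares.** All stride-separated state pairs enter a
   Frobenius-norm fit `min ‖D_T − Φ D_0‖`, solved by SVD pseudo-inverse.
   With exactly d independent anchors this *is* `M(T) M(0)⁻¹`.
2. **Per-section centring, multiple sections.** States on each section are
   centred on their own section mean (the local limit-cycle point), making
   the fit exact for any affine stride-to-stride map. Because ~20 strides
   yield only ~20 pairs, sections at `lf$n_phases` (default 24) evenly
   spaced phase offsets are pooled. For linearized time-invariant sway
   dynamics the one-period propagator is the same at every phase, so
   pooling multiplies the data without biasing the spectrum; estimating
   multipliers at several section phases has long precedent in orbital
   stability analysis of gait.
3. **Energy truncation.** The fit is restricted to the leading principal
   directions of the pooled deviations holding `lf$energy` (default 0.99)
   of the variance, at least two — the rank truncation familiar from
   subspace identification and dynamic-mode decomposition. Delayed copies
   of a smooth planar signal are strongly collinear; the trailing
   directions carry mostly observation noise and would contribute spurious
   multipliers.

Numerical guards: the first and last record samples (one-sided derivative
estimates) are excluded from sections; the condition number of the retained
deviation matrix must stay below `lf$cond_max` (default 1e8) or a typed
ill-conditioning error explains that the stride-to-stride deviations do not
span the space; a multiplier within 1e-10 of the negative real axis sets a
branch-cut flag (the principal logarithm is discontinuous there) rather
than being silently resolved. Floquet exponents are computed as principal
logarithms of the eigenvalues divided by T — identical to the eigenvalues
of the principal matrix logarithm whenever Φ is diagonalizable, which holds
for every non-defective estimate.

**Which state the monodromy sees.** The fit runs on the planar section
state `[Y, Ẏ]` (`lf$embed_n = 0`), not on the full delay embedding. On a
stride-anchored section the cycle phase is pinned by the section itself, so
the planar state spans the transverse dynamics of the sway model, while
every added delay block squares the number of fit parameters resting on ~20
stride pairs and adds noise-dominated directions. The Rosenstein estimator,
whose neighbour searches need a fully unfolded attractor, runs on the
optimized delay embedding instead (`embed$tau`, `embed$n`, both `auto` by
default). This split is the package's own design choice; both embeddings are
configurable if a user wants the single-representation variant.

## Delay and dimension selection

* **Delay** — first local minimum of the average mutual information
  (equiprobable binning, `⌈√L⌉` bins). Binned AMI estimates jitter from lag
  to lag, so the curve is smoothed with a 5-point moving average before the
  minimum search, and lags below 3 samples are not selectable (at 120 Hz
  they carry no phase-space information). If no minimum exists in range,
  the fallback is the first lag where the autocorrelation drops below
  1 − 1/e. A caveat worth knowing: for a *noiseless* pure sinusoid the
  relation between the signal and any lagged copy is deterministic, the
  binned AMI curve is nearly flat, and no estimator of this family places a
  meaningful first minimum at the quarter period; with realistic noise the
  selected delay lands in the physically sensible range (about a quarter of
  the dominant period for sway, ~0.15 s for the Lorenz benchmark, matching
  published practice).
* **Dimension** — smallest n whose false-nearest-neighbour fraction falls
  below `embed$fnn_threshold` (default 5%), with distance-ratio threshold
  15, an attractor-size check, and a Theiler exclusion of one stride period
  so temporally adjacent states are never counted as neighbours. Exact
  recurrences (strictly periodic signals) are counted as true neighbours
  unless the added coordinates separate them.

## The Rosenstein short-term exponent

For each reference state the nearest neighbour outside the Theiler window
(`rosenstein$theiler_strides`, default 1 stride) and inside the same trial
segment is tracked for one stride; `max_LE_S` is the least-squares slope of
⟨ln d(t)⟩ over `[0, 0.5 T]` — half a gait cycle, the window with
demonstrated validity as a fall-risk proxy. The slope is reported in 1/s
with a stride-normalized copy (× T). Reference points are capped at
`rosenstein$max_refs` (default 1000, deterministic even subsample); a fit
with R² < 0.5 sets a low-quality flag and warning. For continuous chaotic
benchmarks the first pseudo-period of the curve is an orientation transient,
so the Lorenz validation fits the linear region `[T, 3T]` with T = 0.75 s
(the attractor's mean orbital period) through the explicit `fit_window`
argument; gait analyses keep `[0, 0.5 T]`.

## What the generators emulate — and what they do not

`simulate_linear_oscillator` integrates `ẍ = −ω²x − 2ζωẋ + u(t)` exactly
(per-sample matrix exponential, zero-order-hold input), with `u(t)` a 0.2 s
half-sine force pulse once per stride — the continuous lateral push of a
step. Because forcing enters additively, the one-period deviation
propagator is `exp(AT)` independent of the pulse shape, so the labels
`|FM| = exp(−ζωT)` and `max LE_L = −ζω` are exact. An earlier design used
instantaneous velocity kicks; the discontinuity interacted with central
differencing and zero-phase filtering to produce stride-varying state
errors, and the smooth pulse is both numerically cleaner and physically
right. With `kick_cv = 0` (the default) the orbit is strictly noise-free
and recovery is exact to finite-differencing error; `kick_cv > 0` adds
stride-to-stride pulse variability (process noise), which is the
excitation that real gait offers the estimator and the configuration used
for cohort realism (`cohort_spec` and the marker generator default to 0.2,
i.e. sway variability of the order seen in older adults). The neutrally
stable ζ = 0 orbit has no decaying transient at all, so its validation run
uses the variability-driven configuration.

`simulate_marker_gait` wraps the oscillator in a six-marker geometry:
pelvis markers = sway + fixed symmetric offsets (their mean recovers the
sway exactly), heels at constant symmetric M/L offsets (CoP surrogate
exactly zero) advancing antero-posteriorly in alternating
stance-hold/swing-advance steps so that coordinate-based detection finds
heel strikes at the construction times. One amplitude scale per participant
is derived from the noiseless reference orbit — per-trial rescaling would
randomize the limit-cycle amplitude across trials and contaminate the
pooled sections. Trial structure mirrors short-walkway protocols: 5 trials
of 8 strides at 120 Hz; trimming 2 strides per end leaves 4 × 5 = 20
analyzable strides, matching the ~19 such studies report. Observation noise
is additive Gaussian on every marker coordinate (default SD 2 mm, typical
optical-capture error).

What the generators deliberately do **not** emulate: anthropometric
geometry beyond fixed offsets, vertical/anterior CoM dynamics, step-width
modulation, ground-reaction forces, marker occlusion patterns, or any
nonlinearity in the sway dynamics. Passing tests therefore demonstrate that
the estimators recover known linear(ized) stability structure under
realistic sampling, trial lengths and noise — not that clinical effect
sizes would reproduce on real recordings.

`simulate_cohort` draws two groups whose structure mirrors a published
PSP-vs-control demographic table: Control cadence 55 ± 4 vs PSP 50 ± 5
steps/min, ages 64 ± 10 vs 71 ± 7 years (truncated to [50, 95], which
lifts the Control mean slightly), group damping ratios centred so the
closed-form |FM| sits near 0.68 (Control) and 0.79 (PSP). Control damping
degrades with age (so the post-hoc age regressions have structure to find)
while PSP damping and the synthetic severity scores (PSPRS 35 ± 12,
gait-midline subscore 10 ± 4) are drawn independently of the dynamics —
encoding the observed *absence* of metric–severity correlation.
`simulate_metrics_cohort` draws the three metrics directly from the
published group statistics (mean FM 0.68/0.79 with common SD 0.16;
max LE_L −0.3/−0.17; max LE_S 2.58/2.6) for statistics-layer studies where
running 60 marker-level pipelines per replicate would be pointless compute.

## The statistical layer

Welch t-tests on demographics; per-metric ANCOVA `metric ~ group + sex +
age + cadence` with Type-II F tests (order-invariant for this design);
Anderson–Darling on residuals and median-centred Levene across groups
attached as diagnostics — reported with warnings, never used to gate
results, since the modelled study reports no remedial action. Post-hoc
per-group regressions run exactly for the continuous covariates whose
ANCOVA p < 0.05 (a pure function of the ANCOVA table), with slopes
rescaled to reporting convention (× 10 per decade of age, × 5 per
5 steps/min of cadence). Spearman correlations against severity use the
t-approximation above n = 10 and the exact distribution below. No
multiple-testing correction is applied, matching the modelled analysis
(three dependents at α = 0.05 each); users comparing many metrics should
adjust externally.

**A power caveat.** At the published group statistics (|FM| gap 0.11,
within-group SD 0.16) and n = 30/group, the closed-form two-sample t-test
power is 0.745, and the covariate-adjusted group test pays a further
collinearity cost because the groups differ in age and cadence (simulated
power ≈ 0.6). A reader should therefore not expect ≥ 80% detection at these
conditions; the published significance implies the realized adjusted effect
in the real cohort was stronger than its printed marginal moments convey.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use: 60-stride oscillators at
120 Hz for Floquet recovery (exact oracle: eigenvalues of `expm(A·T)`);
Lorenz at σ = 10, ρ = 28, β = 8/3, 200 s at 100 Hz against a Benettin/QR
tangent-propagation oracle (λ₁ ≈ 0.906 1/s); marker cohorts of 3
participants per damping level ζ ∈ {0.02, 0.05, 0.1, 0.2} with 5%
observation noise, 20 replicates, correlating per-level mean estimated
max LE_L with −ζω; 100 metrics-level replicates for ANCOVA power and 50
null replicates for post-hoc trigger calibration.

## Known limitations

* Marker IO covers TRC and a documented wide CSV; the binary C3D format is
  out of scope (no reader in the dependency set worth hand-rolling).
* The monodromy spectrum is reported on the identified dominant subspace;
  in a strictly periodic noise-free orbit whose damped frequency locks to
  the stride period, the second section direction is barely excited and the
  conjugate-pair structure of the multipliers is under-determined even
  though the leading exponent is exact. Real (variable) gait excites the
  section fully.
* Single-participant estimates at ~20 strides are intrinsically noisy —
  consistent with reports of ~30% variability in nonlinear gait metrics
  below ~15 strides; cohort-level contrasts are the intended use.
* LE units: per-second values are primary; stride-normalized values are
  also emitted, since conventions differ across the literature.
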