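---
title: "Quantifying the complexity of four-limb movement with MdRQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the complexity of four-limb movement with MdRQA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbrqa)
```

## The problem

During the first year of life, infants' limb movements reorganize from
globally coupled, undifferentiated motion toward selective inter-limb
coordination that adapts to the task at hand. A rhythmic, constrained task
(shaking a rattle) invites stable, repetitive joint movement of all four
limbs; unconstrained free play invites varied, irregular movement. A
longitudinal design — the same infants measured at several ages in both
tasks — asks whether and when the *complexity* of the joint four-limb
dynamics becomes task-dependent.

`limbrqa` implements that analysis end to end for wrist/ankle accelerometer
recordings sampled at 60 Hz, and — because infant movement data are rarely
shareable — ships a synthetic-session generator with the same statistical
skeleton, so every stage is testable without any data download.

## The pipeline

1. **Preprocessing** (`preprocess_session()`): per limb and per axis,
   missing samples are interpolated with a cubic spline; the three axes are
   collapsed to the acceleration magnitude
   $\sqrt{a_x^2 + a_y^2 + a_z^2}$; a third-order (3-point) median filter
   removes one-point outliers; each limb series is z-scored (sample sd) so
   no limb dominates by variance.
2. **Embedding** (`ami_delay()`, `fnn_dimension()`, `embed_multidim()`):
   the four standardized series are embedded jointly in one state space —
   delay $\tau$ from the first local minimum of the channel-averaged mutual
   information, per-channel dimension $m$ from false nearest neighbours,
   giving state vectors with $4m$ coordinates.
3. **Radius calibration** (`calibrate_radius()`): the recurrence radius
   $\varepsilon$ is bisected until the recurrence rate equals a fixed
   operating point (5% by default), making line-based measures comparable
   across subjects. Parameters are estimated on each subject's earliest
   visit and **fixed for later visits** (`fix_params_per_subject()`), so
   longitudinal change reflects dynamics, not parameter drift.
4. **MdRQA** (`rqa_measures()`): from the thresholded distance matrix
   (the recurrence plot) the package extracts the recurrence rate (RR, %),
   the Shannon entropy of the diagonal line-length distribution (Ent,
   nats), and the mean diagonal line length (ML, samples).
5. **Surrogate control** (`shuffle_channels()`, `surrogate_analysis()`):
   each channel is independently permuted — destroying temporal structure,
   preserving the value distribution — re-analysed with the *same*
   embedding parameters and radius, and compared to the observed measures
   with paired t-tests per visit.
6. **Repeated-measures statistics** (`fit_gee()`,
   `bonferroni_pairwise()`): each measure is modelled marginally as
   `measure ~ task * visit` by generalized estimating equations with an
   exchangeable working correlation and robust standard errors, so
   subjects missing a visit still contribute their remaining sessions;
   Wald tests of the three terms and Bonferroni-corrected pairwise cell
   contrasts mirror the standard reporting of such designs.

`run_pipeline()` chains all stages under one configuration with per-stage
logging and deterministic seeding.

## A worked micro-example

```{r example}
p <- regime_params("rhythmic", duration_s = 20, osc_freq_hz = 2.5)
ses <- generate_session("s01", "T1", "rattle", p, seed = 1)
ms <- preprocess_session(ses)
mdrqa(ms, tau = 1, m = 4, target_rr = 5)
```

## The recurrence measures

With states $\vec{x}_i$ and radius $\varepsilon$, the recurrence plot is
$R_{ij} = \mathbf{1}\{\lVert\vec{x}_i - \vec{x}_j\rVert \le \varepsilon\}$
(Euclidean norm). Let $P(\ell)$ count the maximal diagonal runs of
recurrent cells of length $\ell \ge \ell_{\min}$ outside the Theiler band.

* $\mathrm{RR} = 100 \cdot \sum_{|i-j| \ge w} R_{ij} \,/\, \#\{|i-j| \ge w\}$,
* $\mathrm{Ent} = -\sum_\ell p(\ell) \ln p(\ell)$ with
  $p(\ell) = P(\ell)/\sum P(\ell)$,
* $\mathrm{ML} = \sum_\ell \ell P(\ell) / \sum_\ell P(\ell)$,

with defaults $\ell_{\min} = 2$ (standard convention), Theiler half-width
$w = 1$ (exactly the main diagonal excluded — the band `|i - j| < w` is
dropped from both numerator and denominator, so calibration targets genuine
recurrences), and natural-log entropy (`rqa_config(log_base = 2)` switches
to bits). On an all-recurrent $5\times 5$ plot these conventions give
RR = 100%, ML = 3 and Ent = ln 3, which the test suite pins down by hand
enumeration.

Long sessions are processed by a streaming per-diagonal kernel (O(N²) time,
O(N) memory, compiled); `recurrence_plot()` materializes the full matrix
only for inspection, plotting and cross-checks, and the suite verifies the
two routes agree exactly.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `target_rr` | 5% | calibrated recurrence-rate operating point |
| `tau`, `m` | 1, 14 | embedding preset typical for such biological signals; both can be estimated per subject instead |
| `lmin` | 2 | minimum diagonal line counted |
| `theiler` | 1 | main-diagonal exclusion half-width |
| `n_bins` | 10 | equal-width histogram bins per margin for mutual information |
| `rtol`, `atol`, cutoff | 10, 2, 0.10 | false-nearest-neighbour criteria |
| exclusion threshold | 0.15 | worst-limb missing fraction above which a session is excluded |

Radius search: bisection between 0 and the maximum pairwise distance, to
within 0.1 percentage points of the target or 60 iterations; RR is monotone
non-decreasing in the radius, so bisection is valid. Degenerate state sets
(all states identical) are reported as calibration failures.

## Numerical choices and degenerate inputs

* **Interpolation order**: gaps are filled per axis *before* the magnitude
  is formed — the magnitude of interpolated axes is not the interpolation
  of magnitudes, and axes are what a sensor drops. Leading/trailing gaps
  take the nearest valid value; cubic extrapolation beyond the observed
  range can explode and is never used.
* **Median-filter edges**: the truncated window (median of the two
  available samples, i.e. their mean). Zero-padding — the convention of
  some filter implementations — injects spurious zeros into acceleration
  magnitudes and is deliberately avoided.
* **Mutual information on noiseless periodic signals** is degenerate: the
  joint histogram of a deterministic sine lives on a curve and the binned
  AMI acquires spurious local minima from bin-boundary aliasing. With
  observation noise at realistic sensor levels the first local minimum
  recovers the quarter period reliably (the suite measures ≥ 90% of seeds
  within ±1 sample); delay estimation on strictly noiseless signals is not
  a supported use.
* **False nearest neighbours with exact duplicates**: integer-period
  sampling creates duplicate states whose distance-ratio test is numerical
  noise; near-duplicate pairs (within `1e-8` of the attractor size) are
  judged only by whether the added coordinates separate them.
* **Empty task-by-visit cells** leave the saturated factorial model rank
  deficient; aliased columns are dropped by pivoted QR, affected contrasts
  are *flagged* non-estimable rather than silently removed, and term df
  shrink accordingly.
* **Degenerate surrogate differences**: all-zero paired differences give
  t = 0, p = 1; numerically constant non-zero differences give an infinite
  t and the smallest representable p.

## Small-sample inference for the marginal model

With a few dozen subjects the usual sandwich-covariance Wald $\chi^2$ test
over-rejects (the package's own null calibration measures ~10–12% at
nominal 5% for the 3-df interaction with 26 clusters). The defaults
therefore follow small-cluster practice: the Mancl–DeRouen bias-corrected
sandwich, with Wald statistics referred to $F(\mathrm{df},\, m - p)$ and
contrasts to $t(m - p)$, where $m$ is the number of clusters and $p$ the
number of coefficients. Under a no-effect null this holds the interaction
test's size at ~5–6%. `vcov = "robust"` and `test = "chisq"` restore the
large-sample convention of common GEE software — in the degenerate
one-session-per-subject case the plain sandwich equals the HC0 robust
covariance of ordinary least squares exactly, which the suite checks
against an independent implementation.

Factors are coded sum-to-zero, so each term's Wald block test is the
Type-III test: task on 1 df, visit on 3, interaction on 3. The default post
hoc family is all 28 pairs of the 8 task-by-visit cells — the conservative
reading of "Bonferroni-corrected pairwise comparisons"; task-within-visit
and visit-within-task subfamilies are available.

## What the synthetic generator emulates — and what it does not

`generate_session()` produces 3-axis acceleration whose per-limb magnitude
follows either a **rhythmic** envelope (shared-frequency oscillation at
`osc_freq_hz`, default 2.5 Hz; inter-limb phase coupling; random-walk phase
jitter scaled by `1 - regularity`; arms at twice the leg amplitude, as
rattle-shaking is arm-led) or an **unstructured** one (Poisson bursts on a
quiet baseline, no stable spectral peak). Signal directions wander slowly
on the unit sphere and white sensor noise is added per axis. Dropouts are
injected as contiguous gaps with geometric lengths (mean 5 samples —
sensor dropouts are bursty), targeting a 10.1% missing fraction by
default, the rate typical of wearable recordings in this design; sessions
above a 15% worst-limb threshold are excluded.

`cohort_design()` builds the longitudinal skeleton: per-visit counts
(default 19/21/26/17 with nested participation — a realistic attrition
pattern), both tasks per visit, and the built-in task-by-age interaction:
the rhythmic task's `regularity` rises at the third and fourth visits only
(+0.25/+0.30 over a 0.55 baseline), while free play is visit-invariant.
These values were fixed once as plausible defaults; none is calibrated to
any empirical dataset.

The generator does **not** emulate biomechanically realistic infant
kinematics, gravity or orientation (quaternions), caregiver sensors, or
developmental changes in amplitude or frequency. Passing tests therefore
show that the pipeline recovers structure *of the kind assumed*, not that
real infant data contain it.

Because a single signal-level cohort already costs minutes of CPU,
replicate-heavy validation of the statistics stage uses
`simulate_measure_table()`: a measure-level twin of the cohort generator
that draws (subject, visit, task, Ent, RR, ML) tables from a Gaussian
cell-mean model with a shared subject random intercept (intra-class share
0.5 of each cell's variance). Its default cell means and spreads describe a
plausible operating point for a four-visit infant cohort analysed at the 5%
recurrence rate — entropy near 5.1–5.7 nats, mean line near 15–24 samples,
task differences opening at the later visits only — so power and type-I
studies of the marginal model run in seconds. The signal-level path is
still exercised end to end in the test suite on a small cohort so the two
layers stay connected.

## Problem sizes used by the tests

Sessions of 20–50 s (1,200–3,000 samples) at 60 Hz; the operating-point
preset (τ = 1, m = 14, 56 state coordinates) for calibration and surrogate
separation; 50 random state matrices of up to 300 states for the
streaming-vs-matrix identity; 1,000 replicates for the surrogate null
calibration; 200 and 500 measure-level replicates for interaction power
and type-I error. These sizes are the package's own choices for
desk-scale, fully reproducible validation; field sessions of 5–10 minutes
run through the identical code paths.

## Known limitations

* The AMI/FNN estimators use fixed, classical criteria; rank-based or
  kernel MI estimators and alternative delay criteria (first 1/e crossing)
  are out of scope.
* Vertical-line RQA measures (laminarity, trapping time), determinism (DET),
  windowed RQA and cross-recurrence between two multidimensional systems
  are not implemented.
* The GEE stage offers exchangeable, independence and AR(1) working
  correlations only, with a Gaussian identity link; mixed-effects models
  and working-structure selection (QIC) are out of scope.
* Whether anchor calibration should pool tasks at the first visit or treat
  them separately is genuinely open for such designs; the default is per
  task (`per_task = TRUE`), since the two tasks differ in dynamics and a
  pooled radius would sit at neither task's operating point. A pooled
  switch is provided.
* The per-channel reading of the embedding dimension (state space has
  `4 * m` coordinates) is the default interpretation of dimension presets;
  a total-dimension reading would divide by the channel count.
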