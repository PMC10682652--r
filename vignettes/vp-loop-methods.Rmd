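---
title: "Velocity-pressure loop analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-pressure loop analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vploop)
```

## The measurement problem

Severe aortic stenosis is usually graded by valve-centric numbers -- peak and
mean transvalvular gradients, valve area, energy loss index -- or by the
global afterload estimate Zva = (SBP + mean gradient)/SVi.  All of these are
static summaries.  The velocity-pressure (VP) loop instead pairs, instant by
instant over one cardiac cycle, the forward flow velocity measured by pulsed
Doppler in the left ventricular outflow tract (LVOT, just proximal to the
valve) with the invasive pressure in the ascending aorta (just distal to
it).  The loop's early-systolic geometry captures how much aortic pressure
has already risen by the time flow through the valve peaks -- a
time-coupling property that no single gradient reflects.

The central index is

$$\mathrm{slope\_index} \;=\; \frac{P(V_{max}) - P(V_o)}{V_{max}},$$

where $V_{max}$ is the peak LVOT velocity, $P(V_{max})$ the aortic pressure
at that instant, and $P(V_o)$ the pressure at ejection onset, which equals
the diastolic (minimum) pressure of the beat.  On axes of velocity (cm/s,
abscissa) against pressure (mmHg, ordinate) with 1 cm/s treated as one axis
unit per 1 mmHg, this ratio is exactly the tangent of the ALPHA angle of the
loop: `compute_features()` enforces `tan(alpha_deg) == slope_index` as an
algebraic identity, so the two parameterizations are interchangeable.  A
*small* index (pressure still low when flow peaks, i.e. strong
pressure-flow decoupling) marks a heavier stenotic burden and predicts
absence of functional improvement after TAVI.

Two further angles are reported.  BETA is the chord angle from
$(V_{max}, P(V_{max}))$ to $(V_{P_{max}}, P_{max})$, describing the late-systolic
limb; GALA is the global chord from $(0, P(V_o))$ to $(V_{P_{max}}, P_{max})$.
The intraoperative-monitoring literature that introduced these names does
not print closed-form definitions, so these chords -- built only from the
named landmarks -- are this package's stand-ins.  They are deliberately
isolated in one function each (`compute_features()`) so they can be swapped
if authoritative definitions surface; downstream code depends only on ALPHA
and the slope index.

## From traces to one averaged beat

The pipeline assumes each channel carries a simultaneous ECG so beats can be
gated at R-peaks:

1. **Segmentation** (`segment_beats()`): each beat spans $[r_i, r_{i+1})$,
   re-expressed as time since its own R-peak; the final partial beat is
   discarded.
2. **Meshing** (`mesh_beat()`): each beat is linearly interpolated onto
   `n_points` equally spaced relative times.  Linear interpolation is the
   least-assumption choice for curves that were, in the original workflow,
   digitized from plotted images, and it is exactly testable (it is exact on
   piecewise-linear data).  The default mesh of 256 points resolves 1-2 ms
   features at typical heart rates.
3. **Averaging** (`average_beats()`): beats are averaged pointwise by mesh
   index, with the common mesh normalized to the *median* R-R duration.
   Nothing in the source methodology states how beats of unequal duration
   were reconciled; index-wise (time-normalized) averaging is this package's
   choice because it prevents diastolic smearing when cycle lengths vary.
   Twenty beats is the reference practice for a final pressure measurement;
   fewer produces a warning, never a silent result.

Landmark extraction (`extract_landmarks()`) takes discrete extrema on the
mesh, first index on ties (a determinism rule).  Ejection onset $V_o$ is the
first mesh point where the envelope reaches 5% of $V_{max}$ (configurable);
the 5% floor makes onset detection robust to envelope baseline noise, while
$P(V_o)$ itself is simply the beat's minimum pressure and does not depend on
that threshold.

A simplified clinical path to the same number exists:
`pressure_at_vmax_by_rwave()` reads the pressure trace at
R-peak + (R-to-$V_{max}$ interval), averaged across beats.  On noiseless
aligned signals the two routes agree to well under 0.1 mmHg (a two-path
agreement property in the test suite); the residual difference is pure
interpolation error, second-order in the mesh step.

## Endpoint rules

Objective improvement at 6 months is disjunctive and inclusive: a gain of at
least 10% in 6-min-walk distance, or -- only when that is not met -- a drop
of at least 50% in NT-proBNP, both relative to pre-TAVI.  NT-proBNP is
compared as a ratio, not a difference, because the criterion is phrased as a
proportional reduction.  Death handling: death before day 30 from heart
failure counts as *not improved*; death before day 30 from other causes
excludes the patient (no functional evaluation exists); death between the
30-day evaluation and 6 months is classified on the 30-day values with the
same thresholds, overridden to *not improved* if heart failure intervened.
The rule is purely disjunctive as written: a patient passing the walk-test
criterion is improved regardless of the biomarker trajectory.  Subjective
improvement is at least one NYHA class and/or at least 10 KCCQ points.

## Cohort statistics

* **Screening** (`compare_groups()`): Shapiro-Wilk on each group decides
  Welch t vs Mann-Whitney for continuous variables; chi-squared switches to
  Fisher's exact test when any expected cell is below 5.  Variables with
  p < 0.2 enter the multivariable model.
* **Partition** (`stratified_partition()`): per-class
  `round(n_k * fraction)` sampling keeps the train-set prevalence within one
  patient of the cohort's.
* **Balancing** (`rose_balance()`): with ~80% of patients improving, the
  training set is rebalanced by a ROSE-style smoothed bootstrap.  Each
  synthetic patient is a resampled seed patient plus zero-mean Gaussian
  noise with per-dimension bandwidth
  $h_j = \left(4/((q+2)n_k)\right)^{1/(q+4)} s_j$ (the technique's standard
  rule; the source names the technique but not its parameters, so the
  canonical bandwidth with shrink multiplier 1 is the default, and shrink 0
  degrades gracefully to a plain bootstrap).  Generated points inflate each
  dimension's variance to $\sqrt{s_j^2 + h_j^2}$, a closed form the tests
  check.
* **Model** (`fit_logistic_stepwise()`): "stepwise elimination" is
  implemented as backward elimination of the largest Wald p-value until all
  retained predictors have p < 0.05, the common clinical-literature
  convention; AIC-based elimination is available behind a flag.  Odds
  ratios use Wald 95% intervals; calibration is Hosmer-Lemeshow on 10 risk
  deciles (df = 8) and Nagelkerke R².  The reported odds ratio for the
  ALPHA angle is treated as per-degree in documentation; nothing in the
  package asserts that reading in a test.
* **Ensemble** (`bagged_ensemble()`): 100 logistic members, each fit on a
  ROSE-balanced bootstrap resample; the ensemble score is the mean predicted
  probability (majority vote behind a flag -- the aggregation rule is not
  pinned by the source, and probability averaging is the standard bagging
  choice for calibrated scores).
* **ROC** (`roc_analysis()`): midrank AUC (= trapezoid = Mann-Whitney
  concordance with ties at 1/2), DeLong variance for the CI with a
  2000-replicate stratified bootstrap fallback for degenerate cases, and a
  Youden-J cutoff over observed score values with ties resolved to the lower
  cutoff.  The reference cutoff of 0.1 for the slope index is a documented
  comparison value, never a constant in code.
* **Survival** (`km_logrank()`): product-limit curves, log-rank test, and
  the HR from a one-covariate Cox fit, all delegated to the survival
  package; a hand-computed product-limit oracle in the tests guards the
  wiring.

## What the synthetic generator does and does not emulate

`gen_beat_pair()` composes each cycle from closed forms: a raised-cosine
systolic upstroke (default rise time 300 ms -- deliberately slow, the
pulsus tardus of severe stenosis) starting 80 ms after the R-peak, an
exponential diastolic decay (tau 0.5 s) whose asymptote is solved so the
beat's minimum equals the configured diastolic pressure exactly, a Gaussian
dicrotic notch, and a piecewise half-cosine velocity envelope (onset 50 ms,
acceleration time 150 ms, ejection 320 ms, peak 80 cm/s), sampled at 250 Hz
(typical fluid-filled-manometer bandwidth).  The severity dial is
`severity_decoupling`: extra lag of the pressure upstroke relative to the
velocity peak, which strictly decreases the slope index (defaults span
~0.26 down to ~0.03 across 0-80 ms).  Ground-truth landmarks are evaluated
from the same closed forms on a 0.05 ms grid, independent of the sampling
and meshing under test.

`gen_cohort()` draws improvement labels Bernoulli(0.804), then generates
group-conditional baselines from the two-group summaries (slope index
0.23 ± 0.19 improved vs 0.09 ± 0.08 not), functional trajectories consistent
with each label, and exponential survival matched to the 9% vs 44% two-year
mortality split.  Two deliberate choices:

* **Moment-matched truncation.**  Positive quantities are drawn from
  normals truncated at zero.  Naive truncation of N(0.09, 0.08²) discards
  ~13% of its mass and inflates the group mean by ~0.02, which propagates
  to a ~0.07 shift of the between-group AUC.  The generator therefore
  solves for pre-truncation parameters such that the *post-truncation*
  mean and SD equal the configured values; the empirical AUC then sits
  within ~0.01 of the binormal closed form
  $\Phi(\Delta\mu/\sqrt{\sigma_1^2+\sigma_2^2})$, which the acceptance
  tests check at n = 20000.
* **Label-consistent trajectories.**  Walk-test and biomarker changes are
  generated *from* the label (improved: +10-40% walk distance or 50-80%
  NT-proBNP drop; not improved: below both thresholds), and deceased
  improved patients are assigned non-cardiac causes while deceased
  non-improved patients die of heart failure.  This makes endpoint
  classification testable as a round trip: only deaths before the 30-day
  evaluation (a fraction of a percent) can escape it.  It also means the
  generator cannot probe the endpoint's behaviour on contradictory data --
  that is covered by randomized-record property tests instead.

The printed group dispersions for pressures and gradients (e.g. SBP
136 ± 4 vs 130 ± 3 mmHg) are implausibly tight for biological SDs and may
be standard errors, but they are adopted as SDs as printed; the consequence
is an overly clean SBP separation in synthetic cohorts, which affects
nothing downstream except making the univariate screen easier to pass.
Similarly the ratio row's ±0.08/±0.19 are taken as SDs.

None of this is circulation modelling: there is no Windkessel, no wave
reflection, no beat-to-beat variability beyond additive Gaussian noise, no
atrial fibrillation, and the Doppler envelope is noise-free in shape.
Passing tests therefore demonstrate the *pipeline's* correctness on signals
with the right morphology, not clinical validity on measured recordings.

## Numerical choices and problem sizes

Discrete landmark extraction on a 256-point mesh of 250 Hz samples carries
a timing quantization of one to two milliseconds at the velocity peak; with
the default waveforms that bounds the slope-index error near 0.3%, and the
full-pipeline oracle test asserts agreement with the analytic value within
1%.  Monotonicity of the severity sweep is asserted on gaps of several
mmHg, far above the noise floor left after 20-beat averaging
($\sigma/\sqrt{20}$, also checked explicitly).

Simulation-based checks use sizes chosen to keep each property's Monte
Carlo error an order of magnitude below its tolerance: coefficient recovery
with 100 replicates at n = 5000, null-calibration of the log-rank test and
Hosmer-Lemeshow with 200 replicates, ROSE variance inflation at n = 10000,
closed-form AUC agreement at n = 20000, and label round-trips at n = 20000
to 100000.  All stochastic functions take explicit seeds (default
20231114) and restore the caller's RNG state, so whole-pipeline runs are
byte-reproducible -- an acceptance property verified by comparing serialized
reports.

## Known limitations

* BETA and GALA are provisional chord definitions (see above).
* The improvement model's positive class is the second factor level of the
  outcome; with character labels, alphabetical order decides, so recode
  explicitly when in doubt.
* Only LVOT (pulsed-Doppler) velocity is supported; continuous-wave jet
  velocity loops, echo image processing, and intraoperative continuous
  afterload monitoring are out of scope.
* The Hosmer-Lemeshow decile grouping collapses when fitted probabilities
  are nearly constant; the function then refuses rather than returning a
  misleading statistic.
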