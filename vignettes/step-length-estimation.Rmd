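---
title: "Adaptive step-length estimation from acceleration magnitude: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive step-length estimation from acceleration magnitude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitlen)
```

## The problem and the model

Pedestrian dead reckoning needs a per-step (or per-stride) length from a
body-worn accelerometer. Parametric step-length models map a handful of
per-stride features to a length through a few constants tuned per
person. `gaitlen` centres on an estimator with two such constants,

$$ d = K_1 \, F + K_2 \, a_r^{0.1}, $$

with $F$ the stride frequency (Hz) and $a_r$ the within-stride range of
the acceleration *magnitude* (m/s²). Two properties motivate this form:

* the Euclidean norm of the acceleration vector is invariant under any
  rotation of the sensor axes, so the estimate does not depend on device
  orientation — a practical necessity for phones carried in arbitrary
  poses;
* both inputs track walking speed, so a frequency term corrects the
  magnitude-only model $d = K\,a_r^{0.1}$, whose constant otherwise
  drifts with speed.

The exponent $0.1$ is a strong compression of $a_r$: over the
physiological range (roughly 3–9 m/s² at the pelvis) $a_r^{0.1}$ spans
only about 12%, so the term behaves as a gently modulated baseline while
$F$ carries most of the speed response. This has consequences for
calibration design discussed below.

Four published comparison estimators are implemented behind the same
interface (`sl_models()`), covering the main families in the field:
inverse-frequency fourth-root, mean-acceleration with a 2.7th root,
an affine function of frequency and magnitude variance, and a
height-based power law. Models published against *step* frequency or
*vertical* acceleration are fed stride frequency and magnitude features;
the factor of two and the projection are absorbed by the fitted
constants, which is the only consistent choice when device orientation
is unknown. One comparison model's published typography is ambiguous
about grouping; the canonical reading
$0.1\,\bar a\,(K/F)\,a_r^{1/2.7}$ is the default and the alternative
grouping is selectable (`bylemans_variant`), since with a fitted $K$
they differ only in functional shape.

## Stride segmentation

No detector is prescribed by the modelling literature this package
follows, so segmentation is a deliberately simple, fully configurable
design (`seg_config()`):

* the magnitude is smoothed with a trailing 10-sample moving average
  (the same filter length used for marker derivatives);
* step peaks are local maxima with a minimum topographic prominence
  (default 0.5 m/s²) and a minimum spacing (default 0.3 s, admitting
  cadences far above the walking speeds of interest);
* strides pair peaks of the same parity — peak $i$ to peak $i+2$ — so a
  stride spans two steps, matching references that are stride lengths of
  one limb;
* candidate strides outside a physiological duration gate of
  $[0.4, 4]$ s are discarded.

Features are always computed on the **unsmoothed** magnitude: smoothing
exists only to stabilise peak picking, and computing $a_r$ on filtered
data would bias it low by an amount depending on cadence. The
within-stride variance `a_v` is the population variance (divide by $n$):
each stride window is the entire population of its samples, and fixing
the convention keeps fitted constants comparable.

The trailing moving average maps a constant series to itself by
shrinking the window at the start; whether such a filter should be
centred is genuinely open, and the trailing form was chosen because it
is causal and edge-exact.

## Calibration

`sl_fit()` fits constants by least squares per calibration context
(person, sensor position, speed set), following the usual protocol of
tuning on the first five minutes of a trial (`calibration_split()`,
default 300 s) and evaluating on the remainder. Closed forms are used
wherever they exist:

* single-constant models: $K = \sum d_i x_i / \sum x_i^2$, the exact
  least-squares solution through the origin with $x_i$ the model's basis
  value;
* the two-constant model: ordinary least squares on $(F, a_r^{0.1})$
  **without intercept** — the model has none, and adding one would
  change what the constants mean;
* the frequency + variance model: OLS on $(F, a_v, 1)$;
* the height power law: OLS in log space. Within one subject the height
  is constant, so $K_1$ and $h^{K_2}$ cannot be separated; the fit pins
  $K_2 = 1$ and folds the rest into $K_1$, which leaves predictions
  unchanged. The minimized objective for this model is therefore the
  *log-space* residual sum of squares, and the `sl_fit` object records
  which objective it minimized — a grid-search check of the optimizer
  must compare in that space. An optional nonlinear refinement in the
  original space is deliberately omitted from the default path for
  determinism.

Rank-deficient designs (e.g. constant frequency across all strides) are
rejected naming the collinear regressors rather than silently returning
one of infinitely many solutions.

**Identifiability and calibration design.** Because $a_r^{0.1}$ is
nearly constant within a single steady speed, $(F, a_r^{0.1})$ are close
to collinear there, and two-constant fits on one speed are weakly
identified. Calibration data should therefore pool strides across
walking speeds — which is also what the free-walking tuning protocol
does by joining the treadmill speeds (`fit_joined()`). All
parameter-recovery experiments in the tests and the acceptance script
follow this design: three speeds of ~167 strides each, 2 cm
reference-length noise, under which both constants are recovered to
about $\pm 0.01$.

## The adaptive scheme

`fit_speed_profiles()` stores, per walking speed, the fitted constants
together with the tuning window's mean $F$ and mean $a_r$.
`estimate_adaptive()` then processes strides in consecutive windows of
$N$ (default 10), selects for each window the profile whose stored input
averages are nearest — Euclidean distance after z-scoring both features
by the spread of the profile centroids, so Hz and m/s² are comparable —
and applies that profile's constants to the window itself (causal, no
look-ahead). Ties break toward the lower-frequency profile,
independently of list order.

$N$ is not fixed by the source literature; 10 strides (~10 s at
ordinary cadence) balances responsiveness against averaging noise and is
exposed in `adaptive_config()`. Nearest-centroid matching is the
minimal faithful realization of "selection by input averages"; the rule
is isolated in `select_profile()` so richer rules can be plugged in.

## Marker kinematics and reference lengths

Reference stride lengths come from a heel marker. Velocities and
accelerations are finite differences (central in the interior,
one-sided at the ends) followed — in that order — by the 10-point
moving average. Stance phases are runs where the filtered horizontal
heel speed stays below 0.2 m/s for at least 0.1 s; the stride length is
the horizontal displacement between consecutive stance centroids. The
coordinate convention everywhere is x–y ground plane, z vertical.

On a treadmill the belt carries the foot during stance, so the
displacement gains a `belt_speed × interval` term. The synthetic
treadmill trials are expressed in the frame in which stance points are
stationary (net heel displacement near zero over a trial) and the belt
term reconstructs the full stride length; with constant stride timing
the identity $d = v_{belt}\,\Delta t$ is exact, which the tests use as
an oracle. Note that on a constant-speed belt the *true* per-stride
length is $v_{belt} T_i$, so stride-time jitter implies stride-length
jitter; the generator's ground truth reflects this.

## The derivation stage

To justify adding frequency to the magnitude model, the package
reproduces a canonical-correlation analysis between per-stride
constants of the magnitude-only model, $K_i = d_i / a_{r,i}^{0.1}$
(matrix $X_1$), and candidate gait parameters (matrix $X_2$): stride
frequency, stride duration, and the mean, median and range of a
marker's filtered acceleration and velocity in each of three dimensions
— $2 + 2\cdot3\cdot3 = 20$ labelled columns. Columns are centred and
scaled to unit variance; zero-variance columns are dropped with a
warning, exact linear dependencies are an error naming the columns.
Since the inputs are unit-variance, the canonical coefficients are
already standardized, and `rank_parameters()` orders parameters by the
absolute first-pair coefficient — raw coefficients would be
scale-dependent and meaningless as "contribution". With a single-column
$X_1$ the first canonical correlation equals the multiple correlation
of regressing $K$ on $X_2$, which provides an exact independent oracle
(`lm()`), and results whose first correlation falls below a threshold
(default 0.1) are flagged as uninformative. When several markers are
analysed, per-marker rankings are aggregated by mean rank — an
aggregation rule of this package, chosen for transparency.

Stride frequency and stride duration are reciprocals and hence nearly
collinear over walking ranges; rankings between those two columns are
reliable only when the driving signal is strong relative to noise, as
in the seeded experiments here.

## Evaluation metrics

For per-stride evaluation, errors are $e_i = d_{est,i} - d_{ref,i}$ in
cm; for walked distance, $e = (d_{est} - d)/d \cdot 100\%$ per trial.
Reports carry MAE $= \mathrm{mean}|e|$, SD $=$ the *sample* standard
deviation of $|e|$, and CV $=$ SD/MAE — the SD-of-absolute-errors
reading is adopted because it reproduces every published
(MAE, SD, CV) triple in the benchmarking tables this package mirrors at
two decimals, which a signed-error SD need not. The same three
statistics are computed within the over- ($e>0$) and under-estimation
($e \le 0$) subsets; zero counts as underestimation so the shares always
total 100%. With fewer than two errors, SD and CV are reported as `NA`,
never as 0. Display rounding is decimal half-up at 2 dp with a tiny
epsilon guard, because binary doubles store values like 0.725 just
below the midpoint.

## Synthetic gait

`gait_scenario()` fixes every condition of a simulated trial under one
seed. The magnitude is a baseline plus a harmonic at the step frequency
$2F$, a weaker harmonic at $F$ (left/right asymmetry), and i.i.d.
Gaussian noise; a fixed seeded rotation distributes it over three axes
so the magnitude itself is rotation-controlled. Defaults:

* speed labels map to stride frequencies 0.80 / 0.92 / 1.05 Hz (slow /
  normal / fast; polygon 0.90 Hz) — plausible stride rates for 3.3 /
  4.6 / 5.9 km/h, monotone by construction, and explicitly this
  package's choices rather than measured facts;
* position amplitudes 4.0 (hand) > 3.0 (thigh) > 2.5 (upper arm) >
  2.0 (pelvis) m/s² — distal segments swing harder than the trunk;
* stride-time CV 4% and amplitude CV 10%, typical steady-walking
  variability; magnitude noise 0.3 m/s²;
* reference lengths from either the linear truth model
  $d_i = K_1^* F_i + K_2^* a_{r,i}^{0.1} + \varepsilon_i$ (defaults
  $K_1^*=0.35$, $K_2^*=0.20$, $\sigma_\varepsilon = 2$ cm) or an
  inverted-pendulum relation on leg length;
* marker trajectories carry 0.5 mm per-coordinate measurement noise,
  the accuracy class of active optical systems — also what keeps the
  20 kinematic feature columns from being exactly collinear;
* the polygon route is a rectangle of perimeter 21.64 m (aspect 2.6:1).

Noise draws are standard normal and scaled by the configured SDs, so
scenarios differing only in a noise level share underlying draws; this
makes error-versus-noise curves exactly monotone rather than monotone in
expectation. What the generator does **not** emulate: soft-tissue and
mounting artifacts, heavier-tailed sensor noise, turning dynamics,
asymmetric gait, marker dropouts. Passing tests on this data therefore
establish correctness of the pipeline's logic and numerics, not field
accuracy on recorded gait.

## Problem sizes and numerical choices

The test and acceptance experiments use ~500 strides for parameter
recovery, 100 random rotations for orientation invariance, 20 seeded
instances per optimizer/oracle comparison, and 60–100 replicates of the
derivation-stage ranking — sizes at which every stochastic margin
observed is wide (rank-first shares at 100%, oracle agreement at
machine precision). Other conventions: stride intervals are half-open
`[start, end)`; peak candidates are accepted in decreasing height order
under the minimum-distance constraint; the adaptive selector's tie rule
is by stored mean frequency; all lengths are meters internally, with cm
and % appearing only in reports.

## Limitations

The segmentation thresholds are stand-ins calibrated to clean walking
signals and are all config-exposed; recorded data from hand-carried
devices will need tuning. Per-subject calibration with reference
lengths is assumed available — the package does not attempt
calibration-free estimation. The height power-law model is fitted in
log space, which weights relative rather than absolute error. The CCA
stage ranks linear contributions only.
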