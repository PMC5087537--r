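---
title: "Foot motion identification from a shoe-mounted IMU: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foot motion identification from a shoe-mounted IMU: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepdir)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## Problem and signal model

A six-axis MEMS IMU (triaxial gyroscope, rad/s; triaxial accelerometer,
m/s² of *specific force*) is strapped to a shoe and sampled at a nominal
200 Hz. The task is to turn each step into one of five discrete motion
events — jump, left, right, forward, backward — within a fraction of a
second of the foot leaving the ground.

Three frames matter:

* **sensor (body) frame** — axes fixed to the mounted device; its forward
  (y) axis is mounted along the foot's forward direction, but pitch and
  roll vary with shoe style and placement;
* **user frame** — Right (x), Forward (y), Up (z), fixed to the wearer;
* **navigation frame** — the local-level frame used for integration;
  identical to the user frame here because yaw is defined to be zero.

At rest the accelerometer reads the reaction to gravity. We adopt one
convention throughout: the at-rest specific force in the user frame is
`a_n = (0, 0, +g)`, with `g = 9.80665` m/s² by default. Every equation in
the attitude filter (residual, measurement matrix, leveling) is derived
under this single convention, and the consistency between the residual and
its linearisation is verified by a finite-difference Jacobian test rather
than by matching a printed sign pattern.

## Sensor error compensation

Both triads follow the standard deterministic error model

\[
\tilde\omega = \omega + b_\omega + (S_\omega + N_\omega)\,\omega + \varepsilon_\omega ,
\]

and likewise for specific force. `compensate()` inverts the deterministic
part exactly, `ω = (I + S + N)^{-1}(\tilde\omega - b)`, rather than using
the first-order approximation `(I - S - N)`: at desk scale the exact solve
costs nothing and removes a second-order error that would otherwise be
folded into the attitude filter. The stochastic term is deliberately left
in place — it is noise, and it is the smoothing window's and the Kalman
filter's job to handle it. A property test drives random invertible
calibrations through the forward model and back, requiring recovery to
1e-12.

Calibration estimation itself (turntable or hand-rotation schemes) is out
of scope; parameters arrive as a YAML config with identity defaults.
Angular rates are rad/s internally; the CSV reader accepts deg/s behind a
flag and converts on ingest.

## Attitude filter

Gyro integration alone drifts; accelerometer leveling alone is noisy and
corrupted by motion. The filter fuses them in error-state form. The full
attitude is a quaternion (body → navigation) integrated with the
bias-corrected rate; a DCM is exposed wherever a matrix is more
convenient. The quaternion representation avoids the re-orthonormalisation
drift a raw DCM would accumulate; orthonormality to 1e-9 is asserted in
tests after feedback corrections.

The 6-dimensional error state is the attitude error ψ and the gyro-bias
error δb:

\[
\dot\psi = -C_b^n\,\delta b, \qquad
\dot{\delta b} = -\delta b/\tau_b + w .
\]

The bias is a first-order Gauss–Markov process with correlation time
`tau_b` (default 100 s — MEMS bias wanders on minutes, and within a
session the exact value is uncritical). Earth rotation and transport rate
(`ω_in^n`) are set to zero: at ~7.3e-5 rad/s the Earth rate is two orders
of magnitude below MEMS bias, and sessions are short, slow and local. The
code has no provision to re-enable it because no parameter of this
application could make it observable.

The measurement is the body-frame gravity residual
`δa = f^b − C_n^b (0,0,g)ᵀ`, linearised as `δa ≈ C_n^b [a_n ×] ψ`; the
bias block of the measurement matrix is identically zero (bias reaches
the measurement only through propagated attitude error). Using the
acceleration residual rather than accelerometer-derived angles avoids the
±90° pitch singularity.

### Adaptive measurement noise

The residual is only meaningful when the accelerometer sees gravity alone,
so the measurement covariance adapts to the dynamic index
`ε = | ‖f‖ − g |`:

| mode | condition | R |
|---|---|---|
| stationary | `ε < Thres1` | `R₀ = diag(σ_x², σ_y², σ_z²)` |
| low acceleration | `Thres1 ≤ ε < Thres2` | `R₀ + k ε² I` |
| high dynamic | `ε ≥ Thres2` | no update (prediction only) |

`Thres2 = 2g` by default. The stationary threshold is stated in the source
formulation as `3·(σ_x² + σ_y² + σ_z²)`, which is dimensionally a variance,
not an acceleration; the intent is unknowable from the text. The package
implements that form verbatim as the default (`thres1_mode = "variance"`)
and exposes the dimensionally consistent alternative
`3·sqrt(σ_x²+σ_y²+σ_z²)` (`thres1_mode = "std"`) plus a direct `thres1`
override. With the default accelerometer noise (σ = 0.05 m/s² per axis)
the verbatim threshold is small, so on real noisy data the filter spends
most quiet time in the low-acceleration branch — which is benign, because
there `R` inflates smoothly from `R₀`. The inflation gain `k` (default
100, dimensionless) is deliberately aggressive: a residual of 1 m/s²
should contribute almost nothing.

The scalar `k ε²` inflation is applied isotropically. The residual is a
body-frame vector while the index is a norm, so a per-axis inflation is
not identifiable from `ε` alone; isotropic is the only symmetric choice.

### Initialisation and tuning

Pitch/roll come from accelerometer leveling over the first 0.5 s (assumed
static — sessions begin with a stance lead-in); yaw is zero by the
user-frame definition. Initial uncertainty: 5° attitude, 0.05 rad/s bias,
diagonal. Process noise defaults (`q_gyro = 1e-6` rad²/s,
`q_bias = 5e-5` (rad/s)²/s) follow from typical MEMS angle-random-walk and
from the Gauss–Markov identity `q = 2σ_b²/τ_b` with σ_b ≈ 0.05 rad/s; they
are the values under which the filter's static convergence properties
(sub-degree attitude, bias recovery within 20%) hold in the test suite,
and they are config-exposed.

The update uses the Joseph-form covariance update and a Cholesky solve of
the innovation covariance; a non-positive-definite innovation covariance
raises an error rather than silently regularising. After every update the
estimated ψ is folded into the quaternion (small-angle correction, then
renormalisation), δb into the bias estimate, and the error state resets to
zero.

### User-frame projection

Only pitch and roll are observable from gravity; yaw is not, and it is
also irrelevant, because the sensor's forward axis is mounted along the
foot's forward direction. `to_user_frame()` therefore strips the yaw of
the filtered attitude (premultiplying by `Rz(-yaw)`) and rotates both
triads by what remains. At rest the projected specific force is
`(0, 0, +g)` for any mounting pitch/roll — this is exactly the
misalignment cancellation that lets one classifier serve every shoe, and
it is made testable by the generator (below).

## Segmentation

The acceleration norm is smoothed by a **causal** trailing mean of N
samples (default N = 10, i.e. 50 ms at 200 Hz): long enough to suppress
MEMS noise, short enough not to merge the two peaks of a gait cycle. A
causal window introduces a group delay of about N/2 samples; the detected
peak sits slightly after the physical one, which is harmless because the
classification window is anchored to the detected peak.

A peak is `s[i-1] < s[i] ≥ s[i+1]` with height at least `min_peak_height`
(default `g + 2` m/s² — above any at-rest value, below any deliberate
push-off) and at least `refractory` samples after the previously accepted
peak. The rule is decidable one sample after the apex, so the offline and
streaming implementations are equivalent by construction, and a test
replays sessions through both paths to confirm it.

The refractory default is 90 samples (0.45 s). A gait cycle produces, after
the push-off peak, both a deceleration peak (~0.5 of the movement interval
later) and a heel-strike/landing peak (~0.25–0.4 s later), and a vigorous
step or jump makes both large enough to clear any reasonable height
threshold. A refractory shorter than that gap would emit two or three
events per step; one longer than the fastest plausible step period
(~0.7 s peak-to-peak) would drop real steps. 0.45 s sits between the two
with margin on both sides, and the single-event-per-step property is
asserted in the acceptance tests across the generator's full strength and
cadence sweep.

Each accepted peak cuts a fixed 31-sample window — 20 samples before the
peak, the peak, 10 after (indices are 1-based in R; the peak is local
index 21). At 200 Hz the window spans 0.15 s, which fixes the decision
latency: 10 samples of future context plus the smoother delay, about
0.1 s past the peak. Features are computed on the compensated user-frame
signal inside the window; the smoothed norm exists only for detection.

## Features

Per window (x = right, y = forward, z = up):

* per-axis mean and **population** variance (divide by N, matching the
  defining formula) of both triads;
* per-axis SMA of acceleration, computed as the rectangular sum
  `Σ|aᵢ| Δt` — the defining discrete form of `∫|a| dt` for a uniformly
  sampled signal;
* short-horizon displacement: `a_n = a_user − (0,0,g)` doubly integrated
  by the trapezoidal rule from zero initial velocity and position, with
  zero azimuth. Full INS mechanisation over a session would drift
  hopelessly on MEMS; over 0.15 s the double integral is reliable;
* for each of {position, mean, variance, SMA}: the axis ratios
  `x/√(x²+y²+z²)`. These are invariant to the overall strength of the
  motion — a heavy jump and a slight jump have very different vertical
  displacements but nearly the same vertical *share* — and they are what
  makes one bank generalise across wearers. A zero-norm triple returns
  `(0,0,0)` instead of raising: a degenerate window must not kill a
  real-time stream.

Timestamps drive Δt (median spacing, falling back to the nominal rate).
Gyro SMA and gyro-displacement analogues are omitted by default: the
rotational signal enters through the gyro mean/variance features, and the
displacement feature is specifically a translation signature. The schema
(30 named features, fixed order) is versioned, and banks refuse vectors
from a different schema version.

## Classifier bank

One binary classifier per motion, all sharing one backend and schema.
Five one-vs-rest problems are easier and more robust than one five-class
problem: each classifier only needs a boundary for its own motion, class
weighting handles the inherent ~1:4 imbalance (inverse-frequency weights
are on by default), and a future system can give each motion its own
feature subset.

Backends (hyperparameters are unstated in the source formulation; the
defaults below are conventional and config-exposed):

* **decision tree** — CART via `rpart`, Gini impurity, depth cap 10;
* **kNN** — `class::knn`, k = 5 (odd, so binary votes cannot tie),
  Euclidean distance on train-set-standardised features;
* **SVM** — `e1071::svm`, RBF kernel, internally unit-scaled features.

Arbitration of the five binary outputs is artifact plumbing (the source
formulation is silent): none fire → `none`; exactly one fires → that
motion regardless of magnitude; several fire → highest score, ties broken
by the fixed motion order jump, left, right, forward, backward. It is a
pure function of the score matrix and is exported (`arbitrate()`) so the
rule itself is directly testable.

## Evaluation

`metrics()` computes accuracy, precision and recall from confusion counts;
zero-denominator cases return `NA` with an `undefined` flag rather than a
silent zero. `kfold_split()` (default k = 10) partitions into near-equal
folds with every observation validated exactly once; `holdout_split()`
(default 25 %) is stratified by motion by default — stratification is not
part of the source procedure, but it stabilises small-stratum estimates;
plain random choice is available with `stratify = FALSE`. Error profiles
attribute each classifier's misclassified events to true motions and
report the share belonging to the classifier's own motion.

The package ships two small CSV tables of published benchmark counts
(detection counts per backend and motion under 10-fold validation, and
per-classifier misclassification counts) as worked-example inputs. The
test suite recomputes every derivable metric cell from these counts to
2 d.p. Three published cells are internally inconsistent with their own
counts (two accuracy cells that recompute to 99.02 rather than the printed
99.09, and one error-profile row whose counts sum to 37 but whose printed
percentage implies 39); the tests assert the recomputed values *and* the
fact of the discrepancy, rather than silently passing or failing them.

## The synthetic generator

The recorded dataset behind the published benchmark (3,775 motions from
ten testers) is not publicly deposited, so the generator stands in for it.
It is built from displacement profiles, which makes it physically
consistent by construction:

* horizontal travel over the movement interval (push-off + swing phases)
  follows the smooth-step `s(u) = L(u − sin(2πu)/2π)` — velocity zero at
  both ends, a sharp acceleration peak early in push-off and a
  deceleration peak near landing;
* vertical lift follows `z(u) = h sin⁴(πu)` — up and back down, zero net
  displacement, acceleration continuous at the phase boundaries;
* heel strike adds a short biphasic (zero-mean) vertical pulse;
* the foot pitches about the user's right axis by `Θ sin²(πu)` during
  movement; the body attitude is `Rx(θ(t))·R_mis` with `R_mis` the
  constant mounting misalignment, and the gyro and accelerometer outputs
  are the *exact* body-frame projections of these kinematics — so the
  attitude filter is tested against a ground truth it can in principle
  match exactly;
* bias and Gaussian noise are applied through the same forward error
  model that `compensate()` inverts.

Defaults (in `synthetic_defaults()`): step length 0.40 m, foot lift
0.05 m, jump lift 0.12 m, swing pitch 0.35 rad, heel-strike pulse
5 m/s² over 50 ms, cycle 0.7 s split (stance, push-off, swing,
heel-strike) = (0.25, 0.25, 0.30, 0.20), all scaled by a per-step
`strength`. Sessions jitter strength over ±50 % and cadence over roughly
0.42–0.63 s per cycle, per-wearer mounting offsets up to ±20° pitch/roll
and gyro biases up to ±0.02 rad/s — the diversity the pipeline must be
invariant to. Every stream is a pure function of its seed.

The ground-truth push-off peak of each step is annotated as the apex of
the causally smoothed *noiseless* norm within the push-off phase — the
detector's own definition of a peak, evaluated on the clean signal — so
that detection offsets measure noise and misalignment effects, not the
(known, harmless) smoothing delay.

What the generator does **not** emulate, and what that means for the
tests: real heel strikes are broadband impacts, not band-limited pulses;
real gait has step-to-step correlation, fatigue drift, and occasional
shuffles or half-steps; real mounting can slip mid-session; real
accelerometers saturate. Passing the end-to-end benchmark therefore
demonstrates that the pipeline's machinery is correct and
misalignment-invariant under realistic amplitudes and timing — it does not
certify the published accuracy numbers on recorded human data, which would
require the original dataset. The near-perfect synthetic benchmark
accuracies reflect the generator's clean class geometry; the published
figures on human data are lower precisely because humans are messier than
this model.

## Problem sizes

The end-to-end acceptance benchmark uses 10 simulated wearers × 20 steps
of each motion (≥ 200 windows per motion, ~1,000 windows total) — chosen
to match the order of magnitude of windows per motion in the published
study's smaller classes while keeping a full run on one CPU around a
minute. Oracle sweeps use 10⁴ random inputs; parameter-recovery runs use
30 s of 200 Hz data.

## Known limitations

* Yaw is undefined by construction; motions are directions relative to
  the wearer's forward axis, not compass headings.
* The filter assumes sessions begin with ~0.5 s of stance for leveling; a
  stream that starts mid-stride will converge only after the first quiet
  phase.
* Features use per-window attitude frozen at the projection stage;
  attitude drift *within* 0.15 s is negligible, but a grossly wrong
  attitude (e.g. after sensor remounting mid-session) degrades all
  position features until the filter re-converges.
* `class::knn` prediction cost grows with the training set; the tree and
  SVM backends are the real-time choices.
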