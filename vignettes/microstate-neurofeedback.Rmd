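---
title: "Microstate neurofeedback: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate neurofeedback: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnf)
```

This vignette is the package's own account of the science it implements: the
microstate model and segmentation operators, the calibration and feedback
equations, the synthetic generator used for validation, the statistical
layer, and the numerical and design decisions taken where the underlying
procedure left genuine freedom.

## The microstate model and segmentation

Multichannel EEG is modeled as a sequence of quasi-stable topographies
("microstates"): at each sample `t` the average-referenced scalp vector
`x_t` is, up to amplitude, polarity, and noise, one of K fixed template maps
`T_1..T_K`. Backfitting assigns each sample to
`argmax_k |r(x_t, T_k)|`, the template with the highest absolute spatial
correlation — Pearson across channels of the average-referenced vectors. The
absolute value encodes the physical fact that an oscillating dipolar source
flips the polarity of its topography without changing the topography itself.

Conventions worth stating because they are easy to get subtly wrong:

* Templates are stored average-referenced with unit L2 norm, under which the
  spatial correlation reduces to a dot product with the centered, normalized
  sample. Ties in the argmax go to the lowest state index (deterministic).
* A sample with zero spatial variance has no defined correlation and is left
  unassigned (`NA`), reported via a message. Coverage is computed over
  assigned samples by default (`coverage_denominator = "all"` divides by all
  samples instead).
* GFP — the per-sample spatial standard deviation — uses the population
  convention (divide by the channel count).
* GEV weights squared correlations by squared GFP:
  `GEV_k = Σ_{t: L(t)=k} GFP(t)² r²(x_t, T_k) / Σ_t GFP(t)²`. The per-state
  values sum to 1 exactly when every sample fits its template perfectly, and
  to less than 1 under noise.

### Label smoothing

Offline segmentation smooths labels with a windowed relabeling: each sample's
fit criterion for state k (its squared spatial correlation) is boosted by
`factor × n_k / window`, where `n_k` counts same-labeled neighbors within a
`window`-sample neighborhood (default 24 samples, i.e. ±12), and the sample is
relabeled to the best boosted state. The neighbor count is normalized by the
window length so `factor` (default 10) is independent of window size. Updates
are applied in place in a deterministic left-to-right sweep and sweeps repeat
until stable: the asynchronous order makes the iteration a coordinate descent
that terminates, where simultaneous updates can oscillate between two
labelings indefinitely. `factor = 0` returns the input unchanged. The
production implementation is verified, label for label, against a deliberately
naive re-implementation of the same update rule.

A consequence users should expect: at factor 10 the smoothing is strong. It
suppresses spurious label flicker under noise, but it also absorbs genuinely
short visits and therefore biases mean durations upward relative to the
generating process (roughly two-fold at 60 ms true dwell in our synthetic
checks). Coverage is much less affected (the parameter-recovery suite bounds
the error at ±0.05 under a 4:1 signal-to-noise ratio); duration comparisons
should always be made within a fixed smoothing setting.

### Short-segment rejection

Runs shorter than 3 samples are split at their midpoint; the left part takes
the left neighbor's label, the right part the right neighbor's, and the
middle sample of an odd run joins the side whose template correlates better
with that sample (ties to the left). The pass repeats until no short interior
run remains. Runs touching the sequence boundary are left alone on principle:
no neighbor exists there, and inventing one would bias edge coverage.

The online path — calibration epochs and real-time scoring — applies *no*
smoothing and *no* short-segment rejection, matching how a real-time loop
must behave (future samples are unavailable, and the feedback score must
react within one iteration).

## Calibration and the feedback equation

Calibration cuts a preprocessed resting recording into 3 s epochs with 0.5 s
overlap (step 2.5 s), backfits each epoch, and computes the target state's
coverage per epoch. With μ and σ the mean and standard deviation of that
distribution, the gauge range is `min = μ − σ`, `max = μ + σ`. σ uses the
population convention (divide by N): the epochs of the calibration run are
the entire population the thresholds are defined over, not a sample from a
larger one; `sd_type = "sample"` is available. Degenerate inputs error
explicitly: fewer than two epochs (σ undefined) and zero σ (the gauge would
have no width).

During a session, every 250 ms of simulated time the engine scores the last
3 s window, smooths the last 10 raw coverages with linear time weights
(`w_i = i`, newest heaviest, normalized by `Σw = 55` when full), and maps the
smoothed score through

```
feedback = 1 − 2 · (max − coverage) / (max − min)
```

which is −1 at `min`, +1 at `max`, 0 midway, strictly increasing in between,
and clipped to [−1, 1] by default — a gauge cannot over-fill; the unclipped
value is available for analysis. The regulation direction (up/down) never
enters this computation: it only changes how the display interprets the
value, which is what keeps participants blind to the intervention.

Startup and block boundaries needed decisions the procedure leaves open:

* **Warm-up** — scores are emitted only once a full 3 s window exists;
  before that, iterations pass silently. Smoothing uses however many (≤ 10)
  scores exist.
* **Breaks** — the smoothing history is reset at each block start, so no
  pre-break data leaks into a new block. The alternative (a persistent
  buffer) would let up to 2.25 s of stale coverage influence the first
  scores of a block; we flag this as the one place our loop may deviate from
  the original system, whose behavior is unstated.
* **Dependency horizon** — with these defaults a score depends on samples at
  most `3 + 9 × 0.25 = 5.25` s old, a bound the test suite verifies by
  perturbing older samples and checking bit-identical output.
* The loop runs on a simulated clock (one iteration per 250 ms of stream
  time, no dropped iterations), so sessions are exactly reproducible; a
  wall-clock deployment would instead drop iterations under load.

## The synthetic generator and the virtual subject

No participant data ships with the package; every downstream stage is
validated against synthetic EEG with known ground truth. The generating model
is deliberately the simplest one that makes the validation meaningful:

* **Labels** are a first-order Markov chain over K states. Self-transition
  probability `p` gives geometric dwell with mean `1/(1−p)` samples; the
  stationary distribution (left unit eigenvector) is the analytic ground
  truth for coverage. Defaults use 60 ms mean dwell per state — typical
  resting microstate durations.
* **Signals** are `x_t = s · a_seg · √C · T_{L(t)} + ε_t`: the active
  template scaled so the noiseless GFP equals the segment amplitude,
  plus white Gaussian sensor noise. Segment amplitudes are log-normal
  (mean 15 µV, CV 0.3), constant within a segment — the simplest amplitude
  process that makes GEV < 1 under noise; polarity flips are drawn per
  segment, not per sample, to keep segments coherent. The default noise SD
  of 7.5 µV gives a 4:1 template-to-noise power ratio.
* **Templates** for simulation are five smooth, mutually orthogonal
  topographies built from low-order spatial polynomials of the sensor
  positions, on an idealized quasi-uniform spherical cap of 62 channels.
  They are synthetic stand-ins, not grand-average maps.

What this generator does *not* emulate, and hence what passing tests do not
show about real data: 1/f spectra and oscillations, volume-conducted
correlated noise, artifacts (blinks, muscle), non-geometric dwell
distributions, topography variability across time, or anatomically measured
electrode positions. The suite demonstrates that the *operators* are correct
and that the closed loop behaves as designed — not that real participants
behave like the virtual subject.

The virtual subject couples the generator to the loop: after each feedback
emission the target state's self-transition probability moves in the trained
direction by `gain × (1 + feedback)/2`, clamped to (0.5, 0.98). The gating by
gauge fill — rather than by the signed feedback value — is a deliberate model
choice: a raw `gain × feedback` update is a bistable positive-feedback loop
whose drift direction is decided by the first few noisy scores, which is not
how a learning participant behaves; reward-gated progress (no unlearning when
the gauge is empty, fastest progress when it is full) produces the gradual,
monotone improvement a successful up-regulation session shows. The ceiling of
0.98 caps mean dwell at 50 samples, keeping the regulated chain in a
physiologically sensible range; with a floor near the baseline dwell,
down-regulation has little room and its trend is correspondingly attenuated —
mirroring the empirical asymmetry between up- and down-regulation.

## Preprocessing numerics

* **Band-pass** (1–30 Hz default) is Butterworth, applied forward and
  backward (zero-phase). Two numerical choices matter: the filter is realized
  as a cascade of analytically derived second-order sections, because the
  expanded transfer-function polynomial of an order-8 band edge at 1 Hz on a
  250 Hz rate has poles clustered near `z = 1` and is numerically unstable
  (forward-backward filtering visibly diverges); and each pass is seeded with
  steady-state initial conditions on an odd-reflection padding of three
  periods of the low edge, which suppresses edge transients and keeps a
  symmetric input symmetric to below 1e−6. The default order 8 per pass gives
  effective order 16 after the two passes.
* **Notch** (49–51 Hz) comes in two dialects: a zero-phase two-pass IIR
  band-stop (order 4) for the online loop, and a linear-phase Hamming-window
  FIR (transition width 0.5 Hz, length by the standard `3.3/Δf` rule, applied
  once with group-delay compensation) for offline work.
* **Bridged electrodes** are detected by electrical distance — the temporal
  variance of the channel-difference signal. Distances are scaled to
  100 × ed/median(ed); candidates below 30 are thresholded at the local
  minimum of their kernel density, falling back to a fixed cutoff of 5 when
  no interior minimum exists. The algorithm is parameter-free in the common
  case and errs toward reporting nothing when no low-distance cluster exists.
* **Spherical-spline interpolation** uses the Legendre-series kernel
  `g(cosθ) = (1/4π) Σ (2n+1)/(n(n+1))^m P_n`, stiffness `m = 4`, series
  truncated at 50 terms, ridge regularization 1e−5 on the kernel diagonal,
  and the usual zero-sum constraint. Because the spline reproduces constants,
  interpolation weights row-sum to 1 (tested); the operator depends only on
  good channels, so re-interpolation is idempotent.
* **ICA** is applied, never computed: stored mixing/unmixing matrices are
  validated (`U·A ≈ I` on the component subspace) and rejected components are
  projected out. Computing decompositions is out of scope.
* Sample indexing is 0-based half-open `[start, end)` for windows; all
  window parameters are expressed in samples with the sampling rate explicit,
  because second-based round-trips at arbitrary rates are where off-by-one
  errors live.

## The estimation-statistics layer

* **Paired Cohen's d** defaults to mean difference over the average of the
  two condition SDs (the convention of paired estimation plots); `d_z`
  (mean over SD of differences) is available. The two agree in the pure-shift
  case and differ under correlation structure.
* **BCa intervals** use the textbook construction: bias constant
  `z0 = Φ⁻¹(#[θ* < θ̂]/B)`, acceleration from jackknife skewness, adjusted
  percentiles interpolated with quantile type 6. When every bootstrap
  replicate falls on one side of the estimate the bias constant is infinite
  and the plain percentile interval is returned with a warning. At n = 20 the
  BCa interval for a normal mean covers at roughly 0.92–0.93 rather than
  0.95 — the method's documented small-sample behavior, visible in the
  coverage suite, not an implementation artifact (the cross-check against an
  independent implementation agrees to Monte-Carlo error).
* **The permutation test** flips condition labels within pairs. When
  `2^n ≤ n_perm` all flips are enumerated and the p-value is exact (the
  identity flip guarantees p > 0); otherwise Monte-Carlo sampling with the
  add-one correction `(1 + #extreme)/(1 + n_perm)` keeps p strictly positive.
  The test statistic is the paired effect size itself, recomputed per flip
  (condition SDs change under swapping).
* **Repeated-measures correlation** is computed by centering both variables
  within subject; the coefficient is the Pearson correlation of the centered
  variables with the common slope's sign, `df = N_obs − n_subjects − 1`.
  This is algebraically identical to the subject-factor ANCOVA definition
  (the test suite verifies the equality against `aov` sums of squares), and
  unlike a factor-based fit it degrades gracefully to an ordinary
  correlation for a single subject.
* **Power** is exact noncentral-t: `ncp = d√n`,
  `power = P(T′_{n−1, ncp} > t_{1−α, n−1})` one-sided (two-sided adds the
  opposite tail). Power computations default to one-sided: it is the only
  convention consistent with the published planning and post-hoc figures
  this package reproduces. `required_n()` exposes two integer conventions
  and the choice is substantive: the conservative default returns the
  smallest n whose exact power clears the target (22 at d = 0.56, 80%, 5%),
  while `rounding = "nearest"` rounds the continuous noncentral-t root
  (21.135 → 21), the convention behind figures produced by common
  power-analysis software. Reports should state which convention they use.

## Problem sizes used in validation

The test and acceptance suites run at desk scale, chosen once for
Monte-Carlo adequacy: label-operator oracles on 200-sample sequences;
stationary-coverage recovery on 60 s of 62-channel EEG at 250 Hz with
asymmetric 50–100 ms dwells at 4:1 SNR; permutation-test size over 1000 null
replications (n = 10 pairs, exhaustive enumeration); BCa coverage over 500
replications (n = 20, B = 999); and the closed-loop learning analog over 20
seeded sessions of 10 × 20 s blocks at 125 Hz on a 16-channel layout with
gain 2e−4. The full-protocol defaults (10 × 180 s blocks, 62 channels,
250 Hz) run identically, just longer.

## Known limitations

* Templates and electrode geometry are synthetic/idealized; applying the
  package to real recordings requires supplying real template maps and a
  measured montage (`template_set()`, `channel_layout()` accept both).
* Heavy smoothing inflates durations (see above); GEV of smoothed labels is
  slightly below that of raw backfitting by construction.
* The virtual subject is a one-parameter learner on one transition
  probability; it is a test harness for the loop, not a model of cognition.
* File I/O uses delimited text with JSON sidecars; native EEG container
  formats are not read or written.
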