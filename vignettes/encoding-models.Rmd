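---
title: "Point-process encoding models of motor cortex spiking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-process encoding models of motor cortex spiking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

A motor cortex neuron recorded during reaching and grasping spikes
irregularly: only part of its spike-time variability is explained by the
movement itself.  A long-standing hypothesis is that much of the remainder
reflects ongoing collective network dynamics, which are visible in the local
field potential (LFP).  `spikefield` implements the analysis needed to test
this quantitatively: it asks how much single-neuron spiking variability (at
1 ms resolution) is predicted by multiband LFP features, by 3-D reach and
grasp kinematics, by the neuron's own recent spiking history, and —
critically — how much each source adds *conditioned on the others*.
Redundancy here is operational: feature set B is redundant to A if adding B
to a model already containing A does not raise out-of-sample predictive
power.

# The model

Spike trains are binned at $\Delta = 1$ ms, so each bin holds $Y_t \in
\{0,1\}$ and the probability of a spike is $\lambda_t \Delta$ with
$\lambda_t$ the conditional intensity (spikes/s).  The intensity is
log-linear in the covariates,

$$\ln \lambda_t = \mu + A \cdot X_t,$$

and the parameters maximize the per-sample L2-penalized log-likelihood

$$\frac{1}{T}\sum_{t=1}^{T}\left[Y_t \ln(\lambda_t\Delta) -
\lambda_t\Delta\right] - \alpha \lVert A \rVert^2 ,$$

with the baseline $\mu$ unpenalized and every column of the design z-scored
before fitting so the penalty treats all features symmetrically.  The
normalization by $T$ makes $\alpha$ comparable across sessions of different
length.  For a narrow LFP band with analytic signal $z_t$, the feature block
$(|z_t|, \mathrm{Re}\,z_t, \mathrm{Im}\,z_t, \cos\theta_t, \sin\theta_t)$
makes the linear predictor equivalent to cosine tuning
$a\cos(\theta_0 - \theta_t)$ to a preferred phase $\theta_0$ plus amplitude
and analytic-signal coupling; `preferred_phase()` recovers $(\theta_0, a)$
from the fitted cos/sin pair.

# Feature construction

**LFP.**  Eight bands (0.3–2, 2–7, 7–15, 15–30, 30–60, 60–100, 100–200,
200–400 Hz) are extracted with *causal* (forward-only) Butterworth band-pass
filters of prototype order 4.  Causality matters because the unit's own
spike waveform contaminates the LFP recorded on the same electrode: a causal
filter confines that contamination to times after the spike, so the features
cannot "predict" a spike from its own waveform.  The filters are designed
in-package as cascades of second-order sections because the expanded
transfer-function form is numerically unstable in double precision for the
0.3–2 Hz band at 1 kS/s.  The analytic signal is computed over the full
recording block by the frequency-domain Hilbert transform; all features are
delayed by 1 ms as an extra guard.  Narrow bands contribute five columns,
broad bands three (instantaneous phase of a multi-octave band is not a
meaningful quantity), for 32 columns per electrode.

`causality_audit()` quantifies the one remaining non-causal element: it
measures the percentage of the absolute area of the composite impulse
response (band-pass → Hilbert → 1 ms delay, imaginary component) that lies
at negative lags.  The fraction grows as the band's low corner approaches
DC, because the $1/t$ tail of the Hilbert kernel interacts with ever longer
filter responses: with converged integration windows the values are
approximately 2.6% (delta), 0.87% (theta), 0.19% (alpha) and 0.13% (beta),
essentially independent of sampling rate, integration window, and the
band-pass order convention.  Only the beta band (and the faster broad
bands) meet a 0.14% bound; the audit reports per-band values so users can
judge the bands where contamination is physically plausible (spike energy
lives above ~10 Hz) separately from the slow bands where it is not.  First
and last 2 s of each block are excluded from model fitting, where Hilbert
edge effects concentrate.

**Kinematics.**  Wrist position (3-D) and grasp aperture at 240 frames/s
are smoothed and differentiated with Savitzky–Golay kernels (5th-order
polynomial, halfwidth 25 samples), which attenuate content above ~20 Hz and
allow clean down-sampling to 40 S/s.  The "pathlet" feature set samples the
smoothed velocities every 25 ms from 100 ms before to 300 ms after the
current bin (17 lags × 4 channels); the wrist (51-element) and aperture
(17-element) trajectories are separately normalized to unit L2 norm, and
mean speed plus zero-lag position are appended (74 columns).  Features are
computed on the 25 ms grid and held constant across the intervening 1 ms
bins — sample-and-hold does not invent kinematic detail that was never
measured.  Zero-norm (motionless) trajectories map to zero vectors.  A
companion un-normalized position-trajectory set (68 columns) is available
for comparison.  Note these features legitimately see up to 300 ms of
*future* movement; the lag sign is encoded in the column labels.

**Spike history.**  Ten raised-cosine bumps, equally spaced in
$\log(t + 1\,\mathrm{ms})$ with peaks from 2 to 80 ms, tile the preceding
100 ms; each is convolved with the unit's own past spikes, strictly
excluding the current bin.  Early bumps are narrow (refractoriness,
recovery, bursting), late bumps broad (rhythmicity).  Peak height is
normalized to 1 on the sampled lag grid; downstream z-scoring makes the
scale immaterial.  The log-time offset (1 ms) and the peak range are
configurable; any smooth log-spaced family satisfying the same support and
rank properties would serve.

# Evaluation

Predictive power is $PP = 2\,\mathrm{AUC} - 1$, where AUC is the area under
the *convex hull* of the ROC curve for classifying each 1 ms bin as
spike/no-spike from the model's conditional spike probability.  The hull
makes PP range from 0 (chance) to 1 (perfect) on every input.

Fitting uses two-tier cross-validation.  The outer tier is 10-fold: by
default folds are contiguous time blocks (random bin-level folds are
available; contiguous blocks limit optimistic leakage through
autocorrelation).  Within each outer training set, an inner split into two
random halves selects the penalty: for each $\alpha$ in a grid of ten
log-spaced values on $[10^{-9}, 10^{2}]$ plus 0, a model is fit on each
half and scored on the other, the two directions are averaged, and the
best-generalizing $\alpha$ is refit on the full training set (z-scoring
statistics from training data only) and scored on the held-out 10%.  Ties
resolve to the larger penalty.  Per-fold PPs and a pooled PP (one ROC over
all out-of-fold predictions) are both reported.

Chance levels come from block permutation: features are shuffled in 100 ms
chunks relative to the spike train — preserving their autocorrelation while
destroying alignment — and the 95th percentile of the null PP distribution
over (by default) 20 permutations is the chance threshold.  The null fits
reuse the regularization selected by the inner procedure on the first
permutation, so null and real models get the same treatment.  Each
permutation uses a single 90/10 train/test split rather than the full
10-fold machinery; the null distribution needs the location and spread of
chance-level PP, not fold-resolved detail, and this keeps 20 permutations
per unit affordable.

Nested feature sets are compared per unit ($\Delta PP$ = extended − base)
and across the population with a two-sided Wilcoxon signed-rank test
(zero differences discarded; an all-zero comparison reports $p = 1$),
Bonferroni-corrected across however many tests the analysis runs.
Because the cross-validation folds are derived deterministically from the
configuration seed, the same folds underlie every feature set, making the
per-unit comparisons genuinely paired.

# The synthetic-session generator

No public dataset accompanies this analysis, so the generator is a
first-class module that creates sessions with the statistical structure the
method assumes, from a fully specified ground truth:

* **Kinematics** — minimum-jerk point-to-point reaches (0.4–0.8 s long) to
  random targets in a 300 mm workspace at exponentially distributed
  intervals (default 0.4 reaches/s), with a grasp-aperture profile that
  opens toward a 60–90 mm peak late in the reach, closes, and relaxes;
  sampled at 240 frames/s.  The defaults are plausible for unconstrained
  primate reach-and-grasp behavior but are not calibrated to any particular
  dataset.
* **LFP** — per band, band-limited Gaussian noise modulated by a slowly
  varying envelope (rectified 0.5 Hz low-pass noise), plus a $1/f$
  background; default amplitudes fall from 40 µV (delta) to 3 µV
  (200–400 Hz).  The delta-band carrier is a mixture of independent noise
  and the band-filtered wrist speed in proportion `coupling`
  $\in [0,1]$ — the shared drive that makes LFP/kinematics redundancy
  detectable.  The coupled component bypasses the envelope so that
  `coupling = 1` means *fully* movement-driven.  Because the generation and
  feature-extraction filters are both causal, their combined group delay at
  delta frequencies is on the order of a second; the generator therefore
  feeds the coupling path with speed led by 1 s (`speed_lead_s`), so the
  coupled delta component reflects concurrent movement — consistent with
  slow motor potentials accompanying rather than trailing movement.  The
  lead was set from the measured group delay of the filter chain, once.
* **Spikes** — Bernoulli draws per 1 ms bin with probability
  $\min(\lambda_t\Delta, 1)$, where $\ln\lambda_t$ combines the baseline
  (8 spikes/s), weights on the z-scored LFP and pathlet features, and a
  recursive history term: each emitted spike feeds the raised-cosine filter
  back into the intensity of the next 100 ms.  The default history filter
  is strongly refractory at short lags with a mild rebound; default feature
  weights give delta phase tuning at $\theta_0 = 2\pi/3$ (depth 0.4), a
  positive delta analytic-signal weight, a negative beta-amplitude weight
  (firing rises when beta desynchronizes), and speed-dominated pathlet
  tuning.  Pathlet weight bumps are small per lag (0.08 peak) because
  neighboring lag columns are strongly correlated and their contributions
  add almost coherently; the defaults put the total log-rate standard
  deviation near 0.8 and keep intensity clipping far below 0.1% of bins.
* **Populations** — per-unit weights are log-normal jitters of the template
  (sd 0.15) with a small preferred-phase rotation, giving a heterogeneous
  population that shares the session's signals.

What the generator does *not* emulate: spike waveforms and sorting noise,
LFP spike contamination, electrode cross-talk, non-stationarity across
blocks, oscillatory transients with specific phase-amplitude coupling, and
any behavioral structure beyond smooth reaches.  Passing the end-to-end
checks therefore shows the pipeline recovers what it assumes — it does not
certify performance on real recordings.

# Numerical design

The penalized likelihood is smooth and convex, so the optimum is found by
L-BFGS with the analytic gradient (the stated "descent on the penalized
negative log-likelihood" fixes the objective, not the path).  Strict fits
(`fit_ppglm()`) converge at relative objective change below $10^{-9}$ in
double precision and error if the intensity overflow guard (capped at
$10^4$ spikes/s) is active at the solution.  Inside cross-validation, where
thousands of fits only feed rank-based PP scoring, fits run on
single-precision copies of the design with standardization folded into the
likelihood kernel (fitting on z-scored columns equals fitting on raw
columns with $b = A/s$, $b_0 = \mu - \sum_j A_j m_j / s_j$), warm-started
along the penalty path and across folds, at tolerances of $10^{-5}$
(selection) and $10^{-6}$ (refits) — two orders of magnitude above float
rounding noise on the objective.  Line-search termination at the working
precision is treated as convergence-for-scoring; strict fits still reject
it.  Zero-variance columns are dropped with a warning; a column constant
within a fold is left centered at zero.  ROC construction groups tied
scores, includes the (0,0) and (1,1) endpoints, and takes the upper convex
hull by a monotone-chain scan.

Problem sizes in the test suite were chosen to exercise every claim at
desk scale: the parameter-recovery check uses one 600 s session; the
population redundancy check uses one 300 s session with 8 units and
20-permutation chance levels; the shuffle control reuses that session.
With ~10 min of data per session these match typical recording-session
lengths, while unit counts are smaller than a real array yields.

# Known limitations

* The delta-band causality audit honestly exceeds a 0.14% non-causal bound
  (see above); slow-band phase features should be interpreted with the
  audit table in hand.
* Chance thresholds from 20 permutations estimate a 95th percentile from
  20 draws; they are upward-noisy.  More permutations sharpen them at
  linear cost.
* The Wilcoxon comparisons treat units within a session as independent,
  as the source analysis does; shared session signals make them weakly
  dependent.
* The inner two-group split is random at the bin level, which slightly
  favors smaller penalties relative to a blocked split, since the two
  halves are statistically near-identical.
* `coupling` ties only the delta band to movement; gamma/MUA-band
  movement locking is not modeled.

# A minimal session

```{r, eval = FALSE}
library(spikefield)

truth <- ground_truth_spec(coupling = 1)
session <- generate_session(truth, duration_s = 300, n_units = 4, seed = 1)

report <- run_session(
  session, cv_config(seed = 2),
  ladders = c("lfp", "kin"),
  comparisons = list(c("kin", "kin+lfp"), c("kin", "kin+hist")),
  n_perm = 20
)
report$pp_by_unit
report$comparisons
```
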