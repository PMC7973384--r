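---
title: "Hypnodensity correlations and sleep-cycle period estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypnodensity correlations and sleep-cycle period estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypnocycle)
```

## The problem

A night of human sleep is scored, per the AASM convention, as one of five
stages — Wake, N1, N2, N3, REM — for every 30-s epoch. The resulting
hypnogram discards how certain the scorer (human or classifier) was;
a *hypnodensity* series keeps the full probability distribution over the
five stages at every time step. Healthy sleep organizes into ultradian
cycles, a recurring progression through non-REM depth and back to REM,
typically 75–110 min long, and the cycle length is individual. This package
estimates that individual period directly from hypnodensity series, and
provides the surrounding instrumentation: separability analysis of feature
embeddings (GDV), MDS views, plots, generators, and a small sequence
classifier that produces hypnodensities from raw signal.

## The vectorial correlation

For a series of 5-dimensional probability vectors $x_t$, $t = 1..T$, with
per-stage mean $\bar x = \tfrac{1}{T}\sum_t x_t$, the auto-correlation at
lag $\tau$ (in frames) is

$$r_{x,x}(\tau) = \frac{\tfrac{1}{T-\tau}\sum_{t=1}^{T-\tau}
  (x_t-\bar x)\cdot(x_{t+\tau}-\bar x)}
  {\tfrac{1}{T}\sum_{t=1}^{T}\lVert x_t-\bar x\rVert^2},$$

and the cross-correlation between channels $x$ and $y$ replaces the second
factor by $(y_{t+\tau}-\bar y)$ and the denominator by the geometric mean
of the two mean squared deviation norms. Two properties matter in practice:

* $r_{x,x}(0) = 1$ exactly — numerator and denominator coincide at zero lag.
* The normalization is deliberately asymmetric ($1/(T-\tau)$ against
  $1/T$), so $|r|$ can slightly exceed 1 at large lags. We keep the
  formula verbatim and do not clamp; the unit tests pin the implementation
  against a literal double-loop transcription of the sums at $10^{-12}$.

Repeating sleep cycles make the stage-probability pattern recur, so the
auto-correlation shows local side-maxima at multiples of the cycle period.
The lag of the first admissible maximum is the period estimate; a second
maximum near twice that lag corroborates it. Cross-correlations between
EEG channels of the same night peak at lag zero when the channels carry the
same stage sequence — which is also a useful sanity check that any single
channel suffices for staging.

## Peak detection

`detect_local_maxima()` smooths the curve with a centered moving average
(default width 10 min) before searching for interior local maxima, then
snaps each detected peak to the argmax of the *unsmoothed* curve within
half a smoothing width. Smoothing makes detection robust to frame-level
noise; localizing on the raw grid avoids the 2–5-step drift a heavy
smoother causes on asymmetric curves. Peaks below `min_lag` (default
30 min) are excluded — the global maximum at $\tau = 0$ is structural, and
no plausible human sleep cycle is shorter — and peaks need a minimum
prominence (height above the higher flanking saddle).

The prominence default of 0.1 is calibrated on the synthetic generator: on
full-night autocorrelations, true period maxima show prominences of 0.5 and
above, while echo peaks caused by repeated stages within one cycle (the
default template visits N2 twice, producing a shoulder near 0.65 of a
cycle) stay below 0.05. The default sits an order of magnitude from both
regimes; all three detector parameters are exposed.

`windowed_period_track()` repeats the estimate on consecutive parts of the
record to expose non-stationary period lengths. A part should span several
cycles (the function warns below four times the expected period); with
160-min parts, about 1.8 cycles contribute per estimate and part-to-part
scatter of a lag step or two is expected even for stationary nights.

## The synthetic generator

Real polysomnography cannot ship with a package, so every analysis here is
exercised on synthetic data whose structure we control:

* `simulate_hypnogram()` realizes a cyclic night: a fixed within-cycle
  stage template (default N1→N2→N3→N2→REM with dwell fractions
  0.10/0.40/0.25/0.10/0.15), 30-s epochs, brief awakenings inserted at
  2/h. Dwell durations get multiplicative lognormal jitter and are then
  rescaled so **every cycle's total length equals `cycle_period` exactly**:
  jitter moves stage boundaries within a cycle while cycle onsets stay
  strictly periodic. The default jitter of 0.05 shifts boundaries by a few
  epochs per cycle — enough to decorrelate within-cycle fine structure,
  while keeping the night's correlation maximum on the lag step carrying
  the true period; larger jitter (≥ 0.15) makes the realized correlation
  peak itself wander by minutes, at which point no estimator reading the
  curve can report the nominal period to 5-s resolution.
* `simulate_noisy_hypnodensity()` emits, per 5-s frame, a Dirichlet draw
  whose mean is the true stage's one-hot vector blended through a
  diagonally dominant stage-confusion kernel (mass on adjacent stages:
  N2↔N3, N1↔REM, Wake↔N1) and per-channel stage biases. Rows live exactly
  on the probability simplex; at the default concentration of 30 the
  per-frame argmax matches the true stage in ≥ 90% of frames.
* `simulate_multichannel()` drives all channels from one hypnogram with
  independent noise — the construction behind the zero-lag cross-peak
  property.
* `simulate_embeddings()` places isotropic unit Gaussians at equidistant
  centroids (`separation` apart) for GDV calibration.
* `simulate_stage_eeg()` writes toy EEG with textbook spectral signatures
  (alpha in Wake, theta in N1/REM, spindle-band bursts in N2, slow
  oscillations in N3) for the classifier path.

What the generator does **not** emulate: arousal microstructure and
stage-transition grammar beyond the fixed template, inter-night variability
of cycle length within a subject, EMG/EOG context, artifacts with realistic
morphology, or any pathology beyond crude wake insertion. Passing tests
therefore demonstrate the estimator's correctness and its behaviour under
controlled noise — not clinical performance on real polysomnography.

## The GDV

The generalized discrimination value measures how well labeled classes
separate in a feature space. Each dimension is z-scored (population SD)
and scaled by 0.5; dimensions with zero variance are dropped with a
warning. With mean intra-class pairwise Euclidean distance
$\bar d(C_l)$ and mean inter-class distance $\bar d(C_l, C_m)$,

$$\mathrm{GDV} = \frac{1}{\sqrt D}\left[\frac{1}{L}\sum_l \bar d(C_l)
  - \frac{2}{L(L-1)}\sum_{l<m} \bar d(C_l, C_m)\right].$$

0 means non-separable (identical class distributions); −1 is the
perfect-separation convention, attained in the limit of point-like classes
separated along every retained dimension — the 0.5 rescaling factor is what
makes that limit exactly −1. Note that clusters separated along only $k$
of $D$ dimensions plateau well above −1 however far apart they move; GDV
values are comparable across layers of one analysis, not across feature
spaces of different effective dimensionality. `gdv_profile()` evaluates a
list of per-layer embeddings sharing one label vector, the standard view of
how separability deepens along a network.

## MDS views

`mds_project()` uses classical metric scaling (`stats::cmdscale`) on
Euclidean distances — a deterministic eigendecomposition, immune to the
initialization sensitivity that makes t-SNE-style projections unstable.
The seed argument is recorded in the result purely for provenance.
Kruskal's stress-1 is reported, and plots carry the standard caveat that
only relative distances are meaningful.

## The reduced-scale classifier

The classifier module closes the loop raw signal → softmax probabilities →
correlation analysis. Its architecture is the conv/pool/biLSTM/softmax
stack (11 convolutional, 9 max-pooling, 2 bidirectional LSTM layers at
full scale; `scale_factor` shrinks the depth for desk-scale runs). The
desk-scale realization uses fixed random (seeded) convolution kernels and
recurrent weights as a feature extractor and trains only the softmax head,
by multinomial logistic regression (`nnet`). This random-feature design is
deliberate: the package's claims about the module are structural and
property-based — valid simplex output, window/center bookkeeping, layer
census, above-chance accuracy on spectrally signatured synthetic stages,
and a GDV profile whose softmax layer separates better than the raw input —
none of which require learned convolutional features. It makes no claim of
clinical scoring accuracy.

`prepare_training_data()` follows the dataset-level protocol: channels of
one recording are concatenated into a single stream (labels repeated), and
whole recordings — never windows — are assigned to train or test, with the
training size rounded half-down so 68 recordings at 80% give the
conventional 54/14 split.

## Numerical choices and degenerate inputs

* Correlation of a constant series (zero deviation norm) raises a typed
  error rather than returning NaN, which would silently poison peak
  detection downstream.
* Argmax ties in `hypnodensity_to_hypnogram()` resolve to the lowest
  canonical stage index (Wake first) — deterministic, and irrelevant on
  real-valued data.
* Negative cross-correlation lags come from argument swapping
  ($r_{xy}(-\tau) = r_{yx}(\tau)$), not an extended sum.
* Artifact epochs are dropped; by default the remaining frames are
  concatenated onto a contiguous time base (with a warning), because the
  correlation sums assume an unbroken frame index. A `split` policy
  returning per-segment series is available; neither choice is claimed to
  be canonical.
* Row sums are validated to $10^{-6}$; CSV round-trips preserve doubles to
  full precision (`%.17g`).

## Problem sizes in the test suite

The suite exercises full 8-h nights at 5-s resolution (5760 frames,
2880-lag curves) — single runs cost about a second — and uses 50-run
ensembles for the stochastic period-recovery properties, 20 seeds at
500 points/class for GDV calibration, and ~120 windows per class for the
classifier property. These sizes make the stochastic pass criteria
(≥ 90% recovery rates, |GDV| < 0.05) stable across seeds while keeping the
default test run within a few minutes on one CPU.

## Limitations

The period estimator assumes an approximately stationary cycle length;
strongly fragmented sleep (e.g. severe OSAS) destroys the side-maxima
rather than shifting them, and the windowed variant only coarsely tracks
drift. The correlation normalization follows the defining formulas exactly,
so values at lags approaching the record length are upward-biased and
should not be compared across very different `max_lag` settings. All
empirical statements in this vignette are the ones the test suite and the
acceptance script themselves compute on synthetic data.
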