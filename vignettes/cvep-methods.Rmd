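---
title: "Methods: filter-bank CCA decoding of code-modulated VEPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filter-bank CCA decoding of code-modulated VEPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvepr)
```

## The problem

A code-modulated visual evoked potential (c-VEP) speller encodes each of
K on-screen targets with a lagged copy of one pseudorandom flicker code.
The user gazes at a target; occipital EEG then carries a response locked
to that target's code, and the decoder identifies the gazed target by
correlating the incoming multichannel signal with per-target templates.
`cvepr` implements the full chain — code generation, stimulus
scheduling, a synthetic EEG generator, the filter-bank CCA
template-matching classifier with its online sliding-window rule, and
the evaluation tooling (leave-one-block-out accuracy curves, information
transfer rate, simulated copy-spelling).

## Maximal-length sequences over GF(p)

Codes are p-ary maximal-length sequences (m-sequences) produced by a
Fibonacci-form linear-feedback shift register with cells
$(R_{N-1},\dots,R_0)$: each clock pulse shifts $R_i \to R_{i-1}$, emits
$R_0$, and loads $R_{N-1} \gets \sum_j a_j R_j \bmod p$.  The weights
$a_j$ are the coefficients of the generator polynomial.  The two shipped
codes are the binary sequence of x⁶ + x⁵ + 1 with seed (1,1,0,1,0,1)
(period 2⁶−1 = 63) and the quintary sequence of x³ + 3x + 2 with seed
(0,3,0) (period 5³−1 = 124).  `msequence()` clocks the register until
the state first returns to the seed and *fails loudly* if the observed
period is not $p^N-1$: a silent fallback to a different register
convention could produce a valid-looking but wrong sequence.

Two classical properties are asserted exactly in the tests: the balance
property (each nonzero digit occurs $p^{N-1}$ times per period, zero one
time fewer) and, for the binary sequence under a ±1 mapping, the
two-level cyclic autocorrelation.  On the latter the package records a
deliberate sign: the normalised circular inner product at every nonzero
lag is **−1/n**, not +1/n — the brute-force oracle settles this, and the
negative sign is the classical result.  Under the Pearson normalisation
(mean-centred, peak 1 at lag zero) the constant becomes −1/(n−1) = −1/62.

For the quintary sequence under the equally spaced grey-level mapping
d/(p−1), the autocorrelation profile is −1/61 at every nonzero lag
except two special phases, lags 31 and 93, where it is +30/61 ≈ 0.49.
These are the scalar-multiple phases (the lag-31 shift equals the
digitwise multiplication of the sequence by 3 mod 5, lag 93 by 2).
Whether those phases appear "anticorrelated" depends entirely on the
digit-to-value mapping — under a signed-residue mapping they correlate
at 0 — so the package determines them empirically via the oracle rather
than hard-coding an expectation.  The speller's lags 4·(i−1) ≤ 28 stay
clear of both.

## Stimulus scheduling

Digits map to opacities d/(p−1) (alpha blending of white over black:
five shades of grey for p = 5, black/white for p = 2); the opacity
updates every monitor frame.  Targets use left circular shifts of the
base code in steps of 4 frames.  Trials repeat the code 2/4/8 times
(binary) or 1/2/4 times (quintary) at 60/120/240 Hz, keeping durations
near two seconds: 2.1 s = 1260 samples and 2.067 s = 1240 samples at
the 600 Hz sampling rate.

At 600 Hz sampling, a 60 Hz frame spans exactly 10 samples; at 240 Hz
the 2.5-sample average is realised by the floor rule (sample t takes
frame ⌊t·rate/fs⌋), giving alternating 3- and 2-sample spans.  This
deterministic nearest-frame assignment needs no resampling filter and
preserves ordering.  Timing is ideal — no dropped frames, no monitor
latency, and opacity is treated as linear luminance drive (no display
gamma model): the package makes no claim about the original display's
gamma behaviour.

## The synthetic EEG generator

No recordings are distributable for this paradigm, so every downstream
stage is exercised against a generator that emulates the protocol: 16
channels at 600 Hz, 6 blocks × 8 targets = 48 labelled trials per
session, online streams delivered in 30-sample blocks with 2 s pauses.

The evoked model is deliberately simple and fully documented:

* **Drive.** The first difference of the per-sample opacity trace,
  taken cyclically.  VEPs respond to visual *change*, not absolute
  luminance; this also makes the quintary stimulus (many ±0.25 steps)
  gentler per event than the binary one (±1 steps), qualitatively
  matching its subtler appearance.
* **Kernel.** A gamma-shaped impulse response
  $h(t) \propto t^{a}e^{-t/\theta}$ with its single positive peak at the
  configured latency (default 0.10 s, a typical early VEP latency),
  decay constant 0.02 s, support 0.25 s, unit energy.
* **Circular convolution.** Because the flicker is periodic, the evoked
  component is the kernel circularly convolved with the drive.  This
  makes noise-free trials of lagged targets *exact* cyclic shifts of
  one another — the same symmetry the code construction promises — and
  the property is asserted at 60 Hz, where a 4-frame lag is exactly 40
  samples.
* **Optional nonlinearity.** A static saturation
  $r\tanh(x/r)$ (r = the source RMS), off by default, reproduces the
  qualitative observation that real responses to orthogonal codes have
  nonorthogonal autocorrelations.
* **Topography.** A smooth gain ramp (0.4 to 1) standing in for the
  posterior gradient of real VEP topographies; it is configuration, not
  physics.
* **Noise.** Per channel, white Gaussian noise shaped in the frequency
  domain to $f^{-\beta}$ (β = 1) plus a 10 Hz alpha bump and a small
  white floor, normalised to unit expected power and scaled so that the
  ratio of mean evoked power to mean noise power across channels equals
  `snr_db`.  The default is 0 dB, a stand-in chosen because the paradigm
  reports no amplitude or SNR figures; acceptance therefore rests on
  recovery curves, not on matching human accuracies.
* **Determinism.** One global seed; per-trial and per-segment seeds are
  derived from it by a fixed linear-congruential mix, so any trial can
  be regenerated in isolation.

What the generator does **not** emulate: volume conduction from real
sources, eye/EMG artifacts, inter-trial nonstationarity, latency
jitter, photosensitivity.  Passing tests on synthetic sessions
demonstrate that the decoding chain is implemented correctly and
recovers known structure at realistic SNR; they do not certify
performance on human EEG.

## Preprocessing

The acquisition chain is emulated by a 2–100 Hz Butterworth bandpass
(4th order; the original report does not state an order) plus a 50 Hz
notch (second-order constrained biquad, Q = 35 — "around 50 Hz" made
concrete).  Before classification a three-band filter bank is applied:
8–60, 12–60 and 30–60 Hz, each an 8th-order Butterworth bandpass.

Numerical choices: the designs come from `signal::butter`; direct-form
coefficients were verified stable at 600 Hz for all four bands (largest
pole magnitude 0.993, impulse responses decay below 1e−29), so no
second-order-section cascade is needed.  Filtering is **causal** by
default — an online system cannot be acausal, and causality buys a
useful exactness: filtering then truncating a buffer equals truncating
then filtering, so cross-validation can pre-filter trials once and
truncate per window with no approximation.  A zero-phase
(forward–backward) mode is available for offline exploration.  Filter
state is reset per trial and per buffer evaluation, matching a decoder
whose buffer is cleared after each decision; the online rule filters
the current buffer contents at every evaluation rather than filtering
incrementally.

## The classifier

For target k and subband m, the template $X_k^{(m)}$ is the mean of the
class-k training trials after subband filtering.  The spatial filter
$w_k^{(m)}$ is the first canonical weight vector (EEG side) of a CCA
between the class-k trials concatenated along time and the template
tiled to the same length.  Concatenation (rather than trial averaging)
was chosen for the data side because it uses all trial variance.
Covariance blocks receive a ridge of 1e−8 × mean diagonal — enough to
handle the rank-one covariances of noise-free synthetic data without
biasing realistic fits.  Canonical weights are sign-ambiguous; the sign
is fixed so the projected data correlate positively with the projected
template, and weights are normalised (the ensuing correlations are
scale-invariant anyway, which a test asserts).

Classification correlates stacked projections: the buffer Y (first
$n_y$ samples) is projected through *all* K spatial filters, the K
projections are stacked into one vector, the same is done with target
k's template truncated to $n_y$ columns, and $\tilde\lambda_k^{(m)}$ is
the Pearson correlation of the two stacked vectors.  Stacking in class
order is one of two equivalent conventions — any common ordering of the
two sides yields the same correlation, which is asserted as a test
rather than assumed.  Subband values are averaged with equal weights
into $\lambda_k$, and the decision is the argmax, ties broken
deterministically toward the lowest index.

**Online rule.** The amplifier delivers 30-sample blocks; the buffer
grows block by block up to the template length n, then slides FIFO
(the oldest 30-sample block is discarded — the only reading of
"shuffled out" consistent with a fixed-length window).  After each
block the subband-averaged correlations are evaluated; an output is
emitted only when the gap between the highest and second-highest
correlation exceeds the threshold (default 0.15, exposed as a scalar
because the original system allowed slight per-user adjustment).  On
emission the buffer is cleared and a 2 s gaze-shift pause begins during
which incoming blocks are discarded.

## Evaluation

* **Leave-one-block-out CV** (`cvep_loocv`): 6 folds under the default
  protocol; each fold trains on 5 blocks (40 trials) and classifies the
  8 left-out trials at windows up to 1 s.  Accuracies are reported in
  percent, per fold and averaged.
* **ITR** (`itr`): the Wolpaw-style bits/min with continuous extension
  at p = 1 and clipping to zero below chance.
* **Copy-spelling** (`simulate_spelling`): the two-step letter-group
  interface reduced to its selection arithmetic — 26 letters in four
  7-letter groups, one group selection plus one letter selection per
  character, UNDO on target 8.  A misclassification is recovered by one
  UNDO intent followed by a restart of the current letter, so a
  letter-stage error costs three extra selections and a group-stage
  error two.  Accuracy counts every selection, the wrong one included,
  matching the "correct/total selections" definition.  Per-selection
  time includes the flicker actually consumed plus the 2 s gaze shift.
  If the threshold is never crossed within a 10 s flicker cap the
  current argmax is emitted so the task always terminates; with
  default settings decisions arrive well before the cap.

## Problem sizes and test design

The test suite builds everything programmatically.  Structural and
algebraic tests use a miniature period-7 code (x³ + x + 1) with 3–4
channels so they run in milliseconds; protocol-level tests use one full
48-trial binary/60 Hz session at 0 dB shared across files.  The
recovery suite runs 20 independent sessions per SNR level over
{−10, −5, 0, +5} dB and checks that mean LOOCV accuracy at 1 s windows
reaches 95% at 0 dB and is non-decreasing in SNR; these sizes are the
package's chosen balance between statistical stability and a test suite
that completes in a few minutes.  Correlation algebra is checked against
explicit-loop oracles to 1e−12; the CCA implementation is cross-checked
against `stats::cancor` on random data.

## Known limitations

* The generator's realism is intentionally limited (see above); the
  recovery thresholds say nothing quantitative about human accuracy.
* The online false-emission rate on pure noise is substantial at small
  buffer lengths (a 30-sample buffer can produce a correlation gap
  above 0.15 by chance); the original rule has the same exposure, and
  the package reports rather than suppresses it.
* Non-integer samples-per-frame (240 Hz) breaks the exact
  cyclic-shift symmetry between lagged targets; classification still
  works, but the exactness test is specific to 60 Hz.
* The quintary trial length 1240 is not a multiple of the 30-sample
  block, so a full online buffer holds 1230 samples; templates are
  truncated to the buffer length at every evaluation, so no special
  case is needed.
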