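# cvepr

Analysis tools for **code-modulated visual evoked potential (c-VEP)
brain-computer interfaces**. In a c-VEP speller, each of K on-screen
targets flickers according to a lagged copy of one pseudorandom code;
the EEG of a user gazing at a target carries a response locked to that
target's code, and the decoder identifies the target by correlating the
incoming signal with per-target templates. `cvepr` implements the whole
chain:

* **Codes** — p-ary maximal-length sequences (m-sequences) from
  Fibonacci linear-feedback shift registers over GF(p), with
  period/balance verification, cyclic autocorrelation (FFT-based, with
  Pearson and classical inner-product normalisations), cyclic run
  lengths, and lagged code sets. Shipped defaults: the binary 63-bit
  sequence of x⁶ + x⁵ + 1 and the quintary (five grey levels) 124-digit
  sequence of x³ + 3x + 2.
* **Stimulus** — digit-to-opacity mapping d/(p−1), per-frame schedules
  at 60/120/240 Hz refresh rates, trial timing, and expansion to the
  600 Hz EEG sampling grid.
* **Synthetic EEG** — 16-channel sessions (6 blocks × 8 targets) and
  continuous 30-sample-block online streams with a gamma-kernel evoked
  response driven by luminance change, 1/f + alpha-bump + white noise
  at a configurable SNR, and full seed determinism.
* **Classifier** — per-target, per-subband templates and CCA spatial
  filters over a three-band Butterworth filter bank (8–60, 12–60,
  30–60 Hz); ensemble correlations of stacked projections, subband
  averaging, argmax decisions; an online sliding-window rule (30-sample
  blocks, FIFO buffer, 0.15 correlation-gap threshold, 2 s gaze-shift
  pause).
* **Evaluation** — leave-one-block-out cross-validation accuracy
  curves, Wolpaw-style information transfer rate, and simulated
  copy-spelling through the two-step letter-group interface.

The decision statistic for a buffer Y of length *n_y* is, per subband
*m*,

λ̃ₖ⁽ᵐ⁾ = ρ( [Yᵀw₁⁽ᵐ⁾; …; Yᵀw_K⁽ᵐ⁾], [Xₖ⁽ᵐ⁾ᵀw₁⁽ᵐ⁾; …; Xₖ⁽ᵐ⁾ᵀw_K⁽ᵐ⁾] ),

averaged over subbands, λₖ = (1/M) Σₘ λ̃ₖ⁽ᵐ⁾, with C = argmaxₖ λₖ; the
ITR is B = [log₂K + p log₂p + (1−p) log₂((1−p)/(K−1))] · 60/t bits/min.

## Worked example

```r
library(cvepr)

codes   <- code_set(binary_msequence())          # 8 lagged 63-bit codes
cfg     <- cvep_sim_config(snr_db = 0, seed = 7) # 16 ch at 600 Hz, 0 dB
session <- simulate_session(codes, cfg)
session
#> Training session: 6 blocks x 8 targets = 48 trials, binary pattern
#> at 60 Hz (1260 samples/trial)

model <- cvep_fit(session)
model
#> c-VEP filter-bank CCA model: 8 targets, 3 subbands, 16 channels,
#> templates of 1260 samples at 600 Hz
#>   online rule: 30-sample blocks, threshold 0.15, 2 s gaze shift

cvep_loocv(session, windows = seq(0.2, 1, by = 0.2))
#> Leave-one-block-out CV: 6 folds (binary pattern, 60 Hz)
#> Mean accuracy (%) by window:
#> 0.20s 0.40s 0.60s 0.80s 1.00s
#>  97.9 100.0 100.0 100.0 100.0

simulate_spelling("POWERFUL", model, codes, cfg, seed = 7)
#> Copy-spelling 'POWERFUL': 18/20 selections correct (90.0%),
#> 43.0 s total, 62.9 bits/min
```

The LOOCV numbers are fold-averaged percentages of correctly classified
left-out trials per classification window. In the spelling run, each
letter costs a group selection plus a letter selection; the two
misclassified selections each triggered an UNDO-and-redo recovery, and
the reported rate folds accuracy and mean selection time (flicker plus
the 2 s gaze shift) into bits per minute.

Small closed forms behave as they should:

```r
itr(8, 1, 60)    # 3 bits/min: a perfect 8-way choice once a minute
#> [1] 3
unique(round(cyclic_autocorrelation(binary_msequence(),
        mapping = function(d) ifelse(d == 1, 1, -1),
        normalize = "inner")$value[-1], 6))
#> [1] -0.015873     # the two-level m-sequence profile, -1/63
```

`cvep_pipeline(list(pattern = "quintary", refresh_rate = 120, seed = 1),
out_dir = "run1")` runs codes → schedules → session → fit → LOOCV →
spelling from one configuration (YAML/JSON accepted) and writes the
resolved config, report JSON and CSV curves next to the results.

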