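---
title: "Two-timescale feature extraction for heart-sound classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-timescale feature extraction for heart-sound classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcglstf)
```

## The problem

Auscultation screens for heart disease by listening for two things: the
fundamental heart sounds S1 ("lub", closing of the atrioventricular valves)
and S2 ("dub", closing of the semilunar valves), and anything else —
murmurs, clicks, irregular rhythm — between them. A phonocardiogram (PCG)
records this signal digitally, and machine-learning pipelines typically cut
each recording into short fixed-length windows, extract features per window,
and classify the windows as normal or abnormal.

A window, however, knows nothing about the recording it came from: rhythm
regularity, the durations of systole (S1 to S2) and diastole (S2 to the next
S1), and how cleanly the fundamental sounds stand out of the background are
properties of the *whole* recording. `pcglstf` implements a two-timescale
representation: 27 **short-term features** computed on five-second fragments
and 6 **long-term features** computed once per recording and appended to
every one of its fragments, giving a 33-dimensional *long short-term*
(LSTF) vector per fragment.

## Segmentation of the fundamental heart sounds

Long-term features require knowing where S1 and S2 are. The segmentation
chain is:

1. **Low-pass filter.** Fundamental heart sounds and murmurs live below a
   few hundred Hz. Default: 4th-order Butterworth, 400 Hz cutoff, applied
   forward–backward (`signal::filtfilt`) so the filter delays nothing —
   envelope peak *times* are what the rest of the pipeline consumes. At the
   2000 Hz working rate, 400 Hz keeps the murmur band while removing
   broadband noise.
2. **Envelope.** The method of envelope extraction is a design choice; we
   use the normalized average Shannon energy, the standard PCG gating
   envelope: amplitudes are normalized by the recording maximum, and each
   20 ms frame (10 ms hop) contributes
   \(-\tfrac1M \sum x^2 \log x^2\). Shannon energy compresses loud
   components and suppresses faint ones, which makes the soft S2 comparable
   to the loud S1. The result is non-negative and invariant to recording
   gain.
3. **Candidate peaks.** All local envelope maxima at or above 30% of the
   envelope maximum. A relative threshold keeps detection
   amplitude-scale-free.
4. **Extra-peak rejection.** Physiology bounds a cardiac cycle to
   400–1500 ms (40–140 bpm), so: (a) two peaks closer than 50 ms cannot
   both be heart sounds — the smaller is rejected; (b) more than two peaks
   inside a 400 ms span exceed what one cycle (S1 + S2) can produce — the
   smallest of the cluster is rejected, repeatedly, until at most two
   remain; (c) a gap longer than 1500 ms means true heart sounds sit below
   the threshold — the threshold is lowered by a factor of 0.8 (floored at
   5% of the envelope maximum) *over that gap only*, peaks are re-detected
   there, and the rules re-run. The scan iterates to a fixed point, so the
   operation is idempotent and the output never contains two peaks closer
   than 50 ms.

   A note on rule (b): a literal "reject the smaller of any two peaks
   50–400 ms apart" would delete one member of every legitimate S1–S2 pair,
   since systole is itself ≈ 300 ms. We therefore apply the 400 ms
   constraint to *triples*, which is the weakest reading that still removes
   within-cycle spurious peaks while preserving each cycle's S1–S2 pair.
5. **Parity labelling.** Retained peaks alternate S1, S2, S1, …; the open
   question is which peak starts. We use the physiological prior that
   systole is shorter than diastole at rest: of the two parities, the one
   whose S1→S2 intervals have the smaller mean is chosen. An exact tie
   falls back to "first peak is S1" with a warning. This prior fails in
   tachycardia where diastole shortens below systole; the simulator
   therefore draws systole as a *fraction* of the cycle (30–45%), keeping
   the prior valid at every heart rate it generates.

## The features

**Short-term (27 per fragment).** Fourteen time/statistics/energy/frequency
descriptors — mean, median, population standard deviation, mean absolute
deviation, quartiles by the \((n+1)/4\) rank rule with linear interpolation,
IQR, population (non-excess) skewness and kurtosis, Shannon entropy of the
normalized absolute-amplitude distribution, spectral entropy of the
normalized one-sided power spectrum, the argmax frequency of the one-sided
FFT magnitude, that maximum magnitude, and the fraction of total power in
the argmax bin — plus 13 MFCCs. Population (divide-by-\(N\)) moments are
used deliberately: the feature definitions are stated over the full
fragment as a population, not as estimators of something larger. The two
entropy features are computed on *normalized* distributions so that they are
scale-invariant and non-negative; the raw sum \(\sum x \log x\) is neither
defined for negative amplitudes nor scale-free.

**MFCCs.** 25 ms Hamming-windowed frames, 10 ms hop, periodogram power
spectrum, 26 triangular mel filters spanning 0 Hz to Nyquist, log energies
(floored at machine epsilon so silent frames stay finite), orthonormal
DCT-II, coefficients 1–13 kept — including the 0th-order (log-energy)
coefficient as `mfcc_1`, and a fragment's value is the mean over its frames.
Frame length, hop, filter count and coefficient count sit in the
`[short_term]` config block; whether to include the 0th coefficient and
whether to average over frames are genuinely open conventions, and the
chosen ones are recorded here rather than silently assumed.

**Long-term (6 per recording).** Mean and population standard deviation of
the systolic (S1→S2, \(N\) terms) and diastolic (S2→next S1, \(N-1\) terms)
intervals in ms; the fraction of candidate peaks surviving rejection; and
the ratio of the mean envelope amplitude of retained peaks to that of all
candidates. The two rejection ratios are deliberately named "retained":
their defining formulas divide post-rejection quantities by pre-rejection
totals. Candidate counts include any peaks surfaced by threshold
refinement, so the count ratio stays within (0, 1]. All six features are
invariant to a global time shift of the events.

## Feature pooling and selection

The LSTF vector is `[27 short-term | 6 long-term]`; all fragments of a
recording share the trailing block. Features are ranked by neighborhood
component analysis (NCA): per-feature weights \(w_r\) parameterize the
distance \(d_{ij} = \sum_r w_r^2\,|x_{ir} - x_{jr}|\), and the objective is
the expected leave-one-out accuracy of a stochastic 1-NN classifier with
neighbor probabilities \(p_{ij} \propto e^{-d_{ij}}\), minus
\(\lambda \sum_r w_r^2\). Features are z-scored inside NCA; optimization is
L-BFGS-B with analytic gradients from an all-equal start, so weights are
deterministic — the `seed` only governs the optional row subsample (default
cap 500 rows) that bounds the \(O(n^2 p)\) objective. The default
\(\lambda = 1/n\) applies to the *mean* leave-one-out accuracy; at that
strength, label-independent features are driven well below informative
ones.

Five feature sets are built from the ranked table: `STF` (27), `LTF` (6),
`LSTF` (33), `SSTF` (selected short-term) and `SLSTF` (selected short-term
plus all six long-term — long-term features are always kept in the reduced
merged set by definition). The default selection keeps features whose
weight exceeds the mean weight; `select_top_k()` instead pins the
short-term cardinality (16 is the conventional benchmark size, giving
SLSTF = 22). When the mean-weight threshold leaves *no* short-term feature
— which happens when the long-term block dominates, precisely the regime
the representation is designed around — `run_pipeline()` falls back to the
top-16 with a warning rather than failing the four reduced-set analyses.

## Classification protocol

Twenty-two classifier presets across five families (decision trees, naive
Bayes, SVMs, KNN, ensembles) mirror the common fine/medium/coarse preset
vocabulary; the mapping to concrete hyperparameters lives in
`classifier_preset()` and is part of the package's versioned surface.
Internals are delegated: trees to `rpart`, Gaussian NB and SVMs to `e1071`,
bagging to `randomForest`, gradient boosting to `xgboost`, LDA to `MASS`.
Kernel NB, distance-weighted/cosine/cubic KNN, random-subspace ensembles
and undersampled boosting are small in-package learners because no
installed library exposes those exact variants.

Splits are stratified 70/30. The default `fragment` mode splits fragment
rows independently — the conventional protocol for this benchmark — which
lets fragments of one recording fall on both sides; since long-term
features are constant within a recording, this leaks recording identity
and inflates validation accuracy. `recording` mode keeps recordings intact
and is the leakage-safe alternative; the package defaults to the
conventional protocol and documents the caveat rather than silently
changing the experiment. Feature z-scoring uses training-split statistics
only.

## The simulator and what passing means

`synth_spec()`/`generate_recording()` build recordings as Gaussian-windowed
sinusoids — S1 at 60 Hz over ~60 ms, S2 at 90 Hz over ~40 ms at 0.7× the S1
amplitude — placed at cycle boundaries with per-event Gaussian jitter
(default sd 5 ms), plus white noise at a stated SNR. Abnormal recordings
add a systolic murmur: 150–400 Hz band-passed noise gated to the S1–S2
interval with raised-cosine edges. The study conditions
(`default_synth_ranges()`): 20 s recordings, 60–120 bpm, systole 30–45% of
the cycle, SNR 20–30 dB, murmur amplitude 0.25–0.5 of S1.

The simulator emulates what the pipeline *depends on* — pulse-train
periodicity, systole/diastole asymmetry, murmur energy confined to systole,
broadband noise — and not what real auscultation adds: sensor and site
variability, lung and friction artifacts, split S2, S3/S4, clicks, varying
murmur grades and timing, or label noise. Validation on it therefore shows
that segmentation, the feature formulas, selection and the classifier
harness are implemented correctly and recover planted ground truth; it does
not certify clinical accuracy, and the near-ceiling accuracies it produces
(its two classes are separated far more cleanly than clinical data) should
not be read as benchmark performance. On such ceiling-separable data the
pooled-versus-short-term comparison is reported as a non-degradation
direction over the five family-best presets, averaged across five
split/train repetitions.

## Numerical choices and problem sizes

* Resampling is polyphase FIR (`signal::resample`) to the 2000 Hz dataset
  convention, with the rate ratio converted by continued fractions.
* Amplitudes are not normalized at read time (the 30% threshold is already
  relative); a config flag enables per-recording max-abs normalization.
* Event times are reported in ms from recording start; sample indices are
  0-based; fragment windows are half-open \([t, t+5\,\mathrm s)\), and a
  trailing remainder shorter than 5 s is dropped.
* Envelope peak times are quantized to the 10 ms hop; interval features
  inherit that quantization, which is why simulated interval recovery is
  asserted at the 15 ms level rather than at sample resolution.
* Degenerate inputs degrade softly with warnings: constant fragments
  (skewness/kurtosis 0), all-zero fragments (floored MFCC logs), recordings
  shorter than one window (zero fragments); segmentation failure on one
  recording excludes it from the pipeline run instead of aborting.
* Validation problem sizes, chosen to exercise every stage at meaningful
  statistics: 50 simulated recordings for segmentation/interval recovery,
  20 seeded runs of n = 500 × 10 tables for selection sanity, and a
  200-recording (100/100) dataset — 800 five-second fragments — for the
  classifier ablation and a label-permutation chance control.

## Known limitations

* The parity prior (systole < diastole) mislabels S1/S2 in sustained
  tachycardia; no pitch- or energy-based disambiguation is attempted.
* Rule (c)'s threshold refinement searches only the offending gap; a
  recording whose S2 is globally below 5% of the envelope maximum will
  segment as S1-only and typically fail the 4-peak minimum.
* MFCCs use a single fixed analysis configuration; no delta coefficients.
* The classifier preset mapping approximates an external toolbox's named
  presets with documented hyperparameters; it is a faithful vocabulary, not
  a bit-compatible reimplementation.
* WFDB support covers single-signal format-16 records, the layout used by
  public heart-sound corpora; multi-signal records take the first channel
  with a warning.
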