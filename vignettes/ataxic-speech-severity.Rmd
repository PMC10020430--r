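---
title: "Automated severity assessment of ataxic speech: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated severity assessment of ataxic speech: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

Ataxic dysarthria — the speech disorder of cerebellar disease — presents as
imprecise articulation, irregular rhythm, a monotone pattern, and a usually
reduced speech tempo that can abruptly accelerate with loudness bursts
("explosive voice"). Clinically its severity is rated on item 4 of the Scale
for the Assessment and Rating of Ataxia (SARA): an integer 0 (normal) to 6
(anarthria) scored by intelligibility. `ataxvoice` implements an automated
counterpart: it extracts prosodic and lexical features from three
standardized recordings per assessment — free speech (at least 30 s),
counting from one to ten and back, and 10 s of repeating the syllable pair
"PATA" as fast and clearly as possible — and predicts the item-4 score (0-5;
anarthric patients cannot perform the tasks and are excluded) with a
gradient-boosted tree ensemble. Because clinical speech recordings are
identifying and typically cannot be shared, the package also ships a
severity-parameterized speech simulator, so that every stage of the pipeline
is exercised end to end by synthetic data.

## Pipeline and models

### Preprocessing

Each recording is resampled to a canonical 16 kHz mono form (Fourier-domain,
band-limited), peak-normalized to 0.99, and denoised by spectral
subtraction:

1. An energy-based voice activity detector marks analysis frames (25 ms
   Hann, 10 ms hop — the single STFT geometry used package-wide) as speech
   or voiceless. The threshold on frame RMS is the geometric mean of its
   10th and 90th percentiles. Two degenerate regimes need explicit rules:
   if P10 is exact digital zero the geometric mean collapses, so P10 is
   floored at `1e-4 * P90`; and if every frame clears the threshold (a
   constant-amplitude signal), the quietest 10% of frames are forced
   voiceless so a noise estimate always exists. An all-zero recording is
   all-voiceless.
2. The noise profile is the per-frequency-bin mean STFT magnitude over the
   voiceless frames. We read "subtracting the mean energy of the silent
   parts" as per-bin magnitude subtraction — the standard, well-posed
   variant — with a multiplicative floor: each magnitude `m` becomes
   `max(m - noise_bin, 0.02 m)`. The floor avoids negative magnitudes and
   musical-noise zeros. Phase is kept and the signal is reconstructed by
   weighted overlap-add; reconstruction is exact (to rounding) wherever the
   squared-window overlap is positive, which the implementation guarantees
   over the whole original extent by padding before the transform.

Mean-magnitude subtraction cannot remove the Rayleigh fluctuation of noise
magnitudes around their mean: on pure stationary noise the residual RMS is
empirically about a third of the input, and the tests freeze 0.4 as the
bound. What matters downstream is that tone-in-noise SNR strictly improves
and that voiceless-frame energy never increases, both of which are asserted.

### Prosodic features (39 per task, 117 per assessment)

The published feature set is described by family but never enumerated (part
of it is proprietary), so this package fixes an open, documented inventory
that reproduces the published dimensionality — 39 per task × 3 tasks = 117:

* **21 spectral summaries.** Six per-frame descriptors of the magnitude
  spectrogram — centroid, bandwidth, 85% rolloff, flatness, positive flux,
  RMS — each aggregated by mean, SD and IQR over frames, plus the RMS
  dynamic range (P95 − P5), the least-squares slope of the centroid over
  time, and the flux P90. Frames with zero total magnitude are defined to
  have centroid 0 and flatness 1.
* **11 rhythm aggregates.** The onset envelope is the half-wave-rectified
  first difference of `log(1 + magnitude)` summed over bins. From it, a
  Fourier tempogram (magnitude STFT of the envelope; 4 s window, 0.5 s hop,
  tempo axis 0.25-30 Hz) and an autocorrelation tempogram (windowed,
  lag-normalized) are computed. Aggregates measure average and variability
  of rhythmicity: mean and CV of the per-window tempogram peak, dominant
  rate and salience of both tempograms, the Shannon entropy of the
  normalized time-averaged autocorrelation tempogram (rhythm irregularity),
  the SD of per-window dominant rates, and envelope peak-rate/strength
  statistics.
* **7 band tempo features.** The time-averaged Fourier tempogram is scanned
  in three modulation bands — word 0.5-2 Hz, syllable 2-8 Hz, sub-syllable
  8-30 Hz, spanning conversational word, syllable and phone rates — for
  peak tempo and salience, plus the pause ratio (fraction of envelope
  frames below 10% of the envelope P90).

**Numerical tie-break.** A perfectly periodic impulse train places equal
mass on every harmonic of the Fourier tempogram and on every period multiple
of the autocorrelation; floating-point noise would otherwise pick an
arbitrary harmonic. Peak-picking therefore treats rows within a relative
1e-6 of the maximum as tied and resolves ties to the fundamental — the
lowest tempo for harmonic stacks, the shortest lag (highest tempo) for
period multiples.

### Lexical features (8 per task, 24 per assessment)

Lexical features are computed from a per-word transcript with probabilities
behind a pluggable transcriber contract. The shipped `mock_transcriber()`
reads sidecar JSON files (what the simulator writes); `external_transcriber()`
adapts any real speech-to-text engine. A missing engine or sidecar is a
typed capability error, never a silent empty transcript. The eight features
are: detected-word and real-word rates (per second, so recordings of
different lengths are comparable — raw counts are recoverable from the
logged duration), their ratio, word-duration mean and SD, and the mean, SD
and minimum of the word probabilities. The **confidence score** — the
arithmetic mean of all word probabilities — is the transcript-internal
intelligibility measure: no target text is needed. Real-word lookup is a
case-insensitive word list (German numerals plus a small common-word set
built in; full dictionaries load from a plain-text file). Lexical features
are computed for all three tasks, including PATA where the real-word ratio
is ~0 by construction.

### Model and evaluation

Features (141 named columns) and integer labels 0-5 form the dataset; label
6 is rejected at ingestion. Splitting is subject-grouped (follow-up
assessments of one subject always travel together) and label-stratified by
interleaved dealing: holdout subjects first, the rest round-robin into k
folds, deterministic given the seed. With 70 single-assessment subjects,
hold-out 10 and 6 folds this reproduces the pooled-validation-60 /
hold-out-10 design.

The classifier is a 6-class gradient-boosted tree ensemble with a softmax
objective, written for this package in C++ (no suitable boosting library is
available in the target environment): exact greedy splits, Newton leaf
weights with L2 regularization λ = 1, depth-3 trees, 200 rounds at learning
rate 0.1 — small-sample-safe defaults, all exposed in the config. Training
is deterministic (features scanned in order, first strictly better split
kept), so identical runs are byte-identical. Ordinal labels are handled as
classification rather than regression because the clinical readout is a
discrete confusion matrix; the ±1 tolerance is applied to integer labels.

Evaluation reports, for the pooled out-of-fold predictions and once for the
hold-out set: exact accuracy, ±1-tolerance accuracy, Spearman rank
correlation (average ranks; undefined on constant input and reported as
missing), percentile bootstrap 95% CIs (2000 resamples; degenerate rank
resamples skipped and counted), and a label-permutation test of the ±1
accuracy: `p = (1 + #{permuted >= observed}) / (1 + n_perm)`, with a
normal-approximation z from the null's mean and SD reported alongside (the
original analysis reports a z and a p without naming the test; a
permutation test is the assumption-light choice that yields both). Feature
importance follows the stated recipe exactly: per fold, for each feature,
the mean gain over the trees that used it (0 if unused), then the mean over
folds.

## The synthetic-data generator

The generator is a stated world, not a fit to data: no quantitative
acoustics of ataxic speech at given SARA scores are published, so the
severity → parameter map is an invented, documented test harness whose
direction follows the clinical phenomenology (slower tempo, more irregular
rhythm, loudness spikes, noisier signal, less intelligible words):

| parameter | meaning | value at severity s |
|---|---|---|
| `pata_rate_hz` | mean syllable rate, syll/s | `6.0 (1 - 0.12 s)` |
| `interval_cv` | syllable-interval jitter CV | `0.03 + 0.06 s` |
| `spike_prob` | +6 dB loudness-spike probability | `0.02 s` |
| `snr_db` | additive white-noise SNR, dB | `30 - 2 s` |
| `word_prob_mean` | mean word probability | `max(0.2, 0.95 - 0.12 s)` |
| `pause_rate` | long pauses per second (free speech) | `0.05 s` |

Syllables are 30 ms noise bursts followed by 120 ms two-formant vowels
(F0 120 Hz) — crude source-filter synthesis, sufficient for the spectral
descriptors to respond to the noise and timing parameters. Intervals are
log-normal with the profile's CV. Transcript probabilities are drawn from a
Beta with the profile's mean and concentration 20. Labels are drawn from
{0: .08, 1: .22, 2: .30, 3: .22, 4: .12, 5: .06}, matching the clinical
cohort's median 2 and IQR 1-3. The free-speech task replaces
`min(0.6, 0.08 s)` of tokens with non-words so the real-word ratio degrades;
the counting transcript always lists the twenty numerals.

What a green test does establish: the pipeline recovers planted tempo,
rhythm-irregularity and intelligibility gradients, the splitter and metrics
are correct, and the model finds real structure (pooled-CV ±1 accuracy above
the permutation null in every seed). What it does not establish: clinical
performance. Synthetic vowels are not speech, the transcripts come from the
generator rather than a recognizer, and the severity gradients are cleaner
than biology — the published 85%/80% figures are not reproducible without
the (undeposited) clinical audio and are deliberately not targets.

## Design choices made where the design was open

* **Feature inventory.** The published counts (117 + 24) are reproduced
  with documented definitions; the proprietary "further processing" of
  spectral features is unknowable and replaced, not reconstructed.
* **VAD threshold.** The percentile-based geometric-mean rule is
  deterministic and parameter-light; the floors above make it total.
* **Broadband vs per-bin subtraction.** Per-bin magnitude subtraction with
  a 0.02 floor; the original's exact procedure is not described.
* **Counts as rates.** "Averaged word count" is ambiguous; rates per second
  keep variable-length free speech comparable.
* **Permutation test.** The exceedance formula above is implemented as
  specified even though labeled a two-sided design elsewhere; the reported z
  accompanies it.
* **70 vs 71 recording sets.** The published cohort has 71 sets from 67
  patients but reports metrics on 60 + 10; the splitter takes an explicit
  hold-out size and documents any remainder rather than guessing.
* **Entropy saturation.** The autocorrelation tempo entropy rises steeply
  from regular to moderately jittered trains and saturates near CV ≈ 0.3;
  monotonicity tests therefore compare severity extremes (0 vs 5) in
  expectation over paired seeds, and the jitter-ladder test covers the
  severity map's CV range where monotonicity holds.

## Known limitations

* The WAV reader covers PCM16/PCM32/IEEE-float mono and multi-channel RIFF;
  compressed codecs and video containers are out of scope.
* The gradient booster implements exactly what the evaluation needs (dense
  features, softmax, exact splits); it has no missing-value handling,
  subsampling, or early stopping.
* Bootstrap CIs are percentile CIs; at hold-out n = 10 they are wide and
  that is the honest answer.
* The simulator's free-speech vocabulary is tiny; lexical features other
  than the planted ones (confidence, real-word ratio, rates) carry little
  information.

## Reproducibility

Every CLI command (`simulate`, `extract`, `train-eval`, `importance`) is a
pure function of its inputs and the config seed; reruns are byte-identical,
which the acceptance suite asserts. All tunables live in one YAML config
(`default_config()` documents the defaults) and are echoed into the report.
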