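---
title: "Assessing non-invasive foetal ECG signal quality with fecgsqi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing non-invasive foetal ECG signal quality with fecgsqi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Non-invasive foetal electrocardiography (NI-FECG) records foetal cardiac
potentials through electrodes on the maternal abdomen. Each abdominal lead
is a mixture: a large maternal ECG, a much smaller foetal ECG, baseline
wander from respiration and electrode drift, mains interference, and
broadband muscle/sensor noise. The foetal component routinely disappears —
the foetus moves, electrodes sit badly, the vernix caseosa shields the
signal — so before any downstream analysis (foetal heart-rate measurement,
morphology analysis) a technician must decide whether a recording is *good*
(the foetal heart rate can be read from at least one abdominal channel) or
*bad*. `fecgsqi` automates that binary quality decision for four-channel
recordings (one maternal chest lead M, three abdominal leads A1–A3,
sampled at 1 kHz) and provides everything needed to study the problem
without access to clinical data.

Two classifier families are implemented:

* **CNN quality classifier** — each channel of a 2.5 s window is converted
  to a spectrogram image and fed to a channel-specific convolutional path;
  the four paths are concatenated and a sigmoid unit outputs the
  probability that the window is of good quality.
* **Classical SQI benchmark** — 45 signal-quality-index (SQI) features per
  window (statistical moments, band-power ratios, QRS-detector agreement,
  morphology conformity, maternal-residual measures) feed Naive Bayes,
  linear/RBF SVM, and random-forest baselines with grid-searched
  hyper-parameters.

Both are evaluated by nested stratified cross-validation with
recording-level majority voting.

## Synthetic data generator

No public corpus matches the four-lead montage, so the package ships a
generator (`generate_recording()`, `generate_dataset()`) whose output every
stage is tested against. A beat is a sum of five Gaussian lobes (P, Q, R,
S, T) on a beat-phase axis; the foetal template is the maternal one with
QRS widths halved. Beat trains carry truncated-Gaussian RR jitter
(default 3% of the nominal RR). The chest lead holds the maternal render
plus small sensor noise; each abdominal lead holds a weighted maternal
render, a weighted foetal render, sinusoidal baseline wander (0.3 Hz,
amplitude 0.15), 50 Hz mains (amplitude 0.05, i.e. 5% of the maternal R
amplitude) and Gaussian noise (sd 0.03).

The central dial is the **foetal SNR**: the power of the foetal render
against the summed non-maternal noise on a channel. The maternal component
is deliberately excluded from the "noise" because clinical quality is
judged on foetal visibility after maternal cancellation, not on maternal
contamination. The generator rescales the foetal gains by a common factor
so the best abdominal channel attains the target SNR exactly, and labels
the recording *good* iff the target is at least 3 dB. `generate_dataset()`
draws per-recording SNR uniformly from disjoint class intervals (good
\[6, 18\] dB, bad \[−12, 0\] dB), FHR from \[110, 160\] bpm and MHR from
\[65, 95\] bpm, so no synthetic recording is borderline — by design the
generator never produces ambiguous labels, mirroring a labelling protocol
that discarded recordings of inconsistent quality.

What the generator does **not** emulate: foetal/maternal axis changes from
movement, uterine-contraction bursts, electrode pops, non-stationary noise,
and overlapping maternal/foetal QRS morphology changes. Tests that pass on
this corpus therefore demonstrate that the pipeline machinery is correct
and that the classifiers can exploit a genuine SNR contrast; they do not
certify clinical performance.

## Preprocessing chain

Per channel, in order:

1. **Min–max normalization** to \[−1, 1\]:
   \(\bar x_n = 2(x_n - x_{\min})/(x_{\max} - x_{\min}) - 1\). Constant
   (dead-electrode) channels raise an error rather than silently producing
   zeros.
2. **3rd-order Butterworth bandpass, 3–100 Hz**, applied once, causally.
   Zero-phase filtering would double the effective order; the phase delay
   is irrelevant to image classification. One octave above the high edge
   a 3rd-order filter attenuates ≈18 dB — that, not more, is the designed
   stopband behaviour.
3. **Segmentation** into 2.5 s windows with 0.1 s overlap (stride 2.4 s);
   a 60 s recording yields 24 segments, each inheriting the recording
   label.
4. **Spectrogram images**: 80-point Hamming-windowed magnitude STFT. The
   stated framing constants are mutually inconsistent: a hop of 25 samples
   on 2500 samples gives 97 frames, while the image is stated to be
   40 × 126. We honour the printed output shape: the default framing uses
   hop 20 with centred frames (`floor(2500/20) + 1 = 126`), and the
   literal hop-25 variant is available via `stft_image(..., hop = 25,
   centered = FALSE)`. The 40 rows are one-sided FFT bins 1–40
   (12.5–500 Hz); the DC bin is dropped because the 3 Hz high-pass has
   already suppressed it. Raw magnitudes (not log-magnitudes, which the
   source description leaves unstated) are linearly min–max rescaled per
   image to \[0, 128\], kept continuous; an all-zero input maps to the
   all-zero image. This makes the image exactly invariant to positive
   amplitude scaling of the segment.

## QRS detection

Five detector families are provided (`detect_qrs()`): `maxsearch`
(rate-constrained local-maximum search seeded by the autocorrelation RR
estimate), `jqrs` (QRS-band energy envelope with adaptive threshold and
search-back), `pan_tompkins` (derivative–square–integrate with adaptive
dual thresholds and search-back), `gqrs` (adaptive template
cross-correlation) and `wqrs` (curve-length transform thresholding). They
are re-implemented as distinct algorithm *families*: the detector-agreement
features (bSQI) need behavioural diversity under noise, not bit-fidelity
to any reference binary. All detectors snap detections to the nearest
rectified-signal peak and enforce a refractory period (200 ms for
maternal-range search, 150 ms for foetal-range search; the foetal RR prior
is 330–600 ms). On clean synthetic ECG every family reaches F1 ≥ 0.95
against generator truth across 60–160 bpm.

Annotation matching is greedy nearest-neighbour within ±50 ms, one-to-one,
ties toward the earlier reference beat.

## Maternal-ECG cancellation (TSpca)

`extract_fecg()` implements template subtraction with principal-component
modelling of the maternal beat: fixed 500 ms windows centred on each
maternal R peak (truncated at inter-beat midpoints so windows never
overlap), stacked, mean-centred per window, decomposed by SVD, and
reconstructed from the top 2 components; the reconstruction is subtracted
in place and the per-window mean is not restored (baseline content is
assumed removed by the bandpass). Samples outside all windows pass through
unchanged. On perfectly periodic maternal-only input the residual RMS is
below 5% of the input RMS; increasing the component count never increases
residual power. The cited extraction method's per-channel vs
stacked-channel variant is not recoverable from the available description;
per-channel processing was chosen for independence of electrode gains.

## The 45 SQI features

The feature total is stated but not its expansion; the layout used here
(recorded as `layout_version = "fecgsqi-45-v1"`) is:

* 10 detector-independent features, computed once: stdSQI, sSQI, kSQI
  (population moments of the extracted FECG), pSQI
  (\(1 - \int_5^{15}|X|^2 / \int_5^{45}|X|^2\)), basSQI
  (\(\int_0^{3}|X|^2 / \int_0^{100}|X|^2\)), mxSQI, mpSQIa, mpSQIb
  (maternal-harmonic power ratios), mcSQIa, mcSQIb (mean magnitude-squared
  coherence over 3–100 Hz; variant a pairs chest and extracted FECG,
  variant b abdominal mixture and extracted FECG);
* 10 pairwise bSQI features — detector-agreement F1 for each of the
  C(5,2) unordered detector pairs;
* 25 per-detector features — {iSQI, rSQI, cSQI, xSQI, miSQI} × 5
  detectors.

xSQI's exact formula is defined here as \(E_{in}/(E_{in}+E_{out})\) over
±50 ms beat windows, which satisfies the \[0, 1\] range law and the
"extravagance" semantics; mpSQI is reported as the raw harmonic-power
ratio, leaving its orientation to the classifier. Features are computed on
the "best" abdominal channel (highest xSQI under Pan–Tompkins foetal
detection). Degenerate cases map to a sentinel 0 — never a missing value —
so the classical models need no imputation; extraction failure (fewer than
3 maternal beats in a window, possible below ~72 bpm) zeroes the
detection-dependent features and flags the vector's `quality_mask`.

## CNN architecture and training

Each of the 4 paths (3 when the maternal channel is excluded) processes
one channel's 40 × 126 image through three residual blocks. A block is a
pair of 3 × 3 convolutions (stride 1 × 1, no pooling by default), each
followed by batch normalisation, with ReLU between them; a 1 × 1
convolution (plus batch norm) on the bypass matches the filter count, and
the bypass is summed with the second convolution's normalised output
before the block's final ReLU. Default filter counts are (16, 32, 64) with
3 × 3 kernels — the source figure carrying the exact sizes is unavailable,
so both are configuration-exposed. Each path ends in a 24-unit fully
connected layer; the concatenated 96 (or 72) units feed a single sigmoid
output. Training minimises binary cross-entropy with Adam
(lr 5 × 10⁻⁴), default 200 epochs at batch size 28; after each epoch the
model is scored on the validation fold and the weights of the epoch with
the highest validation AUC (earliest on ties) are kept. Weight
initialisation is fan-in-scaled Gaussian, seeded; convolutions carry no
bias (the batch-norm shift plays that role). Inference uses batch-norm
running statistics, so scores are independent of batch composition. An
optional 2 × 2 max-pooling after each block (`arch_config(pool = TRUE)`)
is provided for memory/time-constrained runs. The numerical kernels
(im2col/GEMM convolution, pooling, batch norm, the full path
forward/backward) are compiled code; gradients are verified against
central finite differences in the test suite.

## Evaluation protocol

`nested_cv()` reproduces the nested stratified design: the outer loop
(default 10 folds) holds out one test fold; the inner loop (default 5
folds) selects the best model — best-epoch weights across inner training
runs for the CNN, the best grid point by mean inner-fold AUC for classical
learners — which is then evaluated once on the outer fold. Repetitions
re-randomize folds; the aggregate is the mean and *sample* (n−1) standard
deviation over all outer evaluations. Stratification keeps per-fold class
counts within one of proportional. Folds are assigned at segment level by
default, mirroring the original protocol's description; because segments
of one recording then can appear on both sides of a split,
`grouping = "recording"` provides the leakage-free variant. The good class
is positive throughout; `majority_vote()` resolves ties to *bad* — when
votes are split it is preferable to reject the borderline recording and
re-record. `error_rate_per_minute()` converts confusion counts to FP/FN
per minute of signal.

## Problem sizes used by the test and acceptance runs

The checked-in tests run at desk scale, sizes chosen once as part of the
experimental design:

* property suites: 10 s single-component renders, 100-recording fuzz
  loops where stated;
* classical end-to-end: 100 recordings × 10 s (400 segments), nested CV
  with 2 outer / 2 inner folds, full default grids;
* CNN end-to-end: 100 recordings × 5 s (200 segments), reduced
  architecture (filters 8/16/32, pooling on), 20 epochs, batch 28,
  1 repetition, 2 outer / 2 inner folds;
* recording-level majority voting is checked on the 400-segment classical
  run (4 segments per recording, so a single segment error cannot flip a
  vote).

The acceptance thresholds asserted on this corpus (CNN AUC ≥ 0.90,
RF/SVM-RBF AUC ≥ 0.85, vote recovery ≥ 95%) are repository bounds for the
synthetic conditions, not claims about clinical data.

## Known limitations

* The generator's morphology is stylised; T-wave phase scales with RR, so
  template subtraction at rates below ~70 bpm leaves T-wave tails outside
  the 500 ms cycle window.
* WFDB files are not read or written; recordings are exchanged as CSV with
  plain-text annotation sidecars and JSON metadata.
* The classical NB grid searches the prediction-time variance floor
  (`eps`), the closest native analogue of Gaussian-NB variance smoothing;
  the RF grid uses `ntree` × `nodesize`, the forest's native complexity
  controls.
* Segment-level fold assignment (the default, for protocol fidelity)
  shares recordings between training and test folds; use
  `grouping = "recording"` for honest generalisation estimates.
* Best-epoch selection by validation AUC with earliest-epoch tie-breaking
  optimises ranking, not calibration: on easily separable data with short
  training schedules the returned weights can rank perfectly while all
  scores sit on one side of the 0.5 threshold. Threshold-based metrics
  (accuracy, F1, majority votes) from such runs reflect that; AUC does
  not.
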