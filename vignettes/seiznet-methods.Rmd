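---
title: "Methods: EEG seizure detection via 2D representations and a compound-scaled network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG seizure detection via 2D representations and a compound-scaled network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model implemented by **seiznet**, the
parameters it exposes, and the rationale behind the choices that are not
forced by the problem itself.

## 1. Problem and pipeline

The task is binary classification of EEG segments into *seizure*
(ictal) and *nonseizure* (interictal) states. The model is a five-part
pipeline: windowed decomposition of the record, 2D feature extraction
per slice, rendering of the feature map as an image, depth-feature
extraction with a scalable convolutional network, and classification of
the depth features.

### Decomposition

`slice_record()` slides a window of `window_s` seconds with fractional
overlap `overlap_frac` (default 0.5) across the record. Window start
positions are computed in seconds and floored onto the sample grid, so
the slice boundaries are reproducible across sampling rates. A slice is
labeled `seizure` when the fraction of its duration covered by
(merged) annotated seizure intervals reaches `label_rule`; the default
`label_rule = 1` keeps only fully ictal windows positive, which avoids
diluting the positive class with transition windows.

### Feature extraction

Two front ends produce a 2D real matrix (`feature_map`) per slice:

* **Continuous wavelet scalogram** (single-channel slices).
  `cwt_scalogram()` evaluates
  $W(a, b) = a^{-1/2} \sum_n x[n]\, \psi^{*}\!\big((n - b)/a\big)$
  for integer scales $a = 1, \dots, \texttt{total\_scale}$ via
  zero-padded FFT cross-correlation, and returns magnitudes. The mother
  wavelet is the complex Gaussian of order 8: the 8th derivative of
  $e^{-it}e^{-t^2}$, $L_2$-normalized. Its center frequency has the
  closed form $f_c = \frac{1 + \sqrt{1 + 8n}}{4\pi} \approx 0.7212$ for
  $n = 8$ (the spectral peak of $|\omega|^n e^{-(\omega + 1)^2/4}$ is
  the positive root of $\omega^2 + \omega - 2n = 0$), so scale $a$
  responds to frequency $f_c \cdot f_s / a$. We use the derivative
  definition directly rather than an integrate-and-differentiate
  approximation, which matters only at the smallest scales.

* **Spectral band features** (multichannel slices).
  `fft_band_features()` removes each channel's mean, takes the DFT
  magnitude, and averages it over frequency bins
  $[f - s/2,\, f + s/2)$ for $f$ stepping through the requested band at
  spacing $s$ (default 1 Hz). A 23-channel slice with band 1–23 Hz
  yields a 23 × 23 map; band 1–46 Hz yields 23 × 46. The minimum window
  length for non-empty bins is $1/s$ seconds, and violations are
  reported with that number.

### Image representation

`render_scalogram_image()` draws the scalogram as a contour-style
image: values are min–max scaled, discretized into `levels` bands
(default 10), resized bilinearly to the output resolution, and mapped
through a perceptually uniform colormap, with scale 1 at the bottom
edge. `render_matrix_image()` maps a channel × frequency cell to one
pixel. Both are invariant to affine rescaling of the feature map, so
the network sees shape, not absolute amplitude. `augment()` provides
label-preserving flips and right-angle rotations. `to_net_input()`
resizes to the network resolution and applies the standard per-channel
mean/sd normalization used by backbones pretrained on the large public
image corpus, so pretrained weights remain usable.

## 2. The scalable network

`baseline_spec()` encodes the level-0 architecture as a stage table:
one 3×3 stem convolution (stride 2, 32 channels), seven MBConv stages
(channels 16, 24, 40, 80, 112, 192, 320; repeats 1, 2, 2, 3, 3, 4, 1;
kernels 3, 3, 5, 3, 5, 5, 3; expansion 1 then 6), and a 1×1 head to
1280 channels followed by global average pooling and a dense softmax
layer. Each MBConv block is: 1×1 expansion → batch norm → swish →
depthwise convolution (stride on the first block of a stage) → batch
norm → swish → squeeze-excitation (reduction ratio 0.25) → 1×1
projection → batch norm, with an identity shortcut when the shapes
agree.

`scaling_config(level)` selects compound-scaling coefficients
(resolutions 224–600, width 1.0–2.0, depth 1.0–3.1 across levels 0–7);
`scale_spec()` applies them: channel counts are rounded to multiples
of 8 (never below 90% of the scaled value), repeat counts are scaled by
the depth coefficient and ceiled. Depth scaling is applied to the
MBConv stages only — the stem and head are single layers by
construction, and scaling them would change the meaning of the
architecture rather than its capacity.

Because no deep-learning framework is available to the package, the
forward and backward passes are hand-written: convolutions via
im2col + GEMM in RcppArmadillo, depthwise convolutions and the fused
batch-norm/swish/squeeze-excitation kernels in Rcpp, and the chain rule
assembled in R. The implementation is validated by finite-difference
gradient checks through every block type (worst relative error
~5 × 10⁻⁶). Training (`train_network()`) uses Adam (lr 10⁻³, batch 32)
on softmax cross-entropy with seeded shuffling, and early stopping on
validation accuracy (patience 10), snapshotting the best-validation
weights and batch-norm running statistics. When several epochs tie on
validation accuracy the latest is kept: a saturated validation accuracy
cannot discriminate between epochs, and the longer-trained weights
generalize measurably better to held-out subjects.

A **tiny preset** (`tiny_network_spec()`: resolution 64, width 0.35,
depth 0.5) exists so that end-to-end tests and examples train in about
a minute on one CPU. It is a test fixture, not a scientific variant:
its feature dimension is 448 and its parameter count is under a tenth
of the level-0 network's.

`extract_depth_features()` returns the pooled penultimate activations;
`classify_features()` applies the network's own softmax head, a KNN, or
an SVM to them. `save_network_weights()`/`load_pretrained()` implement
transfer by name-and-shape matching; a classifier head of a different
size is deliberately left at its fresh initialization.

## 3. Synthetic EEG generator

Real seizure corpora cannot be redistributed with the package, so all
tests run on `generate_synthetic()`:

* **Background (interictal)**: Gaussian noise shaped in the frequency
  domain to power ∝ $f^{-\alpha}$ (default $\alpha = 1$, pink-like, a
  reasonable stand-in for resting EEG spectra), unit RMS, DC removed.
* **Ictal**: the same background plus a sinusoid at a single dominant
  frequency drawn uniformly from `ictal_band` (one draw per record,
  shared across channels with random phases), amplitude-modulated by
  20% at 0.5 Hz. The modulation mimics the waxing–waning envelope of
  rhythmic ictal discharge and prevents the oscillation from being a
  trivially pure spectral line. The oscillation is scaled so that the
  *total* ictal RMS is `ictal_amplitude_ratio` times the background
  RMS, i.e. oscillation RMS = $\sqrt{r^2 - 1}$ × background; `r ≤ 1`
  therefore degenerates to pure background, which is the null case used
  to verify that the pipeline finds nothing when nothing is planted.

Each record derives its RNG stream from
(`seed`, subject, record, state), so enlarging a corpus never perturbs
existing records, and everything is bit-reproducible.

This construction makes the two classes separable *exactly by the
property the front end measures* (band power / time–frequency energy),
so the end-to-end test is a genuine parameter-recovery experiment: at
ratio 4 the tiny network must reach ≥95% held-out accuracy in both the
pooled and the leave-subject-out designs, and at ratio 1 its accuracy
must fall inside the binomial 95% interval around chance.

## 4. Evaluation

`compute_metrics()` reports accuracy, sensitivity and specificity in
percent, with the seizure class positive. A metric whose denominator is
zero is reported as missing, never as 0, and missing values propagate
through sweep averages rather than biasing them. `split_intrapatient()`
pools all subjects, optionally balances classes 1:1 by seeded
down-sampling, and partitions by fractions (default 0.6/0.2/0.2,
stratified by class). `split_interpatient()` holds every slice of one
subject out as test and verifies on every call that no subject appears
on both sides. `run_experiment()` sweeps window × band grids, repeats
each cell with seeds `seed + 0..repeats-1`, and logs per-cell failures
without aborting the sweep.

## 5. Numerical choices and limitations

* Batch-norm uses $\epsilon = 10^{-3}$ and running-statistic momentum
  0.9; with few steps per epoch the running statistics need a few
  epochs to warm up, which is visible as low validation accuracy in the
  first epochs of small trainings.
* The wavelet is sampled on $[-8, 8]$ (beyond which the Gaussian
  envelope is below $10^{-27}$) and the kernel support per scale is
  $\pm\lceil 8a \rceil$ samples.
* The EDF reader/writer supports the plain 16-bit dialect with
  homogeneous sampling rates — enough for fixtures and the public
  scalp-EEG corpora it models — not EDF+ event channels.
* Levels 5–7 of the scaling table are constructed and validated
  structurally but are not exercised by training tests; their memory
  and compute demands are beyond a desk-scale CPU budget.
* Slice-level predictions are the final output; no post-hoc smoothing
  across consecutive slices is applied.
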