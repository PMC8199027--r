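---
title: "Methods: synthetic ultrasound swallowing videos and hyoid tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ultrasound swallowing videos and hyoid tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hyoid bone excursion during swallowing is a clinical indicator of
swallowing function: on the midsagittal plane the hyoid first rises
(elevation), then moves anteriorly to its maximum displacement, then
returns. Submental B-mode ultrasound shows the hyoid as a high-echoic
area with a posterior acoustic shadow, and speech therapists annotate its
position frame by frame — a laborious task that single-object trackers
can automate: annotate a 30 × 30 px box in the first frame only, and let
the tracker predict the centre in every subsequent frame.

Real ultrasound swallowing recordings of this kind are not publicly
distributed, so `hyoidtrack` couples the trackers with a *synthetic*
video generator whose ground truth is exact by construction. This makes
the whole pipeline — simulation, offline Siamese training, online
correlation-filter tracking, kinematic evaluation — reproducible from a
single seed, at the cost that all green tests certify behaviour on the
synthetic world, not on clinical data (see *Limitations*).

## The synthetic world

`scene_params()` fixes the imaging geometry: 720 × 540 px frames at
0.325 mm/px and 32 fps by default. Anatomical sizes are specified in
millimetres and converted through `mm_per_px`, so the half-resolution
benchmark scene (360 × 270 px at 0.65 mm/px) renders the same anatomy
with a quarter of the pixels.

Image coordinates are 0-based pixel centres, origin top-left, x rightward
and y downward; elevation is −x and anterior movement +y. The axes are
chosen to match the verbal description of published trace plots (the
trace "moves towards the left then vertically downwards"); display
convention puts the probe at the bottom, so the acoustic shadow extends
toward −y ("vertically above the hyoid").

One frame is composed of:

* a **static multiplicative speckle field** — an i.i.d. Rayleigh field
  smoothed by a small Gaussian (grain size `speckle_smooth_px`, default
  1.2 px), normalised to unit mean and scaled by `speckle_scale`
  (default 0.6). This is the standard first-order approximation of fully
  developed B-mode speckle. The field is static across a sequence
  (tissue texture), with independent per-frame additive Gaussian noise
  (`frame_noise_sd`, default 2 grey levels) for temporal sensor noise;
* a **bright oblique muscle line** ending at the hyoid point (the
  geniohyoid landmark used for annotation), Gaussian profile of
  half-thickness 1.3 mm;
* a **posterior acoustic shadow**: a soft-edged, slightly diverging
  wedge of default width 11 mm multiplying intensities by
  `shadow_attenuation` (default 0.35) from just above the echo to the
  top edge;
* a **bright elliptical echo** (Gaussian, semi-axes 4 × 2.5 mm) at the
  ground-truth point.

The trajectory (`trajectory_params()`) is rest → elevation (−x) →
anterior (+y) → return, with cosine ease-in/ease-out inside each phase —
the mildest smooth interpolation consistent with the three named phases.
The onset frame itself is still at the rest position and the phase
completes its full range of motion at the offset event, so the
generator's per-axis range of motion (ROM) is exactly
`rom_mm / mm_per_px` pixels. Defaults draw each axis ROM uniformly from
13–17 mm, the range reported for healthy adults. Sequence lengths are
uniform on [330, 430] frames so the mean matches the reported average of
382; the swallow always completes at least 50 frames before the end of
the recording (the real recordings were trimmed to 50 frames past the
swallow; the pre-onset rest period stands in for the humming phase,
which has no synthetic analogue). Optional smoothed positional jitter
(SD 0.5 px) emulates annotation/tissue tremor; a `inject_double_shadow()`
utility reproduces the fast-motion artifact in which one frame shows two
echo/shadow complexes.

What the generator deliberately does **not** model: probe or tissue
deformation, other anatomy (mandible, tongue, bolus), attenuation with
depth, harmonic-mode effects, inter-subject appearance variation. The
synthetic target is therefore *more* trackable than clinical data — the
benchmark bounds below must be read in that light.

## The Siamese tracker

The tracker follows the classic fully-convolutional Siamese design: an
exemplar patch (127 × 127) cropped around the first-frame box and a
search patch (255 × 255) around the previous estimate are embedded by
the same padding-free convolutional backbone; valid cross-correlation of
the two feature grids gives a 17 × 17 score map whose peak offset,
multiplied by the backbone stride and the patch scale, is the target
displacement. Three scale hypotheses (step 1.025) are searched per
frame; the template is embedded once and never updated.

Backbone: five convolutions (11/5/3/3/3, conv1 stride 2, two 3 × 3/2
max-pools, total stride 8), no padding anywhere so the network is
exactly shift-equivariant — a property the tests assert bitwise. Widths
are 8/16/16/16/8: the tracking target has no distractors, and narrow
widths keep CPU-only training and inference fast; geometry (127 → 6 × 6
cells, 255 → 22 × 22) matches the classic design. Patches are grayscale
and enter the network as a single channel: replicating a grayscale image
into three identical channels is mathematically equivalent (the first
layer sums over channels) and three times the cost in the dominant first
convolution, so the single-channel form was chosen.

Numerical choices:

* **Crop sampling.** `crop_patch()` samples bilinearly at
  `centre + (i − (out−1)/2) · side/out`, so an odd-sized patch centred
  on an integer pixel reproduces pixels exactly; out-of-frame samples
  take the image mean.
* **Score-map upsampling.** Bicubic (Catmull-Rom), corner-aligned:
  17 × 17 at factor 16 gives 257 × 257 (= (n−1)·f+1), which keeps the
  grid centre an exact cell and makes the displacement arithmetic exact
  (a peak 16 up-cells from centre is exactly stride = 8 image px).
* **Peak selection.** Scale chosen by the largest penalised raw maximum
  (penalty 0.9745 on non-central scales), then the winning map is
  normalised to a unit-sum distribution and blended with a unit-sum
  cosine window (weight 0.176) before the argmax; ties break to the
  lexicographically smallest scale/row/column. Without the window the
  tracker is unstable under speckle.
* **Score adjustment.** The raw correlation is scaled by a learnable
  scalar initialised at 1e-3 plus a bias — standing in for the batch
  normalisation of large-scale implementations, and necessary for a
  well-conditioned logistic loss.

Training samples two frames at most 100 frames apart from a uniformly
chosen training sequence, jitters the search-crop centre by up to 8 px
and stretches crop sides by ±5%, and supervises the score map with a
weighted binary cross-entropy: cells within 16 image px of the true
target cell are +1, others −1, with the two classes carrying equal total
weight. The optimiser is single-pair SGD with momentum 0.9 and a global
gradient-norm clip at 5 (without which rare near-degenerate pairs
destabilise the momentum buffer). The learning rate anneals
geometrically; the source protocol prints endpoints "1 × 10^1 to
1 × 10^5", which can only be sign-dropped exponents, and the intended
magnitudes are not recoverable — the package defaults to 1e-2 → 1e-5,
which trains stably for this backbone at batch size 1. The full protocol
(5000 pairs/epoch × 50 epochs, checkpoint at 30) is the default
configuration; the desk-scale benchmark uses 500 × 10.

## The correlation-filter baseline

A single-channel MOSSE-style discriminative correlation filter
implements the principle that circulant dense sampling turns correlation
into element-wise spectral products: the filter is the regularised ratio
`num/(den + λ)` with `num = Σ G ⊙ conj(F)`, `den = Σ F ⊙ conj(F)`,
desired response `G` a centred Gaussian with σ = target diagonal / 10,
λ = 1e-4. Patches (window = 2 × the 30 px box) are log-transformed,
zero-mean/unit-variance normalised and Hann-tapered — the standard MOSSE
preprocessing. Localisation reads the response argmax with wrap-aware
quadratic sub-pixel refinement; the filter then updates by exponential
moving average (rate 0.125) at the new position. Initialisation
augments with small scale jitters only; rotation warps would displace
the desired-response peak without serving the principle under test.
This is a generic dependency-free DCF baseline, not a reimplementation
of CSRT or ECO.

## Evaluation suite

Per sequence with N frames: centre error δ_t = ‖p_t − g_t‖; precision =
(1/N) Σ [δ_t ≤ threshold] with an inclusive boundary, evaluated under
one-pass evaluation (single initialisation, no re-initialisation);
RMSE = √((1/N) Σ δ_t²); AE = (1/N) Σ δ_t; per-axis Pearson correlation
over all frames; ROM from hyoid onset to offset as the maximum absolute
per-axis displacement (maxima may fall on different frames — the
straight-line ROM is also reported since the convention is ambiguous)
relative to the onset position; relative ROM error
|ROM_gt − ROM_pred| / ROM_gt × 100%.

Aggregation over sequences reports mean ± sample (n−1) SD per metric,
and precision curves are averaged per sequence (each sequence weighted
equally); frame-pooled curves are available behind a flag. Millimetre
displays round half away from zero to two decimals, reproducing the
printed conversions 10 px → 3.25 mm and 5 px → 1.63 mm at
0.325 mm/px. Zero-variance axes and zero ground-truth ROM yield `NA`
with a warning rather than a number.

## Scaling decisions

The package is sized for a single CPU. The acceptance protocol
(`scripts/acceptance.R`, `run_benchmark()`) generates the full 30/10/10
split at 360 × 270 px — the "downscaled by 2" condition, implemented by
generating at half resolution rather than downsampling rendered frames,
which is geometrically equivalent here because all scene sizes are
specified in millimetres — and trains at 500 pairs/epoch × 10 epochs
(about 15 minutes end to end). The in-suite acceptance test runs the
same protocol further scaled down (sequences of 140–200 frames, 300
pairs/epoch × 8 epochs, one seed) with unchanged thresholds. Datasets
are written as PNG image-sequence directories and read lazily so memory
stays within a few hundred MB.

## Limitations

* Green benchmark results establish that the re-implemented pipeline
  tracks an idealised synthetic hyoid at least as well as the reported
  clinical figures; they do not certify clinical performance.
* The backbone is far narrower than production Siamese trackers and is
  trained at batch size 1 without batch normalisation; it is adequate
  for the distractor-free synthetic target.
* Only PNG image-sequence input is supported; no video-container
  decoding is available in the target environment.
* The DCF baseline has no scale estimation and no channel/spatial
  reliability machinery.
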