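---
title: "Cross-device choroidal enhancement: models, phantoms and measurement"
author: "octsynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-device choroidal enhancement: models, phantoms and measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octsynth)
```

## The problem

Spectral-domain OCT (SDOCT, ~840 nm) is the routine clinical imaging
modality for the posterior eye, but scattering in the retinal pigment
epithelium (RPE) and choriocapillaris attenuates its signal so rapidly
with depth that the choroid — the vascular layer between retina and
sclera — and in particular the choroidal-scleral interface (CSI) are
usually not measurable. Swept-source OCT (SSOCT, ~1050 nm) penetrates
deeper and resolves the choroid well, but such devices are confined to a
minority of specialized centres.

`octsynth` implements, end to end, a generative strategy for closing
that gap: paired SDOCT-like and SSOCT-like volumes of the same eye are
harmonized and co-registered; a paired conditional GAN (Pix2Pix) is
trained to translate shallow-penetration B-scans into choroid-enhanced
B-scans using the deep-penetration scan of the same eye as the
reference; and the enhancement is judged not by image metrics but by
whether clinically meaningful choroidal measurements — subfoveal
choroidal thickness (CT), choroidal area (CA) on the foveal B-scan,
choroidal volume (CV), and the choroidal vascularity index
(CVI = luminal area / choroidal area) — agree between the enhanced
images and the deep-penetration reference (Pearson r, ICC(2,1), MAE
with bootstrap confidence intervals, Bland-Altman limits of agreement).

Because no clinical data ship with the package, every stage is
exercised against a seeded synthetic eye phantom with fully analytic
ground truth. The phantom is first-class, tested code: it defines the
study conditions, and every downstream operation has an oracle.

## The synthetic eye phantom

`generateEye()` builds one eye from `phantomParams()`:

* **Geometry.** Three boundary surfaces in mm depth per lateral
  position: internal limiting membrane (ILM), RPE and CSI. Surfaces are
  smooth (band-limited undulation, default amplitude 0.04 mm at a
  1.6 mm wavelength), with a radially symmetric Gaussian foveal pit
  (depth 0.10 mm, sigma 0.35 mm) carved into the ILM only, so the
  retina is thinnest at the pit centre — the landmark the fovea-finding
  rule targets. Per-eye subfoveal retinal thickness is drawn from
  N(0.22, 0.02) mm and choroidal thickness from N(0.25, 0.08) mm,
  matching a healthy macular cohort; the draws are truncated from below
  (0.16 and 0.08 mm) only to keep the geometry well-posed.
* **Vessels.** Choroidal vessel lumens are random cylinders along the
  slow axis, radii 2–5 px, rejection-placed until the realized luminal
  fraction is within ±0.02 of the target (default 0.65). Placement
  respects a clearance below the RPE equal to the bright-band support:
  a lumen is never allowed to erode the RPE band that flattening and
  thickness measurement depend on — where the band is too thin, the
  vessel simply does not pass. The voxelized lumen mask *is* the CVI
  ground truth, so CVI recovery has an exact oracle.
* **Rendering.** Retina and stroma share one base reflectivity so the
  RPE is a clean, symmetric Gaussian bright band (no step bias for the
  peak estimator); the ILM is a second bright band on the
  vitreous-retina edge; lumens are dark; the sclera is dark. A smooth
  lateral reflectance-texture field (sd 12%, ~0.45 mm wavelength)
  multiplies the scene. This texture is the physical correlate of what
  enface registration locks onto: it is the *same tissue* seen by both
  devices, while speckle is independent per acquisition. Band
  amplitudes keep the brightest peak near 0.85 so that typical texture
  excursions never clip it flat — a flat-topped band would defeat
  sub-row peak localization.
* **Noise.** Fully developed speckle is modelled as multiplicative
  Gamma noise with shape equal to the "looks" parameter (mean 1,
  variance 1/looks). The manufacturer-style signal-strength index 1–10
  scales the profile looks linearly; scans below 6 exist only to
  exercise the quality filter. On top of speckle each device adds a
  Gaussian detector-noise floor.
* **Devices.** `ssoctProfile()`: 300 x 300 A/B-scans over
  3 x 3 x 3 mm, no sub-RPE attenuation, floor 0.01.
  `sdoctProfile()`: 245 x 245 over 3 x 3 x 2 mm, exponential sub-RPE
  attenuation 6 mm^-1, floor 0.02, plus a small lateral inter-device
  offset. The pair of coefficients follows one design rule: the depth
  at which the attenuated profile drops below half its near-RPE level
  (where a relative-contrast delineation gives up, ~0.12 mm) lies
  below essentially the whole choroidal-thickness distribution, so an
  image-based CSI delineation on the raw shallow scan collapses — the
  clinical premise — while the depth at which signal sinks to the
  noise floor (~0.4 mm) lies above it, so *latent* signal remains for
  a trained translator to amplify, as it must have for the clinical
  result to be possible at all. The coefficients are calibration
  conveniences, not claims about any vendor's physics.

`degradeEye()` renders the shallow-penetration copy by Lanczos-resampling
the noise-free scene to the shallow grid (its own axial span, measured
from the volume top), applying the attenuation below the (interpolated)
RPE, injecting the lateral offset, and adding independent speckle and
floor. `groundTruthMetrics()` computes RT/CT at the fovea, CA on the
foveal B-scan, CV over the lateral grid and LA/CVI from the lumen mask,
all analytically.

What the phantom does *not* emulate: pathology (drusen, edema, staphyloma),
motion artifacts, vignetting, sensitivity roll-off beyond the
exponential term, anisotropic speckle statistics, or vendor-specific
post-processing. Passing tests therefore demonstrate that the pipeline
is correct and self-consistent under controlled conditions, not that it
is validated on clinical data.

## Paired preprocessing

`preprocessPair()` mirrors the clinical harmonization stack, with every
tunable in `preprocessConfig()`:

1. **Normalization**: per-volume percentile stretch (0.5–99.5%) to
   [0, 1]; device intensity scales differ and are otherwise arbitrary.
2. **Grid matching**: separable Lanczos resampling (order a = 3, the
   standard high-quality choice) of both volumes onto one working grid
   over the shared 3 x 3 mm lateral extent and the shallow device's
   2 mm axial span (top-aligned). Kernel weights are renormalized per
   output sample, so constants are preserved exactly.
3. **Despeckling**: Perona-Malik anisotropic diffusion per B-scan
   (20 iterations, kappa 30 on a 0–255 scale, step 0.2; the explicit
   scheme obeys the maximum principle for step <= 0.25). B-scan-wise
   processing matches the per-image training unit.
4. **RPE estimation and flattening**: per A-scan the RPE is the deepest
   *dominant* bright band — a local maximum of the axially smoothed
   profile (sigma 2 rows) with prominence >= 25% of the A-scan maximum
   *and* height >= 75% of it. The height criterion matters: stromal
   ridges between dark vessel lumens are prominent but dim, and
   prominence alone selects them. Ties break toward depth. Sub-row
   position comes from parabolic refinement; lateral regularization is
   a despike filter (a value is replaced by its 3 x 3 median only when
   it deviates by more than one row) followed by Gaussian smoothing —
   an unconditional median filter rectifies the zero-mean sub-row
   estimation ripple into a measurable depth bias. Both volumes are
   flattened so the RPE sits at a common physical depth (0.9 mm).
5. **Enface registration**: mean-intensity projections over the RPE
   band (±10 rows) are aligned by FFT phase correlation with
   regularized whitening, two candidate estimates (plain and
   Hann-windowed) scored by interior normalized cross-correlation, and
   a local matrix-DFT zoom for sub-pixel refinement. Pairs whose best
   shift exceeds a quarter of the lateral extent, or whose alignment
   score stays below 0.35, are flagged as registration failures and
   excluded — the registration-accuracy screen.
6. **Finalization**: symmetric central crop of the lateral axes from
   3.0 to 2.6 mm, axial span 2.0 mm from the volume top, Lanczos
   resampling to the final grid. Defaults produce exactly 256 B-scan
   pairs of 256 x 256 px per eye at 2.6 x 2.6 x 2.0 mm, so a 589-eye
   training cohort yields 150,784 image pairs and a 146-eye test
   cohort 37,376 — the pipeline's count-conservation arithmetic
   (`studyManifest()` fixes these counts before any image is rendered).

## The translator

`buildGenerator()` realizes the residual encoder-decoder used for
paired image translation: a 7 x 7 stem and two stride-2 encoding blocks
(convolution, instance norm, ReLU), nine residual blocks
(conv-InstanceNorm-ReLU-Dropout-conv-InstanceNorm with an additive
skip), and three decoding blocks that mirror the encoder, ending in a
7 x 7 convolution and tanh. Decoding uses nearest-neighbour upsampling
followed by a 3 x 3 convolution ("resize-convolution") rather than a
fractionally-strided convolution: it avoids checkerboard artifacts and
keeps the backward pass an exact index-map transpose. Instance
normalization is affine-free. Reflection padding is used for the stem
and residual convolutions.

`buildDiscriminator()` is the canonical 70 x 70 patch discriminator:
five 4 x 4 convolutions with strides 2, 2, 2, 1, 1 and leaky-ReLU
activations. Construction verifies the realized receptive field by the
backward recursion `rf <- rf * stride + (kernel - stride)` and fails on
any mismatch; a 256 x 256 input yields a 30 x 30 patch-score map.

Training (`trainPix2pix()`) alternates discriminator and generator
updates per image pair: vanilla cross-entropy adversarial loss plus an
L1 reconstruction term with weight 100 (the canonical paired-GAN
setting; the source architecture publication prints no loss weights),
Adam with learning rate 1e-4 and betas (0.5, 0.999), 15 epochs and
batch size 1 by default. A printed learning rate of "-0.0001" in the
source description is treated as a typographical sign error. Dropout
(0.5) is active in residual blocks during training and disabled at
inference, so `enhance()` is bit-deterministic — the original recipe
keeps test-time dropout, but determinism wins here and is documented.
The whole network engine is plain R: convolutions are im2col index
gathers plus BLAS matrix products, and gradients flow back through the
same index maps via `rowsum()` scatter-adds; every layer's backward
pass is verified against finite differences in the test suite.

Train/test separation is enforced at the subject level: both eyes of a
subject always travel together (`splitCohort()`), and the split is
re-derived from the manifest, never stored ad hoc.

## Measurement

`estimateBoundaries()` provides the three surfaces. The ILM is the
shallowest dominant bright band, detected with a lighter axial kernel
(sigma 1) because it is a one-sided vitreous-retina edge and heavy
smoothing drags its peak into the retina. The RPE uses the estimator
above. The CSI either comes from an externally supplied delineation
(`csi_row`, labelled `"manual-proxy"` — the stand-in for the manual
delineation of the clinical workflow, served by phantom ground truth
here) or from an image-based estimator: the end of the deepest
sustained run of the sub-RPE profile above a contrast threshold placed
halfway between the near-RPE stromal level and the deep background.
Scanning for the deepest run keeps dark vessel lumens from truncating
the band; on attenuated shallow-penetration input the estimate
collapses toward the RPE, which is the honest behaviour of an
image-based delineation and exactly why the enhancement is needed. The
provenance of every boundary set is carried in its `source` label; a
CSI is never silently invented.

`choroidMetrics()` then locates the fovea (thinnest retina within the
central 50% window; ties break to the earliest index and are flagged),
averages the foveal B-scan with its two neighbours, and measures RT and
CT axially (after flattening, "perpendicular" is axial), CA by row
integration cross-checked against pixel counting, CV by integrating
(CSI − RPE) over the grid, and CVI by Niblack local thresholding of the
contrast-stretched (1st–99th percentile to [0, 255]) averaged B-scan.

Niblack parameters are configuration, not constants. The defaults are
a 51 px window and k = +0.2: the threshold `T = mean + k * sd` sits
above the local mean and luminal (dark) pixels are those *below* it —
the standard Niblack parameterization with dark-pixel selection, as in
the Fiji auto-local-threshold workflow. A negative k would place T
below the local mean and thereby exclude the interior of any
homogeneous lumen (local sd ~ 0 implies T < mean), systematically
undersegmenting large vessels; the package's recovery study measures
this directly. The window is deliberately wide: local statistics must
bridge whole lumens. Local means and variances are computed with
integral images over mirrored edges and verified against a brute-force
double-loop oracle.

## Statistics

`agreementReport()` computes, per metric, Pearson r (p from the
regression F-test, equivalent to t² for a simple correlation), ICC(2,1)
— two-way random-effects, absolute agreement, single measurement, from
the ANOVA mean squares, the variant chosen because the two "raters"
(device/model) are a random sample of measurement systems and absolute
agreement is what clinical interchangeability requires — and MAE, each
with a seeded percentile bootstrap 95% CI (5000 iterations by default;
percentile rather than BCa because it is the simplest fully
reproducible variant), plus Bland-Altman bias and 1.96-sd limits of
agreement. `gradingScores()` scores reader-study records: accuracy,
sensitivity (real is the positive class) and specificity per expert and
for the per-item majority, overall and per stratum and task.

The packaged recovery study (50 noise-free phantoms) runs the
estimators with axial smoothing sigma = 1: the smoothing kernel exists
solely for speckle, and on clean data the wider kernel lets dark
lumens a few rows below the RPE pull the band's smoothed peak upward
by ~0.2 rows — negligible for a typical choroid but already 2% of a
near-degenerate 0.08 mm band.

## The desk-scale study

`runStudy(toyStudyConfig())` executes the complete experiment at desk
scale: 20 training and 12 test eyes (one stratum), 64-cube grids over
the physical fields of view, base-width-4 networks, 5 epochs over 16
training B-scans per eye at learning rate 3e-4, with every stage
seeded from one master seed. The narrow networks and raised learning
rate are the desk-scale training design: at these budgets the binding
resource is optimization steps, not model capacity, and pilot runs
showed that per-eye depth transfer only emerges beyond roughly a
thousand generator updates. At the
coarse toy grid the choroid spans only ~8 axial voxels, so the phantom
override uses 1–2 px vessels and a 0.45 luminal target — a resolution
adaptation, not a change of study conditions. The study measures all
three volumes of each test eye (input, enhanced, reference) with
image-estimated boundaries and reports input-vs-reference and
enhanced-vs-reference agreement; the structural claim is that the
enhanced volumes agree with the reference better than the raw input
does (choroid-band reconstruction error and thickness/volume
correlations), and that the translator's reconstruction loss falls
over training. Of the per-eye comparisons, the choroidal-volume
correlation is the statistically stable one at this cohort size — it
integrates (CSI - RPE) over the whole lateral grid, averaging
measurement noise — whereas the single-point subfoveal thickness
correlation at a dozen eyes remains noisy from seed to seed; both are
reported. Full-scale
configurations (`studyConfig()` defaults: 589/146 eyes, 256-cube
grids, 15 epochs) describe the complete design and drive the count
arithmetic, but training at that scale is outside what a single CPU
session should attempt.

Problem sizes used by the packaged checks: the metric-recovery study
runs 50 noise-free phantoms at 96 x 48 lateral / 256 axial samples;
the learning checks run the toy study above; registration and
threshold oracles run on 64–96 px fixtures. These sizes were chosen so
the entire suite completes comfortably on one CPU while every
tolerance is met at study-realistic physical scales.

## Known limitations

* The phantom's regular geometry and piecewise-constant reflectivity
  make boundary estimation easier than on clinical scans; the recovery
  tolerances (RT/CT within 0.02 mm, CA/CV within 2%, CVI within 0.05)
  should not be read as clinical accuracy claims.
* The toy translator (base width 8, 5 epochs, 64 px) demonstrates the
  learning mechanism and the direction of the improvement, not the
  ceiling of the approach.
* The image-based CSI estimator is intentionally simple; on real SSOCT
  data a dedicated segmentation model would replace it.
* CVI values depend on the documented contrast stretch and Niblack
  settings; comparisons are only meaningful at fixed settings.
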