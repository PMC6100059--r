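---
title: "Discriminating seed varieties from NIR hyperspectral images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating seed varieties from NIR hyperspectral images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedhsi)
```

## The analysis problem

Near-infrared hyperspectral imaging records, for every pixel of a scene, a
full reflectance spectrum across hundreds of contiguous narrow bands. For
seed phenotyping this combines the strengths of imaging (every individual
seed is located and delineated) and NIR spectroscopy (the spectrum of each
seed carries overtone and combination bands of C–H, N–H and O–H vibrations
that differ between varieties). `seedhsi` implements the complete
object-wise discrimination chain for such data:

1. **Reflectance calibration.** Raw sensor counts are converted to relative
   reflectance against a dark-current frame and a white-reference frame,
   \(R = (I_\mathrm{raw} - I_\mathrm{dark}) / (I_\mathrm{white} -
   I_\mathrm{dark})\), applied element-wise.
2. **Band cropping.** The noisy spectral edges are discarded; the default
   working range is 975–1646 nm.
3. **Segmentation.** A mask is built by Otsu's threshold on the single band
   where sample/background contrast is maximal; connected foreground
   components become per-seed regions of interest (ROIs).
4. **Pixel-wise denoising.** Each foreground pixel spectrum is smoothed by
   a Daubechies-7 wavelet decomposition of depth 3.
5. **Object spectra.** The spectrum of a seed is the arithmetic mean of its
   pixel spectra.
6. **PCA.** Pixel-level principal components give score images (pattern
   recognition) and loading curves.
7. **Effective wavelengths (EWs).** Prominent local extrema of the loading
   curves, deduplicated by proximity, select a handful of informative
   bands, collapsing the feature space from hundreds of bands to ~10–30.
8. **Discrimination.** An RBF-kernel SVM on the EW-restricted object
   spectra, with the penalty \(c\) and kernel width \(g\) tuned by grid
   search over \(2^{-8} \ldots 2^{8}\), classifies each seed; reserved
   external images are rendered as per-seed classification maps.

No public image archive accompanies the study this pipeline addresses, so
the package ships a synthetic scene generator with known ground truth; all
claims the test suite makes about the chain are claims about its behaviour
on such scenes.

## The synthetic scene model

`scene_config()` + `generate_scene()` emulate the statistical structure the
analysis assumes, not the physics of a line-scan camera:

* **Endmembers.** Each of three classes has one mean reflectance spectrum:
  a smooth quadratic baseline (about 0.58–0.62) minus Gaussian absorption
  dips of width 25 nm at the configured feature centers, by default 1100,
  1200, 1300 and 1450 nm for every class — the band positions typical of
  second-overtone C–H and first-overtone O–H features in seed tissue.
  Class 2's dip depths are interpolated towards class 1's by
  `class_overlap` (0 ⇒ identical endmembers; default 0.4), and its baseline
  sits `0.4 × 0.02` above class 1's, so classes 1 and 2 are spectrally
  close. Class 3 keeps its own depths plus a baseline offset of +0.10,
  which cleanly separates it — and fixes the sign pattern of PC1 score
  images (class 3 opposite to classes 1/2).
* **Layout.** Seeds are ellipses (semi-axes 6–10 × 4–7 px, random
  orientation) placed by rejection sampling with a minimum 2 px gap and a
  conservative bounding-circle test, 300 attempts per seed before a layout
  error. Seeds never touch, matching the acquisition protocol the chain
  assumes; watershed splitting is deliberately out of scope.
* **Radiometry.** Dark level 100 counts, white level 4000 counts, with the
  configured relative illumination gradient across the scan (row) axis
  applied to the white frame. In-seed raw counts are
  `dark + R·(white − dark) + ε` with `ε ~ N(0, noise_sd·(white − dark))`;
  reference frames carry 20 % of that noise. The background is a dark
  plate of reflectance 0.02. Correction therefore recovers endmembers up
  to noise, exactly at `noise_sd = 0`.
* **Defaults as study conditions.** 160 × 200 px, 200 bands over 975–1646
  nm, 5 seeds per class per image, `noise_sd = 0.02` (a realistic
  per-pixel reflectance noise for InGaAs line-scan systems),
  `illumination_gradient = 0.05`. A `grid = "sensor"` preset emits 256
  bands at the instrument-like 3.36 nm spacing starting at 875 nm; this
  grid crops to exactly 200 bands in 975–1646 nm and exists to exercise
  `crop_bands()`.

**What the generator does not model** — and hence what passing tests do
*not* show about real data: within-seed spatial heterogeneity, per-seed
biological variability around the class endmember, wavelength-correlated
(non-isotropic) noise, sensor nonlinearity and stray light, and
maturity/soil effects. Because every seed of a class shares one endmember,
object-level averages are nearly noise-free and the synthetic
discrimination problem is easier than the real one: end-to-end accuracies
near 100 % on synthetic scenes demonstrate the chain's correctness, not
field performance.

## Numerical and design choices

* **Out-of-gamut reflectance.** The correction guards pixels with
  `white − dark < 1e-6` (set to 0 and counted) and clips corrected values
  to \([-0.05, 1.5]\), recording clip counts. The source study is silent on
  this; the policy keeps saturated or dead elements from poisoning later
  stages while preserving slightly negative noise excursions around dark
  backgrounds.
* **Contrast band.** The provisional foreground/background split at each
  band is a gray-level quantile threshold (default 0.5); the band
  maximizing the absolute mean difference wins, ties to the lower index.
* **Otsu on continuous data.** The threshold is computed on a 256-level
  histogram of the min–max-scaled band image (via EBImage); degenerate
  single-level images are rejected.
* **Connectivity and small components.** ROIs are 8-connected by default
  (4 available), discovered in raster-scan order; components under 10 px
  are dropped; border-touching ROIs are kept but flagged, since the
  protocol defines no exclusion rule.
* **Wavelet denoising.** The decimated DWT uses symmetric (half-sample)
  boundary extension, the standard choice for ~200-point spectra. The
  smoothing rule is not fully pinned down by the source description
  ("wavelet transform used for smoothing"), so both common readings are
  implemented: the default universal soft threshold
  \(\sigma\sqrt{2\log n}\) with \(\sigma\) estimated from the finest
  detail coefficients as MAD/0.6745, and an approximation-only
  reconstruction. Neither is asserted to be the original procedure. With
  symmetric extension the transform is slightly oversampled, so
  approximation-only reconstruction is idempotent only up to boundary
  effects; tests check this on smooth spectra and on the interior of noisy
  ones. Because the transform is linear, the package materializes the
  analysis and synthesis operators once per spectrum length and denoises
  whole pixel matrices with two matrix products.
* **PCA.** Fitted by singular value decomposition of the mean-centered
  pixel matrix; each loading column's sign is fixed so its
  largest-magnitude entry is positive, making score images and extremum
  kinds reproducible. The pipeline pools foreground pixels of the
  calibration images (a per-image mode is a matter of feeding
  `fit_pixel_pca()` one image's pixels), with a seeded uniform subsample
  cap of 50 000 pixels for memory. Degenerate (e.g. noiseless) data can be
  analysed via `clamp_rank = TRUE`, which keeps as many components as the
  data support.
* **EW selection.** Interior local extrema with topographic prominence at
  least 0.1 × the curve's max |loading| are pooled over the first six
  components; greedy non-maximum suppression keeps the largest-|loading|
  candidate within each 10 nm window (ties to the lower wavelength).
  Endpoints are never candidates. The 10 nm window is chosen so that
  close-but-distinct feature pairs ~17 nm apart survive while near-duplicate
  extrema from different components collapse. Low-variance components
  carry mostly noise, so the selected set is typically larger than a
  hand-curated one; the SVM is insensitive to the extra bands.
* **SVM.** `e1071`/libsvm with one-vs-one voting, no feature scaling by
  default (an optional standardization flag exists). The grid-search
  selection score is stratified 5-fold cross-validated accuracy on the
  calibration objects with seeded folds — the validation scheme is a
  package decision, chosen to avoid leaking the prediction set. Ties break
  to smaller \(c\), then smaller \(g\). An optional refinement pass
  searches a \(2^{1/4}\)-step grid around the best coarse cell; best
  parameters off the power-of-two lattice are reachable that way, but the
  refinement is not claimed to replicate any particular published search.
* **Split.** The split unit is the image: all objects of an image share a
  fold. Per class group, one external image is reserved first, the rest
  split 2:1 into calibration and prediction with a seeded shuffle.

## Problem sizes used by the tests and the acceptance script

The synthetic study runs 7 images of 160 × 200 px with 15 seeds each
(4 calibration, 2 prediction, 1 external after the split); EW recovery uses
20 seeded replicate scenes at the same scale; the denoising benefit uses
100 seeded replicate spectra at noise 0.02. These sizes were chosen as the
smallest at which every stage (image-level split, pooled PCA, grid search,
external mapping) operates in its intended regime.

## Known limitations

* The ENVI dialect is deliberately narrow: BSQ float32 written, BIL also
  read, BIP and vendor formats rejected.
* Label-map PNGs are 8-bit, capping a scene at 255 seeds.
* The synthetic generator's class geometry (baseline offsets, dip widths)
  is fixed; only centers, depths, overlap and noise are exposed.
* Accuracy figures on synthetic scenes are upper bounds relative to real
  seed populations, for the reasons given above.
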