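---
title: "Two-stage OCTA image quality improvement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage OCTA image quality improvement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaclean)
```

## The problem

*En face* optical coherence tomography angiography (OCTA) projects a 3-D
decorrelation volume of the retinal or conjunctival microvasculature onto a
2-D image. Because acquisition takes several seconds, microsaccadic eye
motion leaves bright horizontal (or vertical) stripe artifacts across the
B-scan direction, and illumination conditions often leave vessels at poor
contrast against the background. Both degradations propagate into
downstream analyses, most directly vessel segmentation.

`octaclean` addresses the two degradations in two stages:

1. **De-striping.** A U-shaped convolutional network estimates the stripe
   noise map from the corrupted image; the clean image is the non-negative
   residual.
2. **Re-enhancing.** An unpaired bi-directional translation GAN maps
   de-striped, low-contrast images toward a high-contrast domain while
   feature-level cycle consistency and a local structure penalty protect
   the vasculature.

## Stage 1: the de-striping model

A corrupted image is modelled as an exact additive decomposition
$I = N + C$ of a stripe-noise map $N$ and a clean map $C$. The network
$f_\theta$ predicts $N_{out} = f_\theta(I_{in})$ and the clean estimate is
the residual rule

$$C_{out} = \max\{I_{in} - N_{out},\, 0\}.$$

Training minimizes the composite objective

$$L = \alpha\, L_{recon} + \beta\, L_{stripe} + \gamma\, L_{ATV},$$

with defaults $\alpha = 0.5$, $\beta = 2$, $\gamma = 1$:

* **Reconstruction**, $L_{recon} = \tfrac12 \lVert I_{in} - (N_{out} +
  C_{out}) \rVert_F$: the two estimates must jointly reconstruct the
  input.
* **Stripe (low-rank) consistency**, $L_{stripe} = \lVert
  \mathrm{Stripe}(N_{ref}) - \mathrm{Stripe}(N_{out}) \rVert_F$, where
  $\mathrm{Stripe}(N) = U\,\mathrm{shrink}_\lambda(S)\,V^T$ soft-thresholds
  the singular values of $N$ ($\max(\sigma_i - \lambda, 0)$, default
  $\lambda = 0.002$ on the $[0,1]$ intensity scale). Soft-thresholding is
  the proximal operator of $\lambda\lVert\cdot\rVert_*$; because stripes
  are near-parallel bands, their energy concentrates in a few singular
  values, so the operator isolates the stripe component that the predicted
  map must match.
* **Anisotropic total variation**, comparing edge sharpness
  $\mathrm{ATV}(C) = \lVert \nabla_x C \rVert_1 + \lVert \nabla_y C
  \rVert_1$ (forward differences, no wrap-around) between $C_{out}$ and
  the clean reference. The default form is the scalar comparison
  $|\mathrm{ATV}(C_{ref}) - \mathrm{ATV}(C_{out})|$; a `"map"` variant
  compares absolute gradient maps elementwise under one Frobenius norm.

All three terms are differentiable almost everywhere and the package
implements their analytic gradients, including full differentiation
through the SVD of $N_{out}$ (thin-SVD backward with the standard
$F_{ij} = 1/(\sigma_j^2 - \sigma_i^2)$ rotation terms, zero-guarded near
degenerate and vanishing singular values). Subgradients at kinks
($\sigma = \lambda$, zero residuals, zero differences) are taken as 0.
Finite-difference agreement of every gradient is asserted in the test
suite.

### Network and optimization

The noise estimator is a U-shaped encoder-decoder: two 3x3
convolution + instance-norm blocks per resolution level (leaky-ReLU
encoder, ReLU decoder), 2x max-pool down, nearest-upsample + convolution
up, symmetric skip concatenation, and a 1x1 convolution head with a final
ReLU so noise estimates are non-negative (stripes are additive bright
artifacts). The head is zero-initialized with a small positive bias: the
untrained model is then a near-identity destriper, which removes the large
transient where a randomly initialized head first has to unlearn a dense
noise estimate; the small bias keeps the final ReLU out of its dead zone.

Optimization is Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$), batch 16, learning rate $2\times10^{-4}$ held
constant for the first half of the schedule and decayed linearly to zero
over the second half (default 150 + 150 epochs). No data augmentation is
applied.

The `"tiny"` profile (depth 2, 8 base channels, 10 + 10 epochs) exists for
CPU-scale runs and differs from the defaults in two deliberate ways:

* **Learning rate $2\times10^{-3}$.** Adam steps have magnitude close to
  the learning rate per parameter, so total parameter movement scales with
  (steps x lr). The short schedule has roughly a tenth of the default
  schedule's steps; a tenfold learning rate restores comparable movement.
* **Gradient-map ATV variant.** The scalar form compares two numbers, so
  its subgradient is a dense global sign pattern whose magnitude does not
  shrink as the estimate improves and which cannot say *where* an edge
  mismatch lives; at short schedules it dominates the other terms'
  unit-norm gradients by two orders of magnitude and stalls stripe
  learning. The map variant localizes the comparison and its gradient
  scales with the mismatch. Package defaults keep the literal scalar form.

## Stage 2: the re-enhancing model

Low- and high-contrast images are treated as two unpaired domains $X$ and
$Y$. Two residual generators $G_{XY}, G_{YX}$ and two patch discriminators
$D_X, D_Y$ are trained with the canonical bi-directional translation
objective — least-squares adversarial terms, image-level cycle consistency
($\lambda_{cyc} = 10$) and identity terms ($\lambda_{idt} = 5$) — plus two
additions, combined as

$$L = L_{bl} + \xi L_p + \rho_1 L_s(G_{XY}, X) + \rho_2 L_s(G_{YX}, Y),
\qquad \xi = \rho_1 = \rho_2 = 0.5 .$$

* **Cyclic perceptual loss** $L_p$: squared Frobenius distances between
  multi-depth convolutional features of each image and of its round-trip
  reconstruction, summed over a low-level and a high-level tap (after the
  2nd and 5th pooling stage) and over both directions. The shipped
  feature extractor is a frozen, seeded random CNN with those two tap
  depths — a fully offline variant of pretrained-backbone perceptual
  losses; random convolutional features preserve the loss's structure
  (multi-scale feature comparison) while requiring no external weights.
* **Structure loss** $L_s$: one minus the mean per-window SSIM structure
  term, $1 - \frac1M \sum_i \frac{\sigma_{x_i g_i} + c}{\sigma_{x_i}
  \sigma_{g_i} + c}$, over non-overlapping 8x8 windows with
  $c = 0.03^2/2$ (the conventional SSIM structure stabilizer on a $[0,1]$
  scale; population moments). It is 0 for identical images and, up to the
  $c$ correction, for any positive affine rescaling; its maximum 2 is
  attained under perfect anti-correlation. In the two-stage pipeline the
  structure loss is applied to the stage-2 input, i.e. the de-striped
  image.

Generators predict a residual added to the input and clamped to $[0,1]$,
with a zero-initialized final convolution so an untrained generator is
exactly the identity; this makes the identity, cycle, perceptual and
structure terms start at zero and the adversarial signal drive the
enhancement. Discriminator updates use a seeded 50-image replay buffer.
Training follows Adam, batch 1, learning rate $2\times10^{-4}$ constant
for 100 epochs then decayed to zero over another 100; the `"tiny"` profile
(8 channels, 2 residual blocks, 64-pixel images, 5 + 5 epochs) raises the
learning rate to $2\times10^{-3}$ for the same movement-budget reason as
above. Setting $\xi = \rho_1 = \rho_2 = 0$ recovers the baseline
objective exactly, which is the package's ablation axis.

## The synthetic data generator

No public stripe-corrupted OCTA corpus is bundled; the package instead
synthesizes phantoms with known ground truth, which is what every
quantitative claim in the tests is measured on.

* **Clean phantoms** emulate high-contrast, noise-free angiograms: smooth
  spline vessels through random waypoints, dilated to a sampled thickness
  (default 1.5-4 px), bright (0.55-0.95) over a dark speckled background
  (level 0.12, speckle s.d. 0.04), lightly blurred. The exact pre-blur
  vessel footprint is returned as the segmentation ground truth.
* **Stripe fields** are additive bright bands of one orientation
  (default horizontal, matching B-scan motion artifacts) with Poisson
  stripe count (mean 3), thickness 1-4 px, amplitude 0.1-0.5, full-span
  probability 0.7, partial stripes at least 30% of the span, each band
  smoothed by a 1-pixel Gaussian along its short axis. Every band is a
  rank-1 pattern, so a field of $k$ stripes has rank at most $k$ — the
  low-rank prior the stripe loss relies on, guaranteed by construction.
* **Graded corruption**: noise level $i$ means $i$ independently drawn
  stripe fields summed onto one clean image. The sum is clipped to
  $[0,1]$ and the stored noise is recomputed as corrupted − clean, so the
  additive decomposition holds exactly after clipping — the identity the
  reconstruction loss assumes of its reference triplet.

Amplitudes and stripe counts are calibration choices (no measured stripe
statistics are available to fit); they are exposed in the parameter
objects. The generator does not attempt vendor-specific appearance,
foveal anatomy, or disease-specific vasculature, and stripes are purely
additive — so passing tests demonstrate correct behaviour of the method
under its own modelling assumptions, not clinical performance on device
data.

Datasets are written as 16-bit grayscale TIFF (images) and 8-bit PNG
(masks) with a plain-text manifest recording every seed; a dataset is
reproducible bit-for-bit from its manifest.

## Evaluation

Fidelity is measured by PSNR ($10\log_{10}(max^2/\mathrm{MSE})$, infinite
for identical images) and SSIM (canonical Gaussian 11x11, $\sigma = 1.5$,
$K_1 = 0.01$, $K_2 = 0.03$, valid-region filtering). Segmentation quality
uses a deliberately simple, deterministic baseline segmenter (optional
Gaussian high-pass, then Otsu or quantile global threshold) against the
phantom's exact vessel mask, reporting Dice, sensitivity, specificity
(TN/(TN+FP)) and G-mean $\sqrt{Sen \cdot Spe}$; a 2-pixel border is
excluded from mask comparison to avoid renderer edge effects. Zero
denominators yield `NA` with a warning and are excluded from aggregates.

## Numerical choices and degenerate inputs

* SVD backward guards: rotation terms are zeroed where
  $|\sigma_j^2 - \sigma_i^2| < 10^{-12}$; $\hat\sigma/\sigma$ ratios are
  zeroed at $\sigma \le 10^{-12}$. Random images have simple spectra with
  probability one, so the guards matter only on constructed inputs.
* Subgradient conventions: 0 at $\max(\cdot, 0)$ kinks, at zero residual
  of unsquared norms, and at zero forward differences.
* Structure-loss windows with (near-)zero variance are stabilized by $c$;
  the gradient's $1/\sigma$ factor is zero-guarded.
* Constant images: the segmenter returns an empty mask with a warning;
  PSNR of identical images returns the `Inf` sentinel, excluded from
  aggregate means.
* All randomness (phantoms, stripe draws, splits, initialization, data
  order, replay buffers) flows through explicit integer seeds; repeated
  runs are bit-identical up to floating-point reduction order, and the
  pipeline reproducibility test asserts agreement to $10^{-5}$.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's CPU-scale study conditions: de-striping is trained
on 200 level-2 64x64 triplets for 20 epochs and evaluated on 40 held-out
triplets (de-striped images must beat corrupted ones on mean PSNR, SSIM
and Dice); enhancement is trained on 30 low- vs 30 high-contrast phantoms
with the seeded random extractor — a 10-epoch smoke run (all loss terms
finite, exact ablation reductions, structure preserved on held-out
phantoms) and a 40-epoch run for the vessel-contrast-gain property; the
end-to-end pipeline reproducibility check runs 8 phantoms with 2 + 1
training epochs twice.

## Known limitations

* At these desk scales the GAN's adversarial signal moves the generators
  only slightly; the contrast gain of the enhancement stage is small and
  the package asserts structure preservation rather than a large contrast
  improvement. Full-scale schedules (hundreds of epochs at 400x400) are
  configured but not exercised by the tests.
* The stripe model is additive and bright-only; multiplicative or dark
  stripes, curved motion artifacts, and inter-B-scan decorrelation noise
  are out of scope.
* The scalar ATV default reproduces the composite objective literally but
  optimizes poorly at short schedules (see above); users running short
  schedules should prefer `atv_variant = "map"`.
* Single-channel 2-D *en face* images only; no 3-D volumes, DICOM, or
  vendor formats.
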