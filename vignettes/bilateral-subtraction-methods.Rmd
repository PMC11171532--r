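---
title: "Bilateral mammogram subtraction: model, phantoms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral mammogram subtraction: model, phantoms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiologists read a mammogram against its contralateral (or prior)
counterpart: a density present in one breast but not at the mirrored
location of the other is a finding; the same density present in both is
usually normal anatomy. A subtraction image — the pixelwise absolute
difference between the right-breast MLO image and the horizontally flipped
left-breast image — makes such asymmetries explicit, but only if the two
images are first aligned. Breasts are soft tissue: positioning, compression
and anatomy differ between sides, so rigid alignment is not enough.
`mammosub` implements the full pipeline: skin-line segmentation and
geometric normalization, an unsupervised convolutional registration network
that predicts a dense nonrigid displacement field, spatial-transformer
warping, and SAD-based evaluation with quartile subgroup analysis.

## Model

Let $f$ be the fixed (right) image, $m$ the flipped moving (left) image,
both $512\times512$ (or any multiple of 16) on $[0,1]$, and $\phi$ a dense
per-pixel displacement field in pixels. A 2-D VoxelMorph-style U-Net maps
the stacked pair $(f, m)$ to $\phi$; a bilinear spatial transformer forms
$m\circ\phi$, i.e. output pixel $(i,j)$ samples $m$ at
$(i+\phi_r(i,j),\, j+\phi_c(i,j))$ with border clamping. Training minimizes

$$L(f, m, \phi) \;=\; L_{\mathrm{mse}}(f, m\circ\phi) \;+\;
  \lambda\, L_{\mathrm{ppm}}(\phi),$$

where $L_{\mathrm{mse}}$ is the mean squared intensity difference computed
**only over the breast + pectoralis mask** of the fixed image, and
$L_{\mathrm{ppm}}$ (the per-pixel misalignment) is the mean of squared
forward-difference spatial gradients of the displacement components.

Architecture (configurable via `unet_config()`): encoder channels
16-32-32-32, each a 3x3 stride-2 convolution with LeakyReLU(0.2); decoder
channels 32-32-32-32-32-16-16 with nearest-neighbour x2 upsampling and skip
connections, including a final skip from the 2-channel input; a 3x3 flow
head outputs the 2-channel field. The flow head is **zero-initialized**, so
an untrained model is exactly the identity transform — training starts from
"no deformation" and only moves pixels when the image evidence pays for it.

No autodiff framework is available to R in this stack, so forward, backward
(im2col + GEMM convolutions, transposed-convolution input gradients), the
spatial transformer with its analytic gradients, and Adam are implemented
directly in C++ (float32 internally; the exposed losses and warp are double
precision and are tested against brute-force per-pixel loops to 1e-12 and
against finite differences to 1e-4 relative error).

### Numerical choices

* **Smoothness normalization.** "Mean of the squared spatial gradients" is
  ambiguous about the denominator. We normalize each direction by
  $2\times(\text{valid positions in that direction})$ and sum the two
  directions: a linear field $u_c = c\cdot\text{col}$ then has
  $L_{\mathrm{ppm}} = c^2/2$, constant fields have zero, and the loss
  magnitudes land on the few-times-$10^{-3}$ scale on $[0,1]$ images.
* **Masking.** $L_{\mathrm{mse}}$ is masked; $L_{\mathrm{ppm}}$ is computed
  for all pixels, taking "for all pixels" literally. The evaluation SAD uses
  the same fixed-image mask, and only that one mask per pair: warping a
  second (moving-side) mask would itself depend on the predicted field.
* **Schedule.** Adam, initial learning rate $2\times10^{-4}$, cosine
  annealing to exactly zero at the final epoch, no warm restarts:
  $\eta(e) = \eta_0 (1 + \cos(\pi e / E))/2$. Defaults: 800 epochs, batch
  32, $\lambda = 1$.
* **Warping.** Bilinear, border-clamped; displacement is expressed in pixels
  of the fixed frame; row-major 0-based pixel-center coordinates with the
  chest wall at column 1 after flipping.
* **Divergence.** A non-finite batch loss aborts training with the epoch in
  the message rather than continuing silently.

## Preprocessing

Raw images are normalized by the full bit-depth range (value 32768 of a
16-bit image maps to 32768/65535), never by per-image min/max, so
intensities remain comparable across cases. The breast + pectoralis mask
comes from skin-line detection: threshold at half the Otsu level (capped
into the skin-line intensity range and floored above background noise —
plain Otsu systematically clips the faint skin rim), keep the largest
connected component, fill holes, and apply a light 5-px disc closing. The
geometric chain pads the nipple side with background to a square, resizes
with Keys bicubic interpolation (a = -0.5, 4x4 neighbourhood) to
`round(out_size * 520/512)` (520 for 512 output), and centre-crops — masks
follow the same chain with nearest-neighbour resampling and
re-binarization. The chain is aspect-preserving (a circle stays a circle to
eccentricity < 0.05) and deterministic.

## The synthetic phantom generator

The clinical cohort behind this design is private, so the package ships a
first-class generator of bilateral MLO-like phantom pairs; it defines the
study conditions for every test in the package.

A right-breast phantom is a half-superellipse anchored to the chest-wall
edge (the exponent grows above 2 only when the requested area cannot be
reached by an ellipse inside the frame; the posterior radius is refined by
bisection against the rasterized mask so requested and realized area agree
within 0.03), a triangular pectoral wedge in the upper posterior corner
(+0.18 intensity, its own edge softening), scattered glandular texture from
Gaussian blobs, a smooth skin-line falloff (~1.5% of image width) with a
sharp 2-px ramp to a 0.10 intensity floor — mammographic skin lines are
visible, and an invisible rim would make the segmentation target
ill-defined — and a global tissue brightness that increases linearly with
compressed breast thickness (0.30 at 12 mm to 0.65 at 84 mm, a monotone
proxy adequate for subgroup machinery). The ground-truth mask is defined as
the tissue support (contour minus the sub-visibility rim), and the
glandular mask is cut at the intensity quantile that realizes the requested
gland coverage exactly, so the density covariate is true by construction.

The left breast is the mirror of the right warped by a smooth random field:
Gaussian-smoothed white noise, recentred and rescaled so its empirical RMS
displacement equals `deform_magnitude` exactly, then tapered to zero at the
image borders — so the chest wall stays put — by a smoothstep ramp spanning
half the correlation length. The taper width matters: a ramp much shorter
than the correlation length would make the taper, not the field, dominate
the smoothness penalty and would break the field's own smoothness contract. The
stored `true_field` is the numerically inverted negative of the generating
warp (fixed-point iteration $\phi \leftarrow -g(x + \phi(x))$), i.e. the
field a perfect registration should predict. An independent glandular
perturbation with amplitude `2 * noise_sd` and independent pixel noise
(`noise_sd`, default 0.01) are added on the left side only, so bilateral
asymmetry never vanishes entirely except in the exact degenerate case
`deform_magnitude = 0, noise_sd = 0`, where the flipped left equals the
right bit for bit.

Chosen defaults, fixed once: cohort covariates are sampled as truncated
normals matching a screening test population (area 34.4 +/- 10.7% in
[11.1, 79.8], gland ratio 44.0 +/- 16.0% in [11.5, 85.0], thickness
45.7 +/- 13.6 mm in [12, 84]); `deform_magnitude` defaults to 3 px — no
quantitative bilateral-asymmetry magnitude is published for screening
cohorts, so this is a plausible, clearly visible misalignment rather than a
calibrated one; the field correlation length defaults to `min(H, W)/4`
(breast-scale), reflecting that positioning and compression differences are
smooth and global — at this scale the smoothness penalty of the true field
(~0.01) is commensurate with the recoverable MSE, so the composite loss
rewards genuine correction rather than suppressing the field.

What the phantoms do **not** emulate: X-ray physics (scatter, beam
hardening), 3-D compression mechanics, calcification morphology, vendor
post-processing, and real glandular branching texture. Passing tests on
phantoms therefore demonstrate that the machinery — segmentation, geometry,
learning dynamics, statistics — behaves correctly under known ground truth;
they do not certify clinical-grade registration quality on real mammograms.

## Evaluation and statistics

SAD is the mean absolute intensity difference over mask pixels on [0,1]
intensities — the only normalization consistent with values like 0.05-0.07
on screening images. Per case we report SAD without registration (fixed vs
flipped), with registration (fixed vs transformed), and their difference
(improvement, positive when registration helped). Quartile subgroups sort
decreasingly for breast area, gland content ratio and thickness, and
increasingly for baseline SAD, with stable ties by case id and contiguous
groups whose sizes differ by at most one (larger first; 500 cases give
4 x 125). The with/without comparison uses a two-sided paired Wilcoxon
signed-rank test (identically-zero differences return p = 1 by convention
rather than erroring); between-group improvement comparisons use pairwise
Mann-Whitney tests with Holm correction. The sources describing this
design name no tests; these nonparametric defaults were chosen for
robustness to the skewed improvement distributions, and paired/two-sample
t tests are available behind `parametric = TRUE`.

## Problem sizes used by the shipped experiments

`run_scaled_experiment()` — also what `scripts/acceptance.R` executes — is
the package's scaled-down analog of the clinical study: 96 phantom pairs at
128 x 128 with 3 px asymmetry, split 64/8/24 (the 1000/100/500 proportions),
trained 150 epochs at batch 8. The smoke profile of `run_end_to_end()` uses
16 cases and 20 epochs. These sizes were chosen so a complete run is a
coffee-break job on a single CPU core while still giving the statistics
room to reach p < 0.01 on 24 paired cases. Deformation recovery is
evaluated on held-out images by constructing `moving = warp(fixed, g)` for
known smooth fields `g` and comparing the predicted field with the inverted
`g` inside the 4-px-eroded mask (median endpoint error).

## Prior-image mode

Nothing in the network knows about laterality: replacing the fixed image
with a prior exam and skipping the horizontal flip turns the same machinery
into temporal subtraction. The CLI exposes this as `register --no-flip`.

## Known limitations

* Phantom realism as listed above; absolute SAD levels on phantoms are not
  comparable to clinical values.
* Single-resolution registration; no diffeomorphic guarantee — large or
  folding deformations are representable and unpenalized beyond the
  gradient term.
* The float32 training core makes runs reproducible on one machine but not
  necessarily bit-identical across BLAS builds.
* DICOM input is out of scope; convert to 16-bit PNG/TIFF first.

## A worked example

```{r example}
library(mammosub)

cohort <- generate_cohort(8, image_size = c(128L, 128L), seed = 42)
pairs <- lapply(seq_len(8), function(k) {
  cs <- cohort$cases[[k]]
  preprocess_pair(cs$right_image, cs$left_image, out_size = 128L,
                  case_id = cohort$manifest$case_id[k])
})
model <- train_registration(pairs[1:6], pairs[7:8],
                            train_config(epochs = 20L, batch_size = 4L,
                                         seed = 1))
autoplot(model)                       # learning curve
records <- evaluate_cohort(model, pairs[7:8])
records
```
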