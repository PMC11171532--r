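# mammosub

Subtraction processing for the comparative interpretation of bilateral
mammograms, in R.

Radiologists routinely read a mediolateral-oblique (MLO) mammogram against
the mirrored image of the contralateral breast: a density present on one
side but absent at the mirrored location of the other is a potential
finding. A subtraction (absolute difference) image makes such asymmetries
explicit — but only after the two soft-tissue images have been aligned,
which rigid registration cannot do. `mammosub` implements the whole
pipeline for researchers in breast-imaging CAD:

* **Preprocessing** — skin-line breast + pectoralis segmentation (Otsu-based
  thresholding, largest component, hole filling), nipple-side padding,
  bicubic (4×4) resize and centre crop to 512×512 (or any multiple of 16).
* **Unsupervised nonrigid registration** — a 2-D VoxelMorph-style U-Net
  predicts a dense per-pixel displacement field `φ` from the stacked
  fixed/flipped pair; a bilinear spatial transformer forms `m∘φ`. Training
  minimises the masked composite loss

  `L(f, m, φ) = L_mse(f, m∘φ) + λ · L_ppm(φ)`

  with `L_mse` the mean squared error over the breast + pectoralis mask and
  `L_ppm` the mean squared forward-difference gradient of the displacement
  components (λ = 1 by default; Adam, initial learning rate 2×10⁻⁴, cosine
  annealing; defaults 800 epochs, batch 32). The network, its backward
  pass, and the optimiser are implemented natively in C++ (im2col + BLAS
  GEMM), since R has no autodiff stack.
* **Evaluation** — per-case SAD (mean absolute difference over the mask, on
  [0, 1] intensities) without vs with registration, the improvement, paired
  Wilcoxon testing, quartile subgroup analysis over breast area, mammary
  gland content ratio, compressed breast thickness, and baseline SAD, with
  pairwise Holm-corrected group comparisons; broom-style `tidy()` /
  `glance()` and `autoplot()` methods throughout.
* **Synthetic phantoms** — a first-class generator of bilateral MLO-like
  phantom pairs (semi-elliptic contour, pectoral wedge, glandular blob
  texture, visible skin line) with known ground-truth deformation fields,
  masks, and covariates, so the whole pipeline is testable without clinical
  data. A lesion-insertion helper supports qualitative cancer-contrast
  demos, and a no-flip mode supports prior-image (temporal) subtraction.

## Worked example

Simulate a small bilateral cohort, train briefly, and evaluate:

```r
library(mammosub)

out <- run_end_to_end(run_config(tempfile("run"), n_cases = 16L,
                                 image_size = 128L, epochs = 20L,
                                 batch_size = 8L, seed = 3L))
out$report
```

```
<subgroup_report> n = 5; SAD 0.0332 +/- 0.005 without vs 0.0314 +/- 0.005 with registration (p = 0.0625)
  mean improvement 0.0018 [0.0001, 0.0049], improved in 100.0% of cases
```

Five held-out test cases: even this 20-epoch training lowers the bilateral
SAD in every case (mean 0.0332 → 0.0314). With five pairs the exact paired
Wilcoxon test cannot go below p = 1/2⁴ = 0.0625 — statistical significance
needs the larger profile below. The run directory contains the cohort images and
manifest, learning curve, model checkpoint, per-case difference images,
and the subgroup report (CSV + Markdown + figures).

The scaled experiment the package is tested against (96 cases at 128×128,
3 px RMS synthetic asymmetry, 64/8/24 split, 150 epochs):

```r
exp <- run_scaled_experiment(seed = 1)
glance(exp$report)
```

On the 24 held-out cases this run reports mean SAD 0.0324 without vs
0.0202 with registration (paired Wilcoxon p = 1.2×10⁻⁷, the exact minimum
for 24 uniformly improved pairs), SAD reduced in 100% of cases, training
loss falling 0.0044 → 0.0019 over the schedule, and median endpoint error
≈ 1.4 px when recovering known 3 px RMS deformation fields — the same
quantities `scripts/acceptance.R` writes below.

## Command line

```sh
Rscript inst/cli/mammosub.R simulate   --n 96 --out runs/sim --size 512 --seed 7
Rscript inst/cli/mammosub.R train      --manifest train.csv --val val.csv --out runs/m
Rscript inst/cli/mammosub.R register   --weights runs/m/weights.rds \
                                       --fixed R.png --moving L.png --out runs/reg
Rscript inst/cli/mammosub.R evaluate   --weights runs/m/weights.rds \
                                       --manifest test.csv --out runs/eval
Rscript inst/cli/mammosub.R run        --out runs/full --seed 1
```

`register --no-flip` switches to prior-image (temporal) subtraction.

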