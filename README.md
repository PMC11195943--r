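# pskde

Contrast enhancement of grayscale radiographs by **pixel-wise
substitution with kernel density estimates** (ps-KDE), with the standard
histogram-based baselines, segmentation scoring, paired augmentation,
and a fully synthetic evaluation pipeline.

## The problem and the method

Semantic segmentation of chest radiographs (heart, lungs, clavicles)
benefits from preprocessing that raises the contrast of the target
structure. The usual tools — global histogram equalization (HE) and
contrast-limited adaptive histogram equalization (CLAHE) — equalize
intensities without regard to *which* structure the user cares about.
ps-KDE instead uses per-structure prior knowledge: on training images
with binary masks, it estimates the probability density f̂ᵣ(v) of pixel
intensity v inside region r (Gaussian kernel, Scott's-rule bandwidth,
truncated to [0,1] and renormalized), stores it, and enhances any image
for region r by

    out(p) = f̂ᵣ(in(p)) / max f̂ᵣ

Intensities common inside the structure render bright, rare ones dark,
and the intensity→output mapping is a fixed function of the stored
model, so it is identical across images. The package is aimed at
medical-image-analysis researchers who want a reproducible, dependency-
light implementation of the transform, its baselines, and the
evaluation harness around them.

Alongside the core transform, the package provides:

- **Baselines** — HE and a from-scratch CLAHE (tile histograms, clip +
  single-pass redistribution, bilinear tile blending).
- **Metrics and losses** — pixel confusion counts, IoU, Dice,
  precision/recall/accuracy, BCE / Jaccard / Dice soft losses, mean(SD)
  aggregation, and Welch's unequal-variance t-test for comparing arms.
- **Paired augmentation** — rotation ±90°, flips at p = 0.5, zoom
  0.5–1.5, resize, applied identically to image and masks (nearest-
  neighbor for masks, so they stay binary); k-fold dataset expansion.
- **Synthetic chest phantom** — one grayscale image plus five binary
  structure masks with distinct per-region intensity distributions, so
  everything above is testable without downloading any dataset.
- **Pipeline** — seeded 50/50 split, leakage-free enhancement fitting,
  a Gaussian naive-Bayes reference segmenter, CSV reports, probability-
  map PNGs, and a command-line front end (`inst/cli/pskde.R`).

## Worked example

Generate 20 synthetic phantoms, compare raw images against ps-KDE
enhancement for heart segmentation, and test the difference:

```r
library(pskde)

data_dir <- file.path(tempdir(), "phantoms")
generate_dataset(20, phantom_config(seed = 42), seed = 42, out_dir = data_dir)

res <- run_experiment(data_dir, regions = "heart",
                      methods = c("none", "pskde"), seed = 42,
                      out_dir = file.path(tempdir(), "run"))
subset(res$report, metric %in% c("dice", "iou"))
#>  region method metric      mean          sd  n
#>   heart   none   dice 0.8387315 0.002000846 10
#>   heart   none    iou 0.7222592 0.002963913 10
#>   heart  pskde   dice 0.9259305 0.002124425 10
#>   heart  pskde    iou 0.8620835 0.003685259 10

compare_methods(res$per_image[res$per_image$method == "pskde", ],
                res$per_image[res$per_image$method == "none", ])
#>  region method_a method_b metric        t       df            p significant
#>   heart    pskde     none   dice 94.48856 17.93573 1.188273e-25        TRUE
```

Ten phantoms were used for training, ten for validation. Enhancing with
the heart density model raises mean validation Dice from 0.839 to 0.926
(IoU 0.722 → 0.862), and Welch's t-test on the per-image Dice scores
calls the difference significant at p < 0.01. The fitted model itself
is inspectable:

```r
m <- res$models$heart
m$grid[which.max(m$density)]   # density peak at v = 0.647,
                               # the phantom's configured heart mean 0.65
```

Models round-trip losslessly through JSON
(`save_density_model()` / `load_density_model()`), so fitted densities
can be stored once and applied to any later image.

## Scope

8-bit grayscale PNG in/out only (no DICOM, no color). The reference
segmenter is an intensity-only probabilistic classifier, not a neural
network: it exercises the enhancement and evaluation machinery at desk
scale. See `vignettes/pskde-methods.Rmd` for the model, the numerical
choices, and the limitations of the synthetic phantom.
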