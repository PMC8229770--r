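# rcnnseg

Recurrent slice-sequence segmentation of 3D CT volumes in R.

Thin, elongated, anatomically connected structures — the mandible is the
canonical example — defeat the standard ways of feeding a 3D CT scan to an
encoder–decoder network (independent 2D slices, 2.5D slice stacks, 3D
patches), because truncating the scan discards the anatomical continuity
that identifies condyles, coronoids and artifact-corrupted regions. This
package implements the recurrent alternative: a single 2D U-Net-style unit is
shared across all slices and, at slice *t*, receives the slice *Iₜ*
concatenated with a learned convolution of the previous slice's predicted
probability map *Oₜ₋₁*:

> *Oₜ = σ( f\_{w_f}( concat(Iₜ, w_r ∗ Oₜ₋₁) ) )*

The model is unrolled over the whole scan (any number of slices, one
parameter set) and trained end-to-end by backpropagation through time with
the compound loss *L = Σₜ (α·BCEₜ + β·Diceₜ)*, α = β = 0.5, Adam, and early
stopping on the validation loss. Since no deep-learning framework is
available to R here, the convolutional layers and all backward passes are
part of the package (Rcpp/Armadillo), with gradients verified against finite
differences.

The package also provides:

* **Evaluation metrics** in physical mm under anisotropic spacing: Dice,
  average symmetric surface distance (ASD), 95% and maximum Hausdorff
  distance, validated against a naive all-pairs oracle to 1e-9 mm.
* **Feeding baselines**: the matched 2D per-slice network (the same unit
  minus the feedback pathway), a 2.5D variant, and 2D/2.5D/3D-patch dataset
  adapters with exact round-trip stitching.
* **Synthetic phantoms**: mandible-like U-shaped arches that split into
  thinning rami and protrusions across slices, with Gaussian noise and
  metal-like streak artifacts on a random subset of slices — exact ground
  truth by construction, fully seeded.
* **I/O**: NIfTI (`.nii`, `.nii.gz`) and NRRD (`.nrrd`) volumes and masks on
  a fixed `(slice, row, col)` axis convention.
* A command-line front end (`exec/rcnnseg`) with `generate`, `evaluate`,
  `train`, `predict` and `compare` subcommands.

## Worked example

Generate a phantom, inspect it, and overfit a small recurrent model on it:

```r
library(rcnnseg)

ph <- generate_phantom(phantom_spec(seed = 11))
ph$volume
#> <volume_grid> 16 x 64 x 64 (slice x row x col), spacing 1.25/1/1 mm
#>   intensity range [-2.351, 2.362]
ph$corrupted_slices
#> [1]  1  2  8  9 10

## a plain intensity threshold is already hurt by noise and streaks:
seg <- binary_mask(array(as.numeric(
         normalize_intensities(ph$volume$intensities, c(0, 1)) > 0.5),
         dim(ph$volume$intensities)), spacing = ph$volume$spacing)
evaluate_pair(seg, ph$mask)
#> <metrics_report> DSC 0.9365 | ASD 0.8653 mm | 95HD 10.6847 mm | HD 19.4695 mm

model <- rcnn_segmenter(unit_config(depth = 2, base_channels = 8),
                        seed = 1, window = c(0, 1))
model
#> <rcnn_segmenter> unet unit, depth 2, 8 base channels, 3x3 feedback kernel
#>   7147 trainable parameters (shared across all slices)

fit <- train(model, list(ph), list(ph),
             config = train_config(learning_rate = 1e-3, max_epochs = 150,
                                   patience = 150, seed = 2))
evaluate_pair(predict(fit, ph$volume), ph$mask)
#> <metrics_report> DSC 0.9713 | ASD 0.1504 mm | 95HD 1.0000 mm | HD 3.0000 mm
```

The fitted model repairs what the threshold cannot: the 95% Hausdorff
distance drops from ~10.7 mm to 1 mm because the recurrence carries the
shape across the streak-corrupted slices. `compare_feeding_strategies()`
runs the corresponding controlled comparison — recurrent model versus the
matched per-slice baseline under identical training budgets on held-out
phantoms (see the vignette for the experimental design).

## Layout

| Where | What |
|---|---|
| `R/grids.R`, `R/io.R`, `R/nrrd.R` | containers, axis conventions, NIfTI/NRRD I/O |
| `R/phantom.R` | phantom specification and generators |
| `R/metrics.R` | DSC, boundary extraction, ASD/HD/95HD, reports |
| `R/unit.R`, `src/primitives.cpp` | the encoder–decoder unit, forward/backward |
| `R/model.R`, `R/loss.R`, `R/train.R` | recurrence, compound loss, BPTT training |
| `R/feeding.R`, `R/baseline.R`, `R/compare.R` | feeding adapters, 2D/2.5D baselines, comparison harness |
| `vignettes/recurrent-slice-segmentation.Rmd` | the methods notes |
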