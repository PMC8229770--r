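---
title: "Recurrent slice-sequence segmentation: model, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent slice-sequence segmentation: model, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Encoder–decoder convolutional networks (the U-Net family) segment medical
images well, but a 3D CT scan does not fit through a 2D network, and full-3D
networks do not fit in memory at clinical resolution. The standard
workarounds — feeding 2D slices independently, feeding three consecutive
slices as channels ("2.5D"), or cropping 3D patches — all truncate the
anatomy. For elongated, anatomically connected structures such as the
mandible this truncation is exactly what hurts: thin superior processes
(condyles, coronoids) occupy a few ambiguous pixels per slice, and metal
streak artifacts can destroy the appearance of individual slices entirely.
What identifies these structures is not the single slice but the *continuity*
of the shape across slices.

This package implements a recurrent formulation of that idea. One 2D
encoder–decoder unit is shared across all slices of a scan; at slice $t$ it
receives two input channels, the slice $I_t$ and a learned transform of the
previous slice's predicted probability map $O_{t-1}$:

$$O_t = \sigma\!\left(f_{w_f}\!\big(\mathrm{concat}(I_t,\; w_r * O_{t-1})\big)\right),$$

where $f_{w_f}$ is the unit, $w_r$ a single 2D convolution and $\sigma$ the
logistic squashing. The model is unrolled along the slice axis, so a scan of
any length is processed with one fixed parameter set, and the previous
prediction acts as an explicit shape prior for the current slice. Training
backpropagates through the whole unrolled sequence (backpropagation through
time), so the network learns to *use* its own feedback.

## Model components and defaults

* **Unit** (`unit_config()`): a U-Net-style encoder–decoder with `depth`
  resolution levels (default 3), double 3×3 convolution + ReLU blocks, 2×2
  max pooling, nearest-neighbour upsampling with skip concatenation, and a
  1×1 output convolution. `base_channels` (default 16) doubles per level.
  `unit_kind = "attention_unet"` adds additive attention gates on the skip
  connections. In-plane sizes must be multiples of $2^{\text{depth}-1}$;
  anything else is an explicit shape error (with the required padding stated)
  rather than silent padding.
* **Recurrent transform**: a single `feedback_kernel`×`feedback_kernel`
  (default 3×3) convolution, 1→1 channel, applied to $O_{t-1}$ before
  concatenation. This is the minimal faithful reading of a learned linear
  recurrent weight acting on the fed-back map.
* **Feedback signal**: the *post-sigmoid* probability map, not the logits.
  Bounded feedback keeps long unrolls stable, and it is the previous output,
  not a hidden state, that carries the shape prior.
* **Initial state**: an all-zero map, so the first slice reduces to a plain
  two-channel network with a constant second channel. A neutral prior was
  preferred over learned initial states to keep step 1 interpretable.
* **Direction**: the recurrence runs in increasing slice index (axis 1 of the
  canonical `(slice, row, col)` order). Which anatomical direction that is
  depends on how the file was written; the package treats the choice as a
  convention, and `unroll(reverse_pass = TRUE)` optionally averages a second,
  reversed pass (off by default).
* **Loss** (`loss_weights()`): per slice, `alpha`·BCE + `beta`·soft-Dice with
  `alpha = beta = 0.5`. The soft-Dice smoothing is `eps = 1` in numerator and
  denominator (avoids 0/0 on empty targets), BCE clips probabilities at
  `1e-7`, and BCE is a *pixel mean* while the sequence loss is a *sum* over
  slices — step losses stay comparable across slice counts while the
  sequence total reflects scan length.
* **Training** (`train_config()`): Adam at learning rate `1e-4`, at most 40
  epochs, early stopping with patience 10 on the *validation loss*
  (validation Dice is logged alongside but does not drive stopping), best
  epoch restored. One optimization step processes one whole case: variable
  sequence lengths make per-slice minibatching awkward, and whole-sequence
  updates are what the recurrent formulation is about. There is no teacher
  forcing — the feedback during training is the model's own previous-step
  output, eliminating any train/inference mismatch. `tbptt_window` offers
  truncated backpropagation through time (state carried across windows
  without gradient) as a memory valve; any window covering the sequence is
  exactly equivalent to full BPTT, which the tests assert to 1e-6.

Because no deep-learning framework is available to R in this stack, the
convolution, pooling and upsampling primitives and all backward passes are
implemented in the package itself (Rcpp/Armadillo, im2col + GEMM), and the
gradients are verified against finite differences in the test suite.

## The synthetic phantom

Clinical CT with expert mandible annotations cannot ship with a package, so
the package carries a parametric phantom (`phantom_spec()`,
`generate_phantom()`) that reproduces the *geometry* that motivates the
recurrence:

* inferior slices contain a connected horseshoe "body";
* toward superior slices the body splits into two rami that thin and, in the
  top quarter, fragment into `protrusion_count` narrow processes per side
  (condyle/coronoid analogues);
* all parameters vary smoothly across slices, so every slice's foreground
  overlaps its neighbours' and the whole structure is one 26-connected
  component (asserted against a breadth-first-search oracle in the tests).

The intensity volume is a lightly smoothed indicator of the mask (background
0, foreground 1; the 3×3×3 smoothing kernel keeps the centre weight above
one half, so midpoint thresholding of a noiseless phantom recovers the mask
*exactly*), plus Gaussian noise, plus streak artifacts: on
`ceiling(artifact_fraction · n_slices)` randomly chosen slices, 4–8 random
straight lines of 1–2 voxel width overwrite intensities at
±`artifact_amplitude`. Streaks are the simplest analogue of metal artifacts:
they corrupt per-slice appearance while leaving inter-slice shape continuity
informative, which is precisely the failure mode the recurrence targets.
Defaults (`noise_sigma = 0.1`, `artifact_fraction = 0.3`,
`artifact_amplitude = 2`) were fixed once as the package's study conditions.

What the phantom does *not* emulate: Hounsfield-calibrated tissue intensity,
beam hardening or photon starvation physics, anatomical shape variability
beyond smooth parameter jitter, or neighbouring confusable structures (teeth,
skull). Passing tests on phantoms therefore demonstrate that the machinery —
recurrence, loss, optimization, metrics — works and that slice continuity is
exploitable; they do not certify clinical accuracy.

## Evaluation metrics

`evaluate_pair()` reports the Dice coefficient and three boundary distances
in physical mm under anisotropic voxel spacing: the average symmetric surface
distance (mean of the two directed average nearest-boundary distances, each
normalized by its source set size), the Hausdorff distance (max of the two
directed maxima) and the 95% Hausdorff distance (directed maxima replaced by
95th percentiles, discarding small outlier regions). Conventions the
definitions leave open are pinned down as: boundary voxels are foreground
voxels with a background 6-neighbour (the volume border counts as
background); voxel coordinates are voxel-centred, `origin + index · spacing`;
the percentile uses the linear-interpolation rule (`quantile()` type 7); and
for empty predictions Dice is 0 and the distances are flagged undefined
rather than silently zeroed (two empty masks have Dice 1). All three
distances are validated to 1e-9 mm against a naive all-pairs oracle on
random anisotropic mask pairs.

## A small experiment

```{r, eval = FALSE}
library(rcnnseg)

spec <- phantom_spec(shape = c(16, 48, 48), spacing = c(1.25, 1, 1),
                     arch_radius_mm = 15, limb_thickness_mm = 7,
                     artifact_fraction = 0.3, noise_sigma = 0.1)
cases <- generate_dataset(8, spec, seed = 101)
tab <- compare_feeding_strategies(
  cases,
  config = train_config(learning_rate = 1e-3, max_epochs = 25, patience = 25,
                        seed = 1),
  unit = unit_config(depth = 2, base_channels = 8),
  strategies = c("recurrent", "slice2d"), window = c(0, 1))
tab[tab$case %in% c("mean", "sd"), ]
```

The harness splits the cases (seeded) into train/validation/test, trains each
arm with an identical budget, and evaluates the held-out cases with
`evaluate_pair()`. The 2D baseline is the same unit minus the feedback
pathway (one input channel, no recurrent transform), so the comparison
isolates the recurrence itself; a 2.5D arm (`"slice25d"`) is available. A
trainable 3D-patch arm is not provided — it would require a 3D convolution
stack that contributes nothing to the recurrent method — but the 3D-patch
dataset adapter and overlap-averaging stitcher (`make_patch3d_samples()`,
`stitch_patches()`) are implemented and tested.

## Numerical and scale choices

* **Problem sizes.** The shipped experiments run at 48×48–64×64 in-plane
  with 12–24 slices, depth-2 units with 8 base channels, 25-epoch comparison
  budgets and a 150-step overfit budget. These sizes were chosen so that the
  full suite and the reproduction script each complete in minutes on one CPU
  core while still exercising every architectural property; they are the
  package's desk-scale study conditions, not clinical settings.
* **Learning rates.** `train_config()` defaults to the whole-dataset regime
  (`1e-4`, 40 epochs). The short phantom runs use `1e-3`: a few hundred Adam
  steps is not the regime the default was specified for, and `1e-4` merely
  converges more slowly without changing any qualitative outcome.
* **Normalization.** `normalize_intensities()` clips to a window and
  rescales to [0, 1]. For CT-like inputs a fixed bone-inclusive window (e.g.
  `c(-500, 2000)` HU) makes the mapping scan-independent; for phantoms the
  window `c(0, 1)` is the natural choice because the phantom's design
  contrast *is* 0/1 — per-scan min–max would let streak outliers compress
  the foreground contrast arbitrarily. With `window = NULL` the package
  passes through data already in [0, 1] and min–max scales anything else.
* **Reproducibility.** Every stochastic operation draws from a private,
  seeded stream and restores the caller's RNG state; phantoms, dataset
  jitter, initialization, shuffling and patch sampling are all bit-exactly
  reproducible from their seeds, and no function touches global random state.
* **Ties and degenerate inputs.** Max-pooling resolves ties to the first
  maximum in scan order; empty training targets raise a degenerate-data
  warning but train (the Dice smoothing keeps the loss finite); reading a
  mask on a mismatched grid is an error, never a silent resample, with
  spacing compared at 1e-4 mm to absorb header rounding.

## Known limitations

* The recurrence is unidirectional by default; structures whose identity is
  only resolvable from the other anatomical direction benefit from
  `reverse_pass = TRUE`, which is an inference-time ensemble rather than a
  trained bidirectional model.
* Gated recurrences (LSTM/GRU-style) are deliberately out of scope: the
  vanilla formulation is the point, keeping end-to-end training cheap.
* The unit is one configurable U-Net family; it stands in for the broader
  zoo of encoder–decoder variants rather than replicating any specific one.
* The hand-rolled NRRD reader covers scalar images with raw/gzip encodings
  and `spacings`/diagonal `space directions` headers — sufficient for
  standard segmentation exchange files, not a general NRRD implementation.
* CPU-only: training at 512×512 clinical resolution is possible in principle
  but not practical here; the package is built for method study at phantom
  scale and for inference-sized workloads.
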