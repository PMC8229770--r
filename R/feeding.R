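#' Batch specification for the classic feeding strategies
#'
#' The three standard ways of feeding a 3D volume to an encoder-decoder
#' network: independent 2D slices (`slice2d`), three consecutive slices as
#' channels (`slice25d`; the context is fixed at exactly 3), or 3D patches
#' cropped from the volume (`patch3d`).
#'
#' @param strategy `"slice2d"`, `"slice25d"` or `"patch3d"`.
#' @param patch_shape integer triple `(slices, rows, cols)`, `patch3d` only.
#' @return An object of class `sample_batch_spec`.
#' @export
sample_batch_spec <- function(strategy = c("slice2d", "slice25d", "patch3d"),
                              patch_shape = c(8L, 64L, 64L)) {
  strategy <- match.arg(strategy)
  patch_shape <- as.integer(patch_shape)
  stopifnot(length(patch_shape) == 3L, all(patch_shape >= 1L))
  structure(list(strategy = strategy, patch_shape = patch_shape, context = 3L),
            class = "sample_batch_spec")
}

#' Per-slice (2D) samples from a volume/mask pair
#'
#' One sample per slice in canonical order; the input is the slice as a
#' 1-channel image, the target its mask slice.  Concatenating the targets
#' reconstructs the mask exactly.
#'
#' @param volume a [volume_grid()].
#' @param mask the congruent [binary_mask()].
#' @return A list of `n_slices` lists with elements `input` (H x W x 1 array)
#'   and `target` (H x W matrix).
#' @export
make_slice2d_samples <- function(volume, mask) {
  check_congruent(volume, mask)
  a <- volume$intensities
  lapply(seq_len(dim(a)[1]), function(t)
    list(input = array(a[t, , ], c(dim(a)[2:3], 1L)),
         target = mask$labels[t, , ]))
}

#' Three-consecutive-slice (2.5D) samples
#'
#' One sample per slice; the channels are slices `t - 1`, `t`, `t + 1` (the
#' boundary slice is replicated at the two ends, keeping the sample count
#' equal to the slice count) and the target is slice `t`.
#'
#' @inheritParams make_slice2d_samples
#' @return A list of `n_slices` lists with `input` (H x W x 3) and `target`.
#' @export
make_slice25d_samples <- function(volume, mask) {
  check_congruent(volume, mask)
  a <- volume$intensities
  S <- dim(a)[1]
  lapply(seq_len(S), function(t) {
    ctx <- c(max(1L, t - 1L), t, min(S, t + 1L))
    list(input = array(aperm(a[ctx, , , drop = FALSE], c(2, 3, 1)),
                       c(dim(a)[2:3], 3L)),
         target = mask$labels[t, , ])
  })
}

#' 3D patch samples and overlap-averaged stitching
#'
#' `make_patch3d_samples()` tiles the volume with a regular grid of patches of
#' `spec$patch_shape` at 50% overlap (strides of half the patch size, with a
#' final patch flush against each border) so that every voxel is covered at
#' least once, optionally plus `n_random` seeded random training patches.
#' `stitch_patches()` inverts the decomposition: per-voxel averaging of the
#' (identical, for targets) overlapping contributions, so stitching the target
#' patches reproduces the mask bit-exactly.
#'
#' @inheritParams make_slice2d_samples
#' @param spec a `patch3d` [sample_batch_spec()].
#' @param seed integer seed for the random patches.
#' @param n_random number of additional random patches.
#' @return A list with `samples` (list of `input`/`target` 3D arrays and
#'   1-based `offset` triples) and `shape` (the full volume shape).
#' @export
make_patch3d_samples <- function(volume, mask,
                                 spec = sample_batch_spec("patch3d"),
                                 seed = 1L, n_random = 0L) {
  check_congruent(volume, mask)
  stopifnot(inherits(spec, "sample_batch_spec"), spec$strategy == "patch3d")
  d <- grid_shape(volume); p <- spec$patch_shape
  if (any(p > d))
    stop(sprintf("geometry error: patch %s larger than volume %s",
                 paste(p, collapse = "x"), paste(d, collapse = "x")), call. = FALSE)
  starts <- lapply(1:3, function(ax) {
    stride <- max(1L, p[ax] %/% 2L)
    unique(c(seq(1L, d[ax] - p[ax] + 1L, by = stride), d[ax] - p[ax] + 1L))
  })
  offs <- expand.grid(starts[[1]], starts[[2]], starts[[3]])
  if (n_random > 0L) {
    rnd <- with_local_seed(seed, {
      cbind(sample.int(d[1] - p[1] + 1L, n_random, replace = TRUE),
            sample.int(d[2] - p[2] + 1L, n_random, replace = TRUE),
            sample.int(d[3] - p[3] + 1L, n_random, replace = TRUE))
    })
    offs <- rbind(as.matrix(offs), rnd)
  } else offs <- as.matrix(offs)
  samples <- lapply(seq_len(nrow(offs)), function(i) {
    o <- as.integer(offs[i, ])
    ix <- lapply(1:3, function(ax) o[ax]:(o[ax] + p[ax] - 1L))
    list(input = volume$intensities[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
         target = mask$labels[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
         offset = o)
  })
  list(samples = samples, shape = d)
}

#' @param patches list of 3D arrays (e.g. predicted probability patches).
#' @param offsets list/matrix of 1-based offset triples matching `patches`.
#' @param shape full volume shape triple.
#' @rdname make_patch3d_samples
#' @export
stitch_patches <- function(patches, offsets, shape) {
  acc <- array(0, shape); cnt <- array(0, shape)
  if (is.matrix(offsets)) offsets <- lapply(seq_len(nrow(offsets)),
                                            function(i) offsets[i, ])
  for (i in seq_along(patches)) {
    o <- as.integer(offsets[[i]]); p <- dim(patches[[i]])
    ix <- lapply(1:3, function(ax) o[ax]:(o[ax] + p[ax] - 1L))
    acc[ix[[1]], ix[[2]], ix[[3]]] <- acc[ix[[1]], ix[[2]], ix[[3]]] + patches[[i]]
    cnt[ix[[1]], ix[[2]], ix[[3]]] <- cnt[ix[[1]], ix[[2]], ix[[3]]] + 1
  }
  if (any(cnt == 0)) stop("stitch_patches: uncovered voxels", call. = FALSE)
  acc / cnt
}

## Inputs-only versions used at prediction time (slices already normalized,
## passed as an (S, H, W) array).
slice_inputs <- function(strategy, slices) {
  S <- dim(slices)[1]
  if (strategy == "slice2d")
    return(lapply(seq_len(S), function(t)
      array(slices[t, , ], c(dim(slices)[2:3], 1L))))
  lapply(seq_len(S), function(t) {
    ctx <- c(max(1L, t - 1L), t, min(S, t + 1L))
    array(aperm(slices[ctx, , , drop = FALSE], c(2, 3, 1)),
          c(dim(slices)[2:3], 3L))
  })
}
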