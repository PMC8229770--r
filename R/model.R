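#' Build a recurrent slice-sequence segmenter
#'
#' Constructs the recurrent segmentation model: one shared 2D encoder-decoder
#' unit (see [unit_config()]) plus one recurrent transform, a single
#' `feedback_kernel x feedback_kernel` convolution applied to the previous
#' slice's probability map.  At slice `t` the model computes
#' `O_t = unit(concat(I_t, conv_r(O_{t-1})))` followed by a sigmoid, so the
#' fed-back signal is always a bounded probability map.  All parameters are
#' shared across the unrolled sequence: the parameter count is independent of
#' how many slices the model is unrolled over, and the same model handles
#' scans of any length.  The initial state `O_0` is an all-zero map.
#'
#' @param config a [unit_config()].
#' @param seed integer; parameter initialization is deterministic in the seed.
#' @param window intensity normalization window passed to
#'   [normalize_intensities()] (`NULL` for the adaptive default).
#' @return An object of class `rcnn_segmenter` with elements `config`,
#'   `params` (named list of arrays), `window`, `seed`.
#' @examples
#' m <- rcnn_segmenter(unit_config(depth = 2, base_channels = 4), seed = 1)
#' length(coef(m))
#' @export
rcnn_segmenter <- function(config = unit_config(), seed = 1L, window = NULL) {
  stopifnot(inherits(config, "unit_config"))
  k <- config$feedback_kernel
  params <- with_local_seed(seed, {
    p <- init_unit_params(config, n_in = 2L)
    add_param(p, "fb", conv_param(k, k, 1, 1))
  })
  structure(list(config = config, params = params, window = window,
                 seed = as.integer(seed)),
            class = "rcnn_segmenter")
}

#' @export
print.rcnn_segmenter <- function(x, ...) {
  cat(sprintf("<rcnn_segmenter> %s unit, depth %d, %d base channels, %dx%d feedback kernel\n",
              x$config$unit_kind, x$config$depth, x$config$base_channels,
              x$config$feedback_kernel, x$config$feedback_kernel))
  cat(sprintf("  %d trainable parameters (shared across all slices)\n",
              param_count(x$params)))
  invisible(x)
}

#' @export
coef.rcnn_segmenter <- function(object, ...) object$params

#' One recurrent step: segment a slice given the previous prediction
#'
#' Applies the recurrent transform to `state`, concatenates the result with
#' the (normalized, `[0, 1]`) slice as a second channel, runs the shared unit
#' and squashes the logits to a probability map, which becomes the next state.
#'
#' @param model an [rcnn_segmenter()].
#' @param slice_t numeric matrix, the current slice with intensities in `[0, 1]`.
#' @param state the previous slice's probability map (matrix of the same
#'   shape), or `NULL` for the all-zero initial state.
#' @return A list with `prob` (probability map matrix) and `state` (identical
#'   to `prob`; pass it to the next step).
#' @export
rcnn_step <- function(model, slice_t, state = NULL) {
  stopifnot(inherits(model, "rcnn_segmenter"))
  slice_t <- as.matrix(slice_t)
  if (is.null(state)) state <- matrix(0, nrow(slice_t), ncol(slice_t))
  if (!identical(dim(slice_t), dim(as.matrix(state))))
    stop("shape error: slice and recurrent state shapes differ", call. = FALSE)
  st <- step_forward(model$params, model$config, slice_t, as.matrix(state))
  list(prob = st$prob, state = st$prob)
}

## Internal single-step forward; returns caches for BPTT when keep_cache.
step_forward <- function(params, cfg, slice_t, state, keep_cache = FALSE) {
  fb_in <- array(state, c(dim(state), 1L))
  fb <- conv_fwd(fb_in, params, "fb")
  x <- cat_channels(array(slice_t, c(dim(slice_t), 1L)), fb)
  uf <- unit_forward(params, cfg, x)
  prob <- sigmoid(uf$logits)
  if (keep_cache) list(prob = prob, fb_in = fb_in, cache = uf$cache)
  else list(prob = prob)
}

## Forward over a (S, H, W) slice array; probs as list of matrices.
forward_sequence <- function(params, cfg, slices, init_state = NULL,
                             keep_cache = FALSE) {
  S <- dim(slices)[1]
  hw <- dim(slices)[2:3]
  state <- if (is.null(init_state)) matrix(0, hw[1], hw[2]) else init_state
  probs <- vector("list", S)
  caches <- if (keep_cache) vector("list", S) else NULL
  for (t in seq_len(S)) {
    st <- step_forward(params, cfg, slices[t, , ], state, keep_cache)
    probs[[t]] <- st$prob
    if (keep_cache) caches[[t]] <- st[c("fb_in", "cache")]
    state <- st$prob
  }
  list(probs = probs, caches = caches, final_state = state)
}

#' Unroll the recurrent segmenter over a whole volume
#'
#' Normalizes the volume's intensities (see [normalize_intensities()]) and
#' iterates [rcnn_step()] along the slice axis in canonical order, threading
#' the recurrent state, for sequences of any length (no reconfiguration
#' between volumes of different slice counts).
#'
#' @param model an [rcnn_segmenter()].
#' @param volume a [volume_grid()].
#' @param reverse_pass if `TRUE`, also run the recurrence superior-to-inferior
#'   and average the two probability maps per slice (off by default; the
#'   canonical recurrence is unidirectional).
#' @return A list of `n_slices` probability-map matrices.
#' @export
unroll <- function(model, volume, reverse_pass = FALSE) {
  stopifnot(inherits(model, "rcnn_segmenter"), inherits(volume, "volume_grid"))
  slices <- normalize_intensities(volume$intensities, model$window)
  check_unit_shape(model$config, dim(slices)[2:3])
  probs <- forward_sequence(model$params, model$config, slices)$probs
  if (reverse_pass) {
    rev_slices <- slices[rev(seq_len(dim(slices)[1])), , , drop = FALSE]
    rp <- rev(forward_sequence(model$params, model$config, rev_slices)$probs)
    probs <- lapply(seq_along(probs), function(t) (probs[[t]] + rp[[t]]) / 2)
  }
  probs
}

#' Predict a binary segmentation mask for a volume
#'
#' Stacks the probability maps from [unroll()] and thresholds them.
#'
#' @param object an [rcnn_segmenter()].
#' @param volume a [volume_grid()].
#' @param threshold probability threshold in `(0, 1)`.
#' @param ... passed to [unroll()] (e.g. `reverse_pass`).
#' @return A [binary_mask()] on the volume's grid.
#' @export
predict.rcnn_segmenter <- function(object, volume, threshold = 0.5, ...) {
  stopifnot(threshold > 0, threshold < 1)
  probs <- unroll(object, volume, ...)
  d <- dim(volume$intensities)
  m <- array(0, d)
  for (t in seq_along(probs)) m[t, , ] <- as.numeric(probs[[t]] >= threshold)
  binary_mask(m, spacing = volume$spacing, origin_mm = volume$origin_mm)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the parameters, the unit
#' configuration and the normalization window (plus the training history when
#' saving a fitted object).
#'
#' @param model an [rcnn_segmenter()] or [train()] result.
#' @param path file path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the restored object.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("rcnn_segmenter", "rcnn_fit", "unit2d_segmenter")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("rcnn_segmenter", "rcnn_fit", "unit2d_segmenter")))
    stop("config error: file does not contain a model checkpoint", call. = FALSE)
  obj
}
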