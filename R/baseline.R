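#' Per-slice baseline segmenter (no recurrence)
#'
#' The matched control for the recurrent model: the identical encoder-decoder
#' unit, fed by one of the classic strategies -- each slice independently
#' (`slice2d`, 1 input channel) or with its two neighbours as context
#' (`slice25d`, 3 input channels).  Parameter counts differ from the recurrent
#' model only in the first-layer input channels and the absent feedback
#' transform, so comparisons isolate the effect of the recurrence.
#'
#' @param config a [unit_config()] (the feedback kernel is ignored here).
#' @param strategy `"slice2d"` or `"slice25d"`.
#' @param seed integer initialization seed.
#' @param window normalization window (see [normalize_intensities()]).
#' @return An object of class `unit2d_segmenter`.
#' @export
unit2d_segmenter <- function(config = unit_config(), strategy = c("slice2d", "slice25d"),
                             seed = 1L, window = NULL) {
  stopifnot(inherits(config, "unit_config"))
  strategy <- match.arg(strategy)
  n_in <- if (strategy == "slice2d") 1L else 3L
  params <- with_local_seed(seed, init_unit_params(config, n_in = n_in))
  structure(list(config = config, params = params, strategy = strategy,
                 n_in = n_in, window = window, seed = as.integer(seed)),
            class = "unit2d_segmenter")
}

#' @export
print.unit2d_segmenter <- function(x, ...) {
  cat(sprintf("<unit2d_segmenter> %s feeding, %s unit, depth %d, %d base channels, %d parameters\n",
              x$strategy, x$config$unit_kind, x$config$depth,
              x$config$base_channels, param_count(x$params)))
  invisible(x)
}

#' @export
coef.unit2d_segmenter <- function(object, ...) object$params

unit2d_probs <- function(model, volume) {
  slices <- normalize_intensities(volume$intensities, model$window)
  check_unit_shape(model$config, dim(slices)[2:3])
  inputs <- slice_inputs(model$strategy, slices)
  lapply(inputs, function(x)
    sigmoid(unit_forward(model$params, model$config, x)$logits))
}

#' @export
predict.unit2d_segmenter <- function(object, volume, threshold = 0.5, ...) {
  stopifnot(inherits(volume, "volume_grid"), threshold > 0, threshold < 1)
  probs <- unit2d_probs(object, volume)
  probs_to_mask(probs, volume, threshold)
}

## Summed per-slice loss and gradient for one case (batch = one volume, so
## the update count per epoch matches the recurrent arm exactly).
unit2d_case_gradient <- function(model, volume, mask, weights) {
  slices <- normalize_intensities(volume$intensities, model$window)
  inputs <- slice_inputs(model$strategy, slices)
  grads <- list(); loss <- 0
  for (t in seq_along(inputs)) {
    uf <- unit_forward(model$params, model$config, inputs[[t]])
    p <- sigmoid(uf$logits)
    tg <- mask$labels[t, , ]
    loss <- loss + step_loss(p, tg, weights)
    dlog <- step_loss_grad(p, tg, weights) * p * (1 - p)
    ub <- unit_backward(model$params, model$config, uf$cache, dlog)
    grads <- merge_grads(grads, ub$grads)
  }
  list(loss = loss, grads = grads[names(model$params)])
}

#' @rdname train
#' @export
train.unit2d_segmenter <- function(object, train_cases, val_cases,
                                   config = train_config(),
                                   weights = loss_weights(), ...) {
  check_cases(train_cases, "training"); check_cases(val_cases, "validation")
  stopifnot(inherits(config, "train_config"))
  model <- object
  res <- fit_loop(
    model$params, length(train_cases), config,
    case_grad = function(params, i) {
      model$params <- params
      unit2d_case_gradient(model, train_cases[[i]]$volume,
                           train_cases[[i]]$mask, weights)
    },
    validate = function(params) {
      model$params <- params
      validate_cases(model, val_cases, weights, config$threshold)
    })
  model$params <- res$params
  new_fit(model, res, config, weights)
}
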