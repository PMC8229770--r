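#' Loss weights for the compound segmentation loss
#'
#' The per-slice training loss is `alpha * BCE + beta * soft-Dice`; the
#' defaults `alpha = beta = 0.5` weight the two terms equally, the
#' configuration used throughout training here.
#'
#' @param alpha nonnegative weight of the binary cross-entropy term.
#' @param beta nonnegative weight of the soft-Dice term.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.5, beta = 0.5) {
  stopifnot(alpha >= 0, beta >= 0)
  if (alpha + beta <= 0)
    stop("loss_weights: alpha + beta must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "loss_weights")
}

DICE_EPS <- 1.0    # soft-Dice smoothing (numerator and denominator)
BCE_EPS <- 1e-7    # probability clipping before logs

#' Per-slice segmentation losses
#'
#' `dice_loss()` is the soft Dice loss
#' `1 - (2 sum(p g) + eps) / (sum(p) + sum(g) + eps)` with smoothing
#' `eps = 1`, zero (up to the eps effect) when the prediction reproduces the
#' binary target and close to 1 under total disagreement.  `bce_loss()` is the
#' pixel-mean binary cross-entropy with predictions clipped to
#' `[1e-7, 1 - 1e-7]`.  `step_loss()` combines them as
#' `alpha * BCE + beta * Dice`, and `sequence_loss()` sums step losses over an
#' unrolled slice sequence (a plain sum, no length normalization, so the loss
#' of a concatenated sequence is the sum of the parts).
#'
#' @param pred numeric matrix of probabilities in `[0, 1]`.
#' @param target numeric matrix over \{0, 1\} of the same shape.
#' @param weights a [loss_weights()].
#' @param preds,targets equal-length lists of prediction/target matrices.
#' @return Scalar loss value.
#' @export
dice_loss <- function(pred, target) {
  check_same_shape(pred, target)
  1 - (2 * sum(pred * target) + DICE_EPS) /
    (sum(pred) + sum(target) + DICE_EPS)
}

#' @rdname dice_loss
#' @export
bce_loss <- function(pred, target) {
  check_same_shape(pred, target)
  p <- pmin(pmax(pred, BCE_EPS), 1 - BCE_EPS)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' @rdname dice_loss
#' @export
step_loss <- function(pred, target, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  weights$alpha * bce_loss(pred, target) + weights$beta * dice_loss(pred, target)
}

#' @rdname dice_loss
#' @export
sequence_loss <- function(preds, targets, weights = loss_weights()) {
  if (length(preds) != length(targets))
    stop(sprintf("argument error: %d predictions vs %d targets",
                 length(preds), length(targets)), call. = FALSE)
  sum(vapply(seq_along(preds),
             function(t) step_loss(preds[[t]], targets[[t]], weights),
             numeric(1)))
}

check_same_shape <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) ||
      (is.null(dim(pred)) && length(pred) != length(target)))
    stop("shape error: prediction and target shapes differ", call. = FALSE)
  invisible(TRUE)
}

## Analytic gradient of the compound step loss with respect to the predicted
## probabilities; must stay in exact correspondence with dice_loss/bce_loss.
step_loss_grad <- function(pred, target, weights) {
  n <- length(pred)
  p <- pmin(pmax(pred, BCE_EPS), 1 - BCE_EPS)
  dbce <- (-(target / p) + (1 - target) / (1 - p)) / n
  dbce[pred <= BCE_EPS | pred >= 1 - BCE_EPS] <- 0
  sp <- sum(pred); sg <- sum(target); spg <- sum(pred * target)
  den <- sp + sg + DICE_EPS
  ddice <- -(2 * target * den - (2 * spg + DICE_EPS)) / den^2
  weights$alpha * dbce + weights$beta * ddice
}
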