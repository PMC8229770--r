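#' Training configuration
#'
#' Defaults follow the whole-scan training regime: Adam with learning rate
#' `1e-4`, at most 40 epochs, early stopping when the validation loss has not
#' improved for 10 epochs (the best-epoch parameters are restored).
#' `tbptt_window` truncates backpropagation through time: gradients never
#' cross window boundaries (the recurrent state is passed forward detached),
#' while the loss is still the full-sequence sum.  `"full"`, or any window at
#' least as long as the sequence, gives exact whole-sequence gradients.
#'
#' @param learning_rate positive Adam learning rate.
#' @param max_epochs maximum number of epochs (0 = no training, e.g. to probe
#'   a warm start).
#' @param patience epochs without validation-loss improvement before stopping
#'   (>= 1, and at most `max_epochs` when that is positive).
#' @param tbptt_window `"full"` or a positive integer window length.
#' @param seed integer seed driving case shuffling (and nothing else).
#' @param threshold probability threshold used for the validation Dice log.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, max_epochs = 40L, patience = 10L,
                         tbptt_window = "full", seed = 1L, threshold = 0.5) {
  max_epochs <- as.integer(max_epochs); patience <- as.integer(patience)
  stopifnot(learning_rate > 0, max_epochs >= 0L, threshold > 0, threshold < 1)
  if (patience < 1L)
    stop("train_config: patience must be >= 1", call. = FALSE)
  if (max_epochs > 0L && patience > max_epochs)
    stop("train_config: patience must not exceed max_epochs", call. = FALSE)
  if (!identical(tbptt_window, "full")) {
    tbptt_window <- as.integer(tbptt_window)
    stopifnot(tbptt_window >= 1L)
  }
  structure(list(learning_rate = learning_rate, max_epochs = max_epochs,
                 patience = patience, tbptt_window = tbptt_window,
                 seed = as.integer(seed), threshold = threshold),
            class = "train_config")
}

## ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  corr1 <- 1 - beta1^st$t; corr2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / corr1) / (sqrt(st$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = st)
}

merge_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

## ---- BPTT gradient for one case --------------------------------------------

#' Whole-sequence loss and parameter gradient for one case
#'
#' Unrolls the model over the volume, computes the summed compound loss
#' against the stacked ground-truth slices, and backpropagates through time:
#' the gradient at step `t` flows both into the loss at `t` and, through the
#' recurrent transform, into step `t + 1`.  With a finite `tbptt_window` the
#' sequence is processed in windows whose boundary states are detached.
#'
#' @param model an [rcnn_segmenter()].
#' @param volume,mask a congruent case.
#' @param weights a [loss_weights()].
#' @param tbptt_window `"full"` or a positive integer.
#' @return List with `loss` (summed sequence loss), `grads` (named list
#'   matching `coef(model)`) and `probs` (per-slice probability maps).
#' @export
rcnn_gradient <- function(model, volume, mask, weights = loss_weights(),
                          tbptt_window = "full") {
  stopifnot(inherits(model, "rcnn_segmenter"))
  check_congruent(volume, mask)
  slices <- normalize_intensities(volume$intensities, model$window)
  S <- dim(slices)[1]
  check_unit_shape(model$config, dim(slices)[2:3])
  win <- if (identical(tbptt_window, "full")) S else min(S, tbptt_window)
  starts <- seq(1L, S, by = win)
  grads <- list(); probs <- vector("list", S); loss <- 0
  state <- matrix(0, dim(slices)[2], dim(slices)[3])
  for (s0 in starts) {
    ts <- s0:min(S, s0 + win - 1L)
    fw <- forward_sequence(model$params, model$config,
                           slices[ts, , , drop = FALSE], init_state = state,
                           keep_cache = TRUE)
    state <- fw$final_state            # detached across the window boundary
    tg <- lapply(ts, function(t) mask$labels[t, , ])
    loss <- loss + sequence_loss(fw$probs, tg, weights)
    bw <- backward_chunk(model$params, model$config, fw, tg, weights)
    grads <- merge_grads(grads, bw)
    probs[ts] <- fw$probs
  }
  list(loss = loss, grads = grads[names(model$params)], probs = probs)
}

backward_chunk <- function(params, cfg, fw, targets, weights) {
  grads <- list()
  d_state <- NULL
  for (t in rev(seq_along(fw$probs))) {
    p <- fw$probs[[t]]
    dO <- step_loss_grad(p, targets[[t]], weights)
    if (!is.null(d_state)) dO <- dO + d_state
    dlog <- dO * p * (1 - p)
    ub <- unit_backward(params, cfg, fw$caches[[t]]$cache, dlog)
    grads <- merge_grads(grads, ub$grads)
    bk <- conv_bwd(fw$caches[[t]]$fb_in, params, "fb",
                   ub$dx[, , 2L, drop = FALSE])
    grads <- acc_grad(grads, "fb", bk$dw, bk$db)
    d_state <- bk$dx[, , 1L]
  }
  grads
}

## ---- generic fitting loop ---------------------------------------------------

## One Adam update per training case (batch = one sequence), validation after
## each epoch, early stopping on the validation loss, best-epoch restore.
fit_loop <- function(params, n_cases, config, case_grad, validate) {
  opt <- adam_init(params)
  hist <- list()
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  stop_reason <- "completed"
  if (config$max_epochs == 0L)
    return(list(params = params, history = empty_history(),
                best_epoch = 0L, stop_reason = "completed"))
  order_seeds <- derive_seeds(config$seed, config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_local_seed(order_seeds[epoch], sample.int(n_cases))
    losses <- numeric(0)
    for (i in ord) {
      cg <- case_grad(params, i)
      losses <- c(losses, cg$loss)
      upd <- adam_step(params, cg$grads, opt, config$learning_rate)
      params <- upd$params; opt <- upd$state
    }
    v <- validate(params)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                val_loss = v$loss, val_dsc = v$dsc)
    if (v$loss < best_val) {
      best_val <- v$loss; best_params <- params; best_epoch <- epoch
    }
    if (epoch - best_epoch >= config$patience) {
      stop_reason <- "early_stopped"
      break
    }
  }
  list(params = best_params, history = do.call(rbind, hist),
       best_epoch = best_epoch, stop_reason = stop_reason)
}

empty_history <- function()
  data.frame(epoch = integer(0), train_loss = numeric(0),
             val_loss = numeric(0), val_dsc = numeric(0))

check_cases <- function(cases, what) {
  if (length(cases) < 1L)
    stop(sprintf("argument error: need at least one %s case", what), call. = FALSE)
  for (cs in cases) {
    stopifnot(inherits(cs$volume, "volume_grid"), inherits(cs$mask, "binary_mask"))
    check_congruent(cs$volume, cs$mask)
  }
  invisible(TRUE)
}

#' Train a segmentation model
#'
#' `train()` is a generic with methods for the recurrent segmenter
#' ([rcnn_segmenter()]) and the per-slice baseline ([unit2d_segmenter()]).
#' Each optimization step processes one case (one full sequence, or a
#' truncated-BPTT window chain for the recurrent model) and updates all shared
#' parameters with Adam; after every epoch the validation loss (early-stopping
#' criterion) and validation Dice (logged) are computed.  Training stops at
#' `max_epochs` or when the validation loss has not improved for `patience`
#' epochs, and the parameters of the best validation epoch are restored.
#' Runs are reproducible from the configuration seed.
#'
#' @param object the model to train.
#' @param ... method arguments.
#' @return An object of class `rcnn_fit`: list with `model` (the trained
#'   model), `history` (per-epoch `data.frame`), `best_epoch`, `stop_reason`
#'   (`"completed"` or `"early_stopped"`), `config`, `weights`.
#' @export
train <- function(object, ...) UseMethod("train")

#' @param train_cases,val_cases lists of cases, each a list with elements
#'   `volume` ([volume_grid()]) and `mask` ([binary_mask()]); phantom
#'   generator output can be passed directly.
#' @param config a [train_config()].
#' @param weights a [loss_weights()].
#' @rdname train
#' @export
train.rcnn_segmenter <- function(object, train_cases, val_cases,
                                 config = train_config(),
                                 weights = loss_weights(), ...) {
  check_cases(train_cases, "training"); check_cases(val_cases, "validation")
  stopifnot(inherits(config, "train_config"))
  if (all(vapply(train_cases, function(cs) sum(cs$mask$labels) == 0, logical(1))))
    warning("degenerate data: every training case has an empty target mask; ",
            "training proceeds but there is no foreground signal")
  model <- object
  res <- fit_loop(
    model$params, length(train_cases), config,
    case_grad = function(params, i) {
      model$params <- params
      rcnn_gradient(model, train_cases[[i]]$volume, train_cases[[i]]$mask,
                    weights, config$tbptt_window)
    },
    validate = function(params) {
      model$params <- params
      validate_cases(model, val_cases, weights, config$threshold)
    })
  model$params <- res$params
  new_fit(model, res, config, weights)
}

validate_cases <- function(model, cases, weights, threshold) {
  losses <- numeric(length(cases)); dscs <- numeric(length(cases))
  for (i in seq_along(cases)) {
    vol <- cases[[i]]$volume; msk <- cases[[i]]$mask
    probs <- if (inherits(model, "rcnn_segmenter")) unroll(model, vol)
             else unit2d_probs(model, vol)
    tg <- lapply(seq_along(probs), function(t) msk$labels[t, , ])
    losses[i] <- sequence_loss(probs, tg, weights)
    pred <- probs_to_mask(probs, vol, threshold)
    dscs[i] <- dsc(pred, msk)
  }
  list(loss = mean(losses), dsc = mean(dscs))
}

probs_to_mask <- function(probs, volume, threshold) {
  m <- array(0, dim(volume$intensities))
  for (t in seq_along(probs)) m[t, , ] <- as.numeric(probs[[t]] >= threshold)
  binary_mask(m, spacing = volume$spacing, origin_mm = volume$origin_mm)
}

new_fit <- function(model, res, config, weights) {
  structure(list(model = model, history = res$history,
                 best_epoch = res$best_epoch, stop_reason = res$stop_reason,
                 config = config, weights = weights),
            class = "rcnn_fit")
}

#' Resume training from a pre-trained checkpoint
#'
#' Identical loop to [train()] but initialized from the checkpoint's
#' parameters, the transfer-learning entry point for adapting a model trained
#' on one dataset to another (spacing does not enter the network, so cases
#' with different voxel spacing are fine).  With `max_epochs = 0` the
#' parameters are returned unchanged.
#'
#' @param checkpoint a path accepted by [load_checkpoint()], an
#'   [rcnn_segmenter()]/[unit2d_segmenter()], or a previous [train()] result.
#' @inheritParams train.rcnn_segmenter
#' @return An `rcnn_fit`, as for [train()].
#' @export
fine_tune <- function(checkpoint, train_cases, val_cases,
                      config = train_config(), weights = loss_weights()) {
  model <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  if (inherits(model, "rcnn_fit")) model <- model$model
  if (!inherits(model, c("rcnn_segmenter", "unit2d_segmenter")))
    stop("config error: checkpoint does not contain a compatible model", call. = FALSE)
  train(model, train_cases, val_cases, config = config, weights = weights)
}

## ---- fitted-model methods ---------------------------------------------------

#' @export
print.rcnn_fit <- function(x, ...) {
  cat(sprintf("<rcnn_fit> %s after %d epoch(s); best epoch %d (%s)\n",
              class(x$model)[1], nrow(x$history), x$best_epoch, x$stop_reason))
  if (nrow(x$history) > 0) {
    b <- x$history[x$history$epoch == x$best_epoch, ]
    cat(sprintf("  best validation loss %.4f, validation DSC %.4f\n",
                b$val_loss, b$val_dsc))
  }
  invisible(x)
}

#' @export
summary.rcnn_fit <- function(object, ...) {
  print(object)
  if (nrow(object$history) > 0) print(object$history)
  invisible(object)
}

#' @export
coef.rcnn_fit <- function(object, ...) object$model$params

#' @export
predict.rcnn_fit <- function(object, volume, threshold = 0.5, ...)
  predict(object$model, volume, threshold = threshold, ...)

#' @importFrom graphics legend lines
#' @export
plot.rcnn_fit <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) { warning("no training history to plot"); return(invisible(x)) }
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = range(c(h$train_loss, h$val_loss)), ...)
  lines(h$epoch, h$val_loss, lty = 2)
  legend("topright", legend = c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}
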