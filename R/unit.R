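#' Configure the per-slice encoder-decoder unit
#'
#' The unit is a 2D U-Net-style encoder-decoder: `depth` resolution levels of
#' double 3x3 convolution + ReLU blocks, 2x2 max pooling between levels,
#' nearest-neighbour upsampling with skip concatenation on the way up, and a
#' final 1x1 convolution producing one logit map.  `attention_unet` adds
#' additive attention gates on the skip connections (1x1 convs on gating and
#' skip features, ReLU, 1x1 conv + sigmoid, multiplicative gating), which
#' strictly increases the parameter count.  In the recurrent segmenter the
#' unit always sees exactly 2 input channels: the CT slice and the transformed
#' feedback map from the previous slice.
#'
#' @param unit_kind `"unet"` or `"attention_unet"`.
#' @param depth number of resolution levels (>= 2); the in-plane size must be
#'   divisible by `2^(depth - 1)`.
#' @param base_channels channels at the first level (>= 4); doubled per level.
#' @param feedback_kernel odd kernel size (>= 1) of the recurrent transform
#'   applied to the previous slice's probability map before concatenation.
#' @return An object of class `unit_config`.
#' @export
unit_config <- function(unit_kind = c("unet", "attention_unet"), depth = 3L,
                        base_channels = 16L, feedback_kernel = 3L) {
  unit_kind <- match.arg(unit_kind)
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  feedback_kernel <- as.integer(feedback_kernel)
  stopifnot(depth >= 2L, base_channels >= 4L)
  if (feedback_kernel < 1L || feedback_kernel %% 2L == 0L)
    stop("unit_config: feedback_kernel must be an odd integer >= 1", call. = FALSE)
  structure(list(unit_kind = unit_kind, depth = depth,
                 base_channels = base_channels,
                 feedback_kernel = feedback_kernel),
            class = "unit_config")
}

## ---- primitive wrappers -----------------------------------------------------

relu <- function(x) { x[x < 0] <- 0; x }

sigmoid <- function(x) 1 / (1 + exp(-x))

conv_fwd <- function(x, params, name) {
  w <- params[[paste0(name, "_w")]]
  .conv2d_fwd(x, as.numeric(w), params[[paste0(name, "_b")]],
              dim(w)[1], dim(w)[2], dim(w)[4])
}

conv_bwd <- function(x, params, name, dy) {
  w <- params[[paste0(name, "_w")]]
  out <- .conv2d_bwd(x, as.numeric(w), dy, dim(w)[1], dim(w)[2])
  out$dw <- array(out$dw, dim(w))
  out$db <- as.numeric(out$db)
  out
}

cat_channels <- function(a, b)
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))

## ---- parameters -------------------------------------------------------------

conv_param <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))        # He initialization for ReLU stacks
  list(w = array(rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout)),
       b = rep(0, cout))
}

add_param <- function(params, name, p) {
  params[[paste0(name, "_w")]] <- p$w
  params[[paste0(name, "_b")]] <- p$b
  params
}

level_channels <- function(cfg, l) cfg$base_channels * 2L^(l - 1L)

## Deterministic initialization of all unit parameters for `n_in` input
## channels.  Caller is responsible for seeding (see with_local_seed).
init_unit_params <- function(cfg, n_in) {
  D <- cfg$depth
  params <- list()
  for (l in seq_len(D)) {
    cin <- if (l == 1L) n_in else level_channels(cfg, l - 1L)
    cl <- level_channels(cfg, l)
    params <- add_param(params, sprintf("enc%d_c1", l), conv_param(3, 3, cin, cl))
    params <- add_param(params, sprintf("enc%d_c2", l), conv_param(3, 3, cl, cl))
  }
  for (l in rev(seq_len(D - 1L))) {
    cl <- level_channels(cfg, l)
    params <- add_param(params, sprintf("dec%d_up", l),
                        conv_param(3, 3, level_channels(cfg, l + 1L), cl))
    if (cfg$unit_kind == "attention_unet") {
      cint <- max(1L, cl %/% 2L)
      params <- add_param(params, sprintf("att%d_g", l), conv_param(1, 1, cl, cint))
      params <- add_param(params, sprintf("att%d_x", l), conv_param(1, 1, cl, cint))
      params <- add_param(params, sprintf("att%d_p", l), conv_param(1, 1, cint, 1))
    }
    params <- add_param(params, sprintf("dec%d_c1", l), conv_param(3, 3, 2L * cl, cl))
    params <- add_param(params, sprintf("dec%d_c2", l), conv_param(3, 3, cl, cl))
  }
  params <- add_param(params, "out", conv_param(1, 1, cfg$base_channels, 1))
  params
}

param_count <- function(params) sum(vapply(params, length, numeric(1)))

## ---- forward ----------------------------------------------------------------

check_unit_shape <- function(cfg, hw) {
  f <- 2L^(cfg$depth - 1L)
  if (hw[1] %% f != 0L || hw[2] %% f != 0L)
    stop(sprintf(paste0("shape error: in-plane size %dx%d is not divisible by %d ",
                        "(unit depth %d); pad rows to %d and cols to %d"),
                 hw[1], hw[2], f, cfg$depth,
                 f * ceiling(hw[1] / f), f * ceiling(hw[2] / f)), call. = FALSE)
  invisible(TRUE)
}

## Forward pass through the unit; x is (H, W, n_in).  Returns the logit map
## and every intermediate needed by unit_backward.
unit_forward <- function(params, cfg, x) {
  D <- cfg$depth
  check_unit_shape(cfg, dim(x)[1:2])
  cc <- list(enc_in = vector("list", D), enc1 = vector("list", D),
             enc2 = vector("list", D), pool = vector("list", D - 1L),
             pool_dim = vector("list", D - 1L),
             up_conv_in = vector("list", D - 1L), up_out = vector("list", D - 1L),
             att = vector("list", D - 1L), cat_in = vector("list", D - 1L),
             dec1 = vector("list", D - 1L), dec2 = vector("list", D - 1L))
  a <- x
  for (l in seq_len(D)) {
    if (l > 1L) {
      mp <- .maxpool2_fwd(a)
      cc$pool[[l - 1L]] <- mp$idx
      cc$pool_dim[[l - 1L]] <- dim(a)
      a <- mp$y
    }
    cc$enc_in[[l]] <- a
    a <- relu(conv_fwd(a, params, sprintf("enc%d_c1", l)))
    cc$enc1[[l]] <- a
    a <- relu(conv_fwd(a, params, sprintf("enc%d_c2", l)))
    cc$enc2[[l]] <- a
  }
  for (l in rev(seq_len(D - 1L))) {
    u <- .upsample2_fwd(a)
    cc$up_conv_in[[l]] <- u
    g <- relu(conv_fwd(u, params, sprintf("dec%d_up", l)))
    cc$up_out[[l]] <- g
    s <- cc$enc2[[l]]
    if (cfg$unit_kind == "attention_unet") {
      at <- att_forward(params, l, g, s)
      cc$att[[l]] <- at
      s <- at$s_gated
    }
    a <- cat_channels(s, g)
    cc$cat_in[[l]] <- a
    a <- relu(conv_fwd(a, params, sprintf("dec%d_c1", l)))
    cc$dec1[[l]] <- a
    a <- relu(conv_fwd(a, params, sprintf("dec%d_c2", l)))
    cc$dec2[[l]] <- a
  }
  cc$final_in <- a
  logits <- conv_fwd(a, params, "out")
  list(logits = logits[, , 1], cache = cc)
}

att_forward <- function(params, l, g, s) {
  zg <- conv_fwd(g, params, sprintf("att%d_g", l))
  zx <- conv_fwd(s, params, sprintf("att%d_x", l))
  q <- relu(zg + zx)
  alpha <- sigmoid(conv_fwd(q, params, sprintf("att%d_p", l)))
  ab <- array(alpha, dim(s))               # broadcast the 1-channel gate
  list(g = g, s = s, q = q, alpha = alpha, s_gated = s * ab)
}

## ---- backward ---------------------------------------------------------------

acc_grad <- function(grads, name, dw, db) {
  wn <- paste0(name, "_w"); bn <- paste0(name, "_b")
  grads[[wn]] <- if (is.null(grads[[wn]])) dw else grads[[wn]] + dw
  grads[[bn]] <- if (is.null(grads[[bn]])) db else grads[[bn]] + db
  grads
}

## Backpropagate dlogits (H x W) through the unit.  Returns the gradient with
## respect to the unit input (H, W, n_in) and a named list of parameter
## gradients (same names/shapes as the parameters touched).
unit_backward <- function(params, cfg, cc, dlogits) {
  D <- cfg$depth
  grads <- list()
  dl <- array(dlogits, c(dim(dlogits), 1L))
  bk <- conv_bwd(cc$final_in, params, "out", dl)
  grads <- acc_grad(grads, "out", bk$dw, bk$db)
  da <- bk$dx
  dskip <- vector("list", D - 1L)
  for (l in seq_len(D - 1L)) {               # reverse of the decoder descent
    dz <- da * (cc$dec2[[l]] > 0)
    bk <- conv_bwd(cc$dec1[[l]], params, sprintf("dec%d_c2", l), dz)
    grads <- acc_grad(grads, sprintf("dec%d_c2", l), bk$dw, bk$db)
    dz <- bk$dx * (cc$dec1[[l]] > 0)
    bk <- conv_bwd(cc$cat_in[[l]], params, sprintf("dec%d_c1", l), dz)
    grads <- acc_grad(grads, sprintf("dec%d_c1", l), bk$dw, bk$db)
    cl <- level_channels(cfg, l)
    ds <- bk$dx[, , seq_len(cl), drop = FALSE]
    dg <- bk$dx[, , cl + seq_len(cl), drop = FALSE]
    if (cfg$unit_kind == "attention_unet") {
      ab <- att_backward(params, cfg, l, cc$att[[l]], ds)
      grads <- ab$apply(grads)
      ds <- ab$ds
      dg <- dg + ab$dg
    }
    dz <- dg * (cc$up_out[[l]] > 0)
    bk <- conv_bwd(cc$up_conv_in[[l]], params, sprintf("dec%d_up", l), dz)
    grads <- acc_grad(grads, sprintf("dec%d_up", l), bk$dw, bk$db)
    da <- .upsample2_bwd(bk$dx)
    dskip[[l]] <- ds
  }
  d_in <- NULL
  for (l in rev(seq_len(D))) {
    d2 <- if (l == D) da else
      dskip[[l]] + .maxpool2_bwd(d_in, cc$pool[[l]],
                                 cc$pool_dim[[l]][1], cc$pool_dim[[l]][2])
    dz <- d2 * (cc$enc2[[l]] > 0)
    bk <- conv_bwd(cc$enc1[[l]], params, sprintf("enc%d_c2", l), dz)
    grads <- acc_grad(grads, sprintf("enc%d_c2", l), bk$dw, bk$db)
    dz <- bk$dx * (cc$enc1[[l]] > 0)
    bk <- conv_bwd(cc$enc_in[[l]], params, sprintf("enc%d_c1", l), dz)
    grads <- acc_grad(grads, sprintf("enc%d_c1", l), bk$dw, bk$db)
    d_in <- bk$dx
  }
  list(dx = d_in, grads = grads)
}

att_backward <- function(params, cfg, l, at, ds_gated) {
  dalpha <- apply(ds_gated * at$s, c(1, 2), sum)
  dalpha <- array(dalpha, c(dim(dalpha), 1L))
  ds <- ds_gated * array(at$alpha, dim(at$s))
  dz_p <- dalpha * at$alpha * (1 - at$alpha)
  bp <- conv_bwd(at$q, params, sprintf("att%d_p", l), dz_p)
  dq <- bp$dx * (at$q > 0)
  bg <- conv_bwd(at$g, params, sprintf("att%d_g", l), dq)
  bx <- conv_bwd(at$s, params, sprintf("att%d_x", l), dq)
  list(ds = ds + bx$dx, dg = bg$dx,
       apply = function(grads) {
         grads <- acc_grad(grads, sprintf("att%d_p", l), bp$dw, bp$db)
         grads <- acc_grad(grads, sprintf("att%d_g", l), bg$dw, bg$db)
         acc_grad(grads, sprintf("att%d_x", l), bx$dw, bx$db)
       })
}
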