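test_that("model construction is deterministic and weight-shared", {
  cfg <- unit_config(depth = 2, base_channels = 4)
  m1 <- rcnn_segmenter(cfg, seed = 11)
  m2 <- rcnn_segmenter(cfg, seed = 11)
  expect_identical(coef(m1), coef(m2))
  m3 <- rcnn_segmenter(cfg, seed = 12)
  expect_false(identical(coef(m1), coef(m3)))

  ## the parameter set does not depend on the unrolled length: the same model
  ## (same parameter objects) processes 5- and 50-slice volumes
  set.seed(1)
  v5 <- volume_grid(array(runif(5 * 16 * 16), c(5, 16, 16)))
  v50 <- volume_grid(array(runif(50 * 16 * 16), c(50, 16, 16)))
  p_before <- coef(m1)
  expect_length(unroll(m1, v5), 5)
  expect_length(unroll(m1, v50), 50)
  expect_identical(coef(m1), p_before)

  ## attention gates add parameters to the matched plain unit
  ma <- rcnn_segmenter(unit_config("attention_unet", depth = 2, base_channels = 4),
                       seed = 11)
  expect_gt(length(unlist(coef(ma))), length(unlist(coef(m1))))
})

test_that("a recurrent step honours the output contract and the zero initial state", {
  cfg <- unit_config(depth = 2, base_channels = 4)
  m <- rcnn_segmenter(cfg, seed = 2)
  set.seed(2)
  sl <- matrix(runif(16 * 16), 16, 16)
  st1 <- rcnn_step(m, sl, NULL)
  expect_identical(dim(st1$prob), dim(sl))
  expect_true(all(st1$prob >= 0 & st1$prob <= 1))
  expect_identical(st1$prob, st1$state)
  ## deterministic at inference
  expect_identical(st1$prob, rcnn_step(m, sl, NULL)$prob)

  ## step with zero state is the unit applied to concat(I, w_r * 0)
  p <- coef(m)
  fb0 <- rcnnseg:::conv_fwd(array(0, c(16, 16, 1)), p, "fb")
  x <- rcnnseg:::cat_channels(array(sl, c(16, 16, 1)), fb0)
  direct <- rcnnseg:::sigmoid(rcnnseg:::unit_forward(p, cfg, x)$logits)
  expect_equal(st1$prob, direct, tolerance = 1e-12)

  expect_error(rcnn_step(m, sl, matrix(0, 8, 8)), "shape error")
})

test_that("the unidirectional recurrence is causal", {
  cfg <- unit_config(depth = 2, base_channels = 4)
  m <- rcnn_segmenter(cfg, seed = 5, window = c(0, 1))
  set.seed(5)
  v <- volume_grid(array(runif(6 * 16 * 16, 0.1, 0.9), c(6, 16, 16)))
  pr <- unroll(m, v)
  v2 <- v
  v2$intensities[4, , ] <- pmin(pmax(v2$intensities[4, , ] + 0.05, 0), 1)
  pr2 <- unroll(m, v2)
  for (t in 1:3) expect_identical(pr[[t]], pr2[[t]])
  for (t in 4:6) expect_false(identical(pr[[t]], pr2[[t]]))
})

test_that("incompatible in-plane sizes raise a shape error naming the padding", {
  m <- rcnn_segmenter(unit_config(depth = 3, base_channels = 4), seed = 1)
  v <- volume_grid(array(0.5, c(2, 10, 10)))
  expect_error(unroll(m, v), "shape error.*pad")
})

test_that("prediction thresholds monotonically and preserves the grid", {
  m <- rcnn_segmenter(unit_config(depth = 2, base_channels = 4), seed = 7,
                      window = c(0, 1))
  set.seed(7)
  v <- volume_grid(array(runif(4 * 16 * 16), c(4, 16, 16)), spacing = c(2, 0.7, 0.7))
  lo <- predict(m, v, threshold = 0.3)
  hi <- predict(m, v, threshold = 0.6)
  expect_identical(dim(lo$labels), dim(v$intensities))
  expect_equal(lo$spacing, v$spacing)
  ## lowering the threshold never shrinks the foreground
  expect_true(all(lo$labels - hi$labels >= 0))
  ## a threshold above the maximum probability empties the mask
  pmax_prob <- max(unlist(unroll(m, v)))
  if (pmax_prob < 0.99) {
    near1 <- predict(m, v, threshold = (1 + pmax_prob) / 2)
    expect_equal(sum(near1$labels), 0)
  }
})

test_that("gradients flow across the recurrent connection (finite differences)", {
  cfg <- unit_config(depth = 2, base_channels = 4)
  m <- rcnn_segmenter(cfg, seed = 3, window = c(0, 1))
  set.seed(3)
  vol <- volume_grid(array(runif(2 * 8 * 8), c(2, 8, 8)))
  msk <- binary_mask(array(rbinom(2 * 8 * 8, 1, 0.3), c(2, 8, 8)))
  g <- rcnn_gradient(m, vol, msk)
  ## the recurrent transform receives gradient only through step t-1's output
  expect_gt(max(abs(g$grads$fb_w)), 0)
  loss_at <- function(mm) rcnn_gradient(mm, vol, msk)$loss
  h <- 1e-6
  for (nm in c("fb_w", "enc1_c1_w", "out_w")) {
    set.seed(10)
    i <- sample(length(m$params[[nm]]), 1)
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
    mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - h
    num <- (loss_at(mp) - loss_at(mn)) / (2 * h)
    expect_equal(g$grads[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip through save/load", {
  m <- rcnn_segmenter(unit_config(depth = 2, base_channels = 4), seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(coef(m), coef(m2))
  expect_identical(m$config, m2$config)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_checkpoint(bad), "config error")
})
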