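test_that("training configuration enforces its invariants", {
  expect_error(train_config(patience = 0), "patience")
  expect_error(train_config(max_epochs = 5, patience = 10), "patience")
  expect_error(train_config(tbptt_window = 0), "tbptt_window >= 1")
  expect_s3_class(train_config(max_epochs = 0), "train_config")
})

test_that("truncated BPTT with a window covering the sequence equals full BPTT", {
  m <- rcnn_segmenter(unit_config(depth = 2, base_channels = 4), seed = 6,
                      window = c(0, 1))
  set.seed(6)
  vol <- volume_grid(array(runif(5 * 16 * 16), c(5, 16, 16)))
  msk <- binary_mask(array(rbinom(5 * 16 * 16, 1, 0.25), c(5, 16, 16)))
  gf <- rcnn_gradient(m, vol, msk, tbptt_window = "full")
  gw <- rcnn_gradient(m, vol, msk, tbptt_window = 8)
  expect_equal(gf$loss, gw$loss, tolerance = 1e-10)
  for (nm in names(gf$grads))
    expect_equal(gf$grads[[nm]], gw$grads[[nm]], tolerance = 1e-6)
  ## a shorter window keeps the loss (plain sum) but truncates the gradient
  gt <- rcnn_gradient(m, vol, msk, tbptt_window = 2)
  expect_equal(gt$loss, gf$loss, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(gt$grads$fb_w, gf$grads$fb_w, tolerance = 1e-10)))
})

test_that("two training runs with the same seed produce identical histories", {
  cases <- lapply(1:2, tiny_case)
  val <- list(tiny_case(99))
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 3, patience = 3, seed = 21)
  m <- rcnn_segmenter(unit_config(depth = 2, base_channels = 4), seed = 8,
                      window = c(0, 1))
  f1 <- train(m, cases, val, cfg)
  f2 <- train(m, cases, val, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
  expect_equal(nrow(f1$history), 3)
})

test_that("early stopping halts after patience epochs and restores the best epoch", {
  cases <- lapply(1:2, tiny_case)
  val <- list(tiny_case(99))
  ## a deliberately divergent learning rate makes the validation loss worsen
  ## after the first epochs, forcing the early-stop branch
  cfg <- train_config(learning_rate = 5, max_epochs = 30, patience = 2, seed = 4)
  m <- rcnn_segmenter(unit_config(depth = 2, base_channels = 4), seed = 8,
                      window = c(0, 1))
  fit <- train(m, cases, val, cfg)
  h <- fit$history
  expect_equal(fit$stop_reason, "early_stopped")
  expect_equal(fit$best_epoch, which.min(h$val_loss))
  expect_equal(nrow(h), fit$best_epoch + cfg$patience)
  ## restored parameters reproduce the best recorded validation loss
  vl <- rcnnseg:::validate_cases(fit$model, val, loss_weights(), cfg$threshold)
  expect_equal(vl$loss, min(h$val_loss), tolerance = 1e-8)
  expect_lte(min(h$val_loss), min(h$val_loss[seq_len(nrow(h))]))
})

test_that("fine-tuning warm-starts from a checkpoint", {
  cases <- lapply(1:2, tiny_case)
  val <- list(tiny_case(99))
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 2, patience = 2, seed = 5)
  m <- rcnn_segmenter(unit_config(depth = 2, base_channels = 4), seed = 9,
                      window = c(0, 1))
  fit <- train(m, cases, val, cfg)

  ## zero additional epochs: parameters unchanged
  f0 <- fine_tune(fit, cases, val, train_config(max_epochs = 0, patience = 1))
  expect_identical(coef(f0), coef(fit))
  expect_equal(nrow(f0$history), 0)

  ## the checkpoint reproduces its recorded best validation loss exactly
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  reloaded <- load_checkpoint(path)
  vl <- rcnnseg:::validate_cases(reloaded, val, loss_weights(), cfg$threshold)
  expect_equal(vl$loss, fit$history$val_loss[fit$best_epoch], tolerance = 1e-6)

  ## fine-tuning runs on cases with different spacing (spacing never enters the net)
  resp <- lapply(cases, function(cs) {
    cs$volume$spacing <- c(3, 0.5, 0.5); cs$mask$spacing <- c(3, 0.5, 0.5); cs
  })
  f2 <- fine_tune(path, resp, resp[1], train_config(learning_rate = 1e-3,
                                                    max_epochs = 1, patience = 1))
  expect_s3_class(f2, "rcnn_fit")
  expect_error(fine_tune(list(not = "a model"), cases, val), "config error")
})

test_that("all-empty targets trigger a degenerate-data warning but training runs", {
  cs <- tiny_case(1)
  cs$mask$labels[] <- 0
  m <- rcnn_segmenter(unit_config(depth = 2, base_channels = 4), seed = 2,
                      window = c(0, 1))
  expect_warning(
    fit <- train(m, list(cs), list(cs),
                 train_config(learning_rate = 1e-3, max_epochs = 1, patience = 1)),
    "degenerate")
  expect_equal(nrow(fit$history), 1)
})

test_that("the comparison harness produces the per-case and summary table layout", {
  ## smallest legal experiment: 4 cases, 1-epoch budget; checks format, not skill
  cases <- generate_dataset(4, small_phantom_spec(), seed = 55)
  tab <- compare_feeding_strategies(
    cases, config = train_config(learning_rate = 1e-3, max_epochs = 1,
                                 patience = 1, seed = 1),
    unit = unit_config(depth = 2, base_channels = 4),
    strategies = c("recurrent", "slice2d", "slice25d"), window = c(0, 1))
  expect_true(all(c("method", "case", "dsc", "asd_mm", "hd95_mm", "hd_mm")
                  %in% names(tab)))
  for (st in c("recurrent", "slice2d", "slice25d")) {
    sub <- tab[tab$method == st, ]
    expect_true(all(c("mean", "sd") %in% sub$case))
    expect_equal(nrow(sub), 1 + 2)       # 1 test case + mean + sd
  }
  expect_error(compare_feeding_strategies(cases[1:3]), "argument error")
})
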