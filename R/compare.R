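#' Compare the recurrent model against classic feeding strategies
#'
#' The central experimental design at phantom scale: the cases are split
#' (seeded) into train/validation/test, each requested arm is trained from
#' scratch with an identical budget (same [train_config()], same loss), and
#' every arm is evaluated on the held-out cases with [evaluate_pair()].
#' Available arms: `"recurrent"` (the slice-sequence model), `"slice2d"` (the
#' matched per-slice baseline) and `"slice25d"` (three-slice context
#' baseline).
#'
#' @param cases list of cases (`volume` + `mask`), at least 4.
#' @param config a [train_config()]; its `seed` also drives the split and the
#'   model initializations.
#' @param unit a [unit_config()] shared by all arms.
#' @param strategies character vector of arms to run.
#' @param weights a [loss_weights()].
#' @param window normalization window for all arms.
#' @return A `data.frame` with one row per (method, case) holding `dsc`,
#'   `asd_mm`, `hd95_mm`, `hd_mm`, plus `mean` and `sd` summary rows per
#'   method.  The trained fits are attached as `attr(, "fits")` and the split
#'   as `attr(, "split")`.
#' @export
compare_feeding_strategies <- function(cases, config = train_config(),
                                       unit = unit_config(depth = 2L, base_channels = 8L),
                                       strategies = c("recurrent", "slice2d"),
                                       weights = loss_weights(), window = NULL) {
  if (length(cases) < 4L)
    stop("argument error: need at least 4 cases to split into train/val/test",
         call. = FALSE)
  stopifnot(all(strategies %in% c("recurrent", "slice2d", "slice25d")))
  check_cases(cases, "comparison")
  n <- length(cases)
  n_test <- max(1L, n %/% 4L)
  ord <- with_local_seed(config$seed + 1000L, sample.int(n))
  test_id <- ord[seq_len(n_test)]
  val_id <- ord[n_test + 1L]
  train_id <- ord[(n_test + 2L):n]
  fits <- list(); rows <- list()
  for (st in strategies) {
    model <- if (st == "recurrent") rcnn_segmenter(unit, seed = config$seed, window = window)
             else unit2d_segmenter(unit, strategy = st, seed = config$seed, window = window)
    fit <- train(model, cases[train_id], cases[val_id], config = config,
                 weights = weights)
    fits[[st]] <- fit
    for (i in test_id) {
      pred <- predict(fit, cases[[i]]$volume, threshold = config$threshold)
      r <- evaluate_pair(pred, cases[[i]]$mask)
      rows[[length(rows) + 1L]] <-
        data.frame(method = st, case = sprintf("case%02d", i), dsc = r$dsc,
                   asd_mm = r$asd_mm, hd95_mm = r$hd95_mm, hd_mm = r$hd_mm)
    }
  }
  tab <- do.call(rbind, rows)
  for (st in strategies) {
    sub <- tab[tab$method == st & !(tab$case %in% c("mean", "sd")), -(1:2)]
    tab <- rbind(tab,
                 data.frame(method = st, case = "mean", t(colMeans(sub, na.rm = TRUE))),
                 data.frame(method = st, case = "sd",
                            t(apply(sub, 2, stats::sd, na.rm = TRUE))))
  }
  attr(tab, "fits") <- fits
  attr(tab, "split") <- list(train = train_id, val = val_id, test = test_id)
  tab
}
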