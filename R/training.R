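#' Training configuration
#'
#' Optimiser and schedule settings used for all five architectures: Adam
#' with `beta1 = 0.9`, `beta2 = 0.999`, `epsilon = 1e-7`, a staircase
#' exponential learning-rate schedule starting at `1e-3` and decaying by
#' 4% every 800 optimiser steps, and a 0.5 decision threshold on the
#' sigmoid output.
#'
#' @param initial_lr initial learning rate.
#' @param decay_rate multiplicative decay factor (0.96 = 4% decay).
#' @param decay_steps steps between decays ("step" = one batch update).
#' @param staircase if `TRUE` the decay is applied in discrete jumps.
#' @param beta1,beta2,epsilon Adam moment and stability parameters.
#' @param epochs training epochs.
#' @param batch_size images per optimiser step.
#' @param threshold sigmoid threshold for binary prediction.
#' @param augment logical: apply random shift/rotation/flip augmentation.
#' @param seed integer seed controlling initialisation, data order and
#'   augmentation.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(initial_lr = 1e-3, decay_rate = 0.96,
                         decay_steps = 800L, staircase = TRUE,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         epochs = 150L, batch_size = 8L, threshold = 0.5,
                         augment = TRUE, seed = 1L) {
  stopifnot(initial_lr > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            threshold > 0, threshold < 1)
  structure(as.list(environment()), class = "train_config")
}

#' Learning-rate schedule
#'
#' Staircase exponential decay: `initial_lr * decay_rate^floor(step /
#' decay_steps)` (continuous decay uses the unfloored exponent).
#'
#' @param step non-negative optimiser step count.
#' @param cfg [train_config()].
#' @return learning rate at `step`.
#' @examples
#' lr_schedule(0)     # 1e-3
#' lr_schedule(800)   # 9.6e-4
#' @export
lr_schedule <- function(step, cfg = train_config()) {
  stopifnot(all(step >= 0))
  expo <- step / cfg$decay_steps
  if (cfg$staircase) expo <- floor(expo)
  cfg$initial_lr * cfg$decay_rate^expo
}

# Reverse-mode gradient through the layer graph.  `dout` is the gradient
# at the output conv's *pre-activation* (the sigmoid is folded into the
# cross-entropy gradient by the caller).  Returns per-conv-node gradients.
backward <- function(model, cache, weights, dout) {
  d <- list()
  d[[model$output_id]] <- dout
  grads <- list()
  for (n in rev(model$nodes)) {
    if (n$op == "input" || is.null(d[[n$id]])) next
    g <- d[[n$id]]
    if (n$op == "conv") {
      # sigmoid output conv: caller already supplies pre-activation grad
      act <- if (n$activation == "sigmoid") 0L else act_code(n$activation)
      need_dx <- n$inputs != "input"
      r <- cpp_conv2d_bwd(cache$out[[n$inputs]], weights[[n$id]]$K,
                          cache$out[[n$id]], g, act, need_dx)
      if (is.null(grads[[n$id]])) {
        grads[[n$id]] <- list(K = r$dK, b = r$db)
      } else {
        grads[[n$id]]$K <- grads[[n$id]]$K + r$dK
        grads[[n$id]]$b <- grads[[n$id]]$b + r$db
      }
      if (need_dx) d[[n$inputs]] <- accum(d[[n$inputs]], r$dx)
    } else if (n$op == "maxpool2") {
      sh <- dim(cache$out[[n$inputs]])
      d[[n$inputs]] <- accum(d[[n$inputs]],
                             cpp_maxpool2_bwd(g, cache$poolidx[[n$id]],
                                              sh[1], sh[2]))
    } else if (n$op == "upsample2") {
      d[[n$inputs]] <- accum(d[[n$inputs]], cpp_upsample2_bwd(g))
    } else if (n$op == "concat") {
      at <- 0L
      for (inp in n$inputs) {
        ch <- dim(cache$out[[inp]])[3]
        d[[inp]] <- accum(d[[inp]], g[, , at + seq_len(ch), drop = FALSE])
        at <- at + ch
      }
    } else if (n$op == "add") {
      for (inp in n$inputs) d[[inp]] <- accum(d[[inp]], g)
    } else if (n$op == "activation") {
      gi <- if (n$activation == "relu") g * (cache$out[[n$id]] > 0) else g
      d[[n$inputs]] <- accum(d[[n$inputs]], gi)
    }
    d[[n$id]] <- NULL  # free
  }
  grads
}

accum <- function(a, b) if (is.null(a)) b else a + b

adam_state <- function(weights) {
  lapply(weights, function(w) list(mK = w$K * 0, vK = w$K * 0,
                                   mb = w$b * 0, vb = w$b * 0))
}

adam_update <- function(weights, grads, state, lr, cfg, t) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- cfg$epsilon
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (id in names(grads)) {
    g <- grads[[id]]; s <- state[[id]]
    s$mK <- b1 * s$mK + (1 - b1) * g$K
    s$vK <- b2 * s$vK + (1 - b2) * g$K^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    weights[[id]]$K <- weights[[id]]$K - lr * (s$mK / c1) / (sqrt(s$vK / c2) + eps)
    weights[[id]]$b <- weights[[id]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[id]] <- s
  }
  list(weights = weights, state = state)
}

# per-image loss and pre-activation gradient of the weighted BCE
wbce_and_grad <- function(p, y, eps = 1e-7) {
  w <- class_weights(y)
  wm <- y * w$wT + (1 - y) * w$wF
  pc <- pmin(pmax(p, eps), 1 - eps)
  loss <- sum(-(y * log(pc) + (1 - y) * log(1 - pc)) * wm)
  list(loss = loss, dz = wm * (p - y))
}

#' Fit a segmentation network
#'
#' Trains a [build_model()] architecture on image/mask pairs with Adam on
#' the class-weighted binary cross-entropy, using the staircase
#' exponential learning-rate schedule.  All randomness (weight
#' initialisation, shuffling, augmentation) flows through `cfg$seed`, so
#' a fit is fully reproducible.
#'
#' @param model `"model_spec"`, or an architecture name passed to
#'   [build_model()] (the input shape is then taken from the data).
#' @param data list of scenes, each a list with `image` and `mask`
#'   (e.g. from [synth_dataset()] or [crop_tiles()] tiles).
#' @param cfg [train_config()].
#' @param validation optional list of scenes evaluated (loss and pooled
#'   recall-weighted F1) at the end of every epoch.
#' @param verbose print per-epoch progress.
#' @return object of class `"tinyseg_fit"`: list with `model`, `weights`,
#'   `history` (data frame: epoch, loss, lr, and validation columns when
#'   supplied), and `config`.  Supports `predict`, `print`, `summary`,
#'   `coef`, `plot` and `residuals` methods.
#' @export
tinyseg_fit <- function(model, data, cfg = train_config(),
                        validation = NULL, verbose = FALSE) {
  if (is.character(model)) {
    sh <- as.integer(dim(as_hwc_guess(data[[1]]$image)))
    model <- build_model(model, input_shape = sh)
  }
  if (length(data) == 0) stop("no training data")
  set.seed(cfg$seed)
  weights <- init_weights(model)
  st <- adam_state(weights)
  step <- 0L
  hist_rows <- list()
  aug_cfg <- if (isTRUE(cfg$augment)) {
    fill <- mean(vapply(data, function(s) mean(s$image), 0))
    augment_config(fill = fill)
  } else NULL
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(length(data))
    ep_loss <- 0; npix <- 0
    for (b0 in seq(1, length(data), by = cfg$batch_size)) {
      batch <- ord[b0:min(b0 + cfg$batch_size - 1, length(data))]
      nb <- length(batch)
      lr <- lr_schedule(step, cfg)
      agg <- NULL
      for (ix in batch) {
        sc <- data[[ix]]
        img <- sc$image; msk <- sc$mask
        if (!is.null(aug_cfg)) {
          a <- augment(img, msk, aug_cfg)
          # degenerate all-background masks can't drive the weighted loss
          if (sum(a$mask) > 0) { img <- a$image; msk <- a$mask }
        }
        if (sum(msk) == 0 || sum(msk) == length(msk)) next
        cache <- forward_cache(model, img, weights)
        out <- cache$out[[model$output_id]]
        p <- matrix(out, dim(out)[1], dim(out)[2])
        lg <- wbce_and_grad(p, msk)
        ep_loss <- ep_loss + lg$loss; npix <- npix + 1
        dz <- array(lg$dz / nb, dim = c(dim(p), 1L))
        g <- backward(model, cache, weights, dz)
        agg <- if (is.null(agg)) g else {
          for (id in names(g)) {
            agg[[id]]$K <- agg[[id]]$K + g[[id]]$K
            agg[[id]]$b <- agg[[id]]$b + g[[id]]$b
          }
          agg
        }
      }
      if (is.null(agg)) next
      step <- step + 1L
      up <- adam_update(weights, agg, st, lr, cfg, step)
      weights <- up$weights; st <- up$state
      if (any(!is.finite(unlist(lapply(weights, `[[`, "b")))))
        stop("training diverged (non-finite weights) at step ", step)
    }
    row <- data.frame(epoch = epoch,
                      loss = if (npix > 0) ep_loss / npix else NA_real_,
                      lr = lr_schedule(step, cfg))
    if (!is.null(validation)) {
      vm <- evaluate_scenes(model, weights, validation, cfg$threshold)
      row$val_loss <- vm$loss
      row$val_rw_f1 <- vm$metrics$rw_f1
    }
    hist_rows[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.1f%s", epoch, row$loss,
                      if (!is.null(validation))
                        sprintf("  val rw.F1 %.3f", row$val_rw_f1) else ""))
  }
  structure(list(model = model, weights = weights,
                 history = do.call(rbind, hist_rows), config = cfg),
            class = "tinyseg_fit")
}

as_hwc_guess <- function(x) if (is.matrix(x)) array(x, c(dim(x), 1L)) else x

# pooled loss + metric suite over a scene list
evaluate_scenes <- function(model, weights, scenes, threshold = 0.5) {
  counts <- list(TP = 0, FP = 0, FN = 0, TN = 0)
  loss <- 0
  for (sc in scenes) {
    p <- forward(model, sc$image, weights)
    if (sum(sc$mask) > 0 && sum(sc$mask) < length(sc$mask))
      loss <- loss + wbce_and_grad(p, sc$mask)$loss
    cc <- confusion_counts(sc$mask, p > threshold)
    for (f in names(counts)) counts[[f]] <- counts[[f]] + cc[[f]]
  }
  cl <- structure(counts, class = "confusion_counts")
  list(loss = loss / length(scenes), counts = cl,
       metrics = metric_suite(cl))
}

#' Predict a binary mask (or probability map)
#'
#' @param object `"tinyseg_fit"`.
#' @param image input image matching the model input shape.
#' @param type `"mask"` (threshold at `config$threshold`, strict `>`) or
#'   `"prob"` (raw sigmoid probabilities).
#' @param threshold override of the configured threshold.
#' @param ... unused.
#' @return binary (0/1) or probability matrix.
#' @export
predict.tinyseg_fit <- function(object, image, type = c("mask", "prob"),
                                threshold = NULL, ...) {
  type <- match.arg(type)
  p <- forward(object$model, image, object$weights)
  if (type == "prob") return(p)
  th <- if (is.null(threshold)) object$config$threshold else threshold
  (p > th) * 1
}

#' @export
print.tinyseg_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<tinyseg_fit> %s, %d epochs, final loss %.2f\n",
              x$model$name, nrow(h), h$loss[nrow(h)]))
  invisible(x)
}

#' @export
summary.tinyseg_fit <- function(object, ...) {
  cat(sprintf("Architecture : %s\n", object$model$name))
  cat(sprintf("Parameters   : %s\n",
              format(count_parameters(object$model), big.mark = ",")))
  cat(sprintf("Epochs       : %d\n", nrow(object$history)))
  cat(sprintf("Final loss   : %.2f\n",
              object$history$loss[nrow(object$history)]))
  if ("val_rw_f1" %in% names(object$history))
    cat(sprintf("Final val recall-weighted F1: %.4f\n",
                object$history$val_rw_f1[nrow(object$history)]))
  invisible(object)
}

#' @export
coef.tinyseg_fit <- function(object, ...) object$weights

#' @export
plot.tinyseg_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "weighted BCE (per image)",
                 main = paste("training loss:", x$model$name), ...)
  if ("val_loss" %in% names(h))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  invisible(x)
}

#' Per-pixel residuals of a fitted segmentation network
#'
#' @param object `"tinyseg_fit"`.
#' @param data list of scenes; residual is `mask - probability`.
#' @param ... unused.
#' @return list of residual matrices.
#' @export
residuals.tinyseg_fit <- function(object, data, ...) {
  lapply(data, function(sc)
    sc$mask - forward(object$model, sc$image, object$weights))
}

#' Five-fold cross-validation of one or more architectures
#'
#' Trains each architecture on every fold's training subset and reports
#' the pooled test-set metric suite per fold, plus per-architecture
#' averages, mirroring the layout of the published per-fold tables.
#'
#' @param archs character vector of architecture names.
#' @param data list of scenes.
#' @param cfg [train_config()].
#' @param k folds (default 5).
#' @param input_shape passed to [build_model()]; default inferred from
#'   the first scene.
#' @param predictor optional function `(model_name, train_scenes,
#'   test_scene) -> probability matrix` replacing network training (used
#'   for oracle checks).
#' @return data frame of class `"crossval_result"`: one row per
#'   architecture x fold plus average rows, columns `precision`,
#'   `recall`, `f1`, `miou`, `rw_f1`, `rw_miou`.
#' @export
cross_validate <- function(archs, data, cfg = train_config(), k = 5L,
                           input_shape = NULL, predictor = NULL) {
  if (length(data) < k) stop("need at least k scenes")
  if (is.null(input_shape)) {
    d <- dim(as_hwc_guess(data[[1]]$image))
    input_shape <- as.integer(d)
  }
  folds <- kfold_split(length(data), k = k, seed = cfg$seed)
  rows <- list()
  for (arch in archs) {
    per_fold <- list()
    for (f in seq_len(k)) {
      tr <- data[folds[[f]]$train]
      te <- data[folds[[f]]$test]
      counts <- list(TP = 0, FP = 0, FN = 0, TN = 0)
      if (is.null(predictor)) {
        model <- build_model(arch, input_shape = input_shape)
        fit <- tinyseg_fit(model, tr, cfg)
        ev <- evaluate_scenes(fit$model, fit$weights, te, cfg$threshold)
        m <- ev$metrics
      } else {
        for (sc in te) {
          p <- predictor(arch, tr, sc)
          cc <- confusion_counts(sc$mask, p > cfg$threshold)
          for (fld in names(counts)) counts[[fld]] <- counts[[fld]] + cc[[fld]]
        }
        m <- metric_suite(structure(counts, class = "confusion_counts"))
      }
      per_fold[[f]] <- data.frame(arch = arch, fold = f,
                                  precision = m$precision, recall = m$recall,
                                  f1 = m$f1, miou = m$miou,
                                  rw_f1 = m$rw_f1, rw_miou = m$rw_miou)
    }
    pf <- do.call(rbind, per_fold)
    avg <- pf[1, ]; avg$fold <- NA
    for (cn in c("precision", "recall", "f1", "miou", "rw_f1", "rw_miou"))
      avg[[cn]] <- mean(pf[[cn]])
    rows[[arch]] <- rbind(pf, avg)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("crossval_result", "data.frame")
  out
}

#' @export
print.crossval_result <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  for (cn in c("precision", "recall", "f1", "miou", "rw_f1", "rw_miou"))
    y[[cn]] <- round(y[[cn]], digits)
  y$fold <- ifelse(is.na(y$fold), "avg", as.character(y$fold))
  print(y)
  invisible(x)
}
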