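#' Class weights for imbalanced binary masks
#'
#' Computes the per-class weights of the weighted binary cross-entropy used
#' to train the segmentation networks.  With `P` pixels of which `sum(Y)`
#' are foreground, the foreground (true-class) weight is `P / sum(Y)` and
#' the background (false-class) weight is `P / (P - sum(Y))`, so that each
#' class contributes equally to the loss regardless of its pixel share.
#' For scenes where foreground covers less than 1% of pixels the
#' foreground weight exceeds 100 while the background weight stays near 1.
#'
#' @param Y binary mask (vector, matrix or array of 0/1 values).
#' @param P total pixel count; defaults to `length(Y)`.
#' @return object of class `"loss_weights"`: list with elements `wT`
#'   (foreground weight) and `wF` (background weight).
#' @examples
#' m <- matrix(0, 8, 8); m[1, 1] <- 1
#' class_weights(m)
#' @export
class_weights <- function(Y, P = length(Y)) {
  sY <- sum(Y)
  if (sY <= 0 || sY >= P)
    stop("degenerate mask: class weights need 0 < sum(Y) < P")
  structure(list(wT = P / sY, wF = P / (P - sY)), class = "loss_weights")
}

#' @export
print.loss_weights <- function(x, ...) {
  cat(sprintf("class weights: wT (foreground) = %.4f, wF (background) = %.4f\n",
              x$wT, x$wF))
  invisible(x)
}

#' Weighted binary cross-entropy
#'
#' Pixel-wise binary cross-entropy weighted per class: each pixel's
#' cross-entropy term is multiplied by `wT` where the ground truth is
#' foreground and by `wF` where it is background, then summed over pixels
#' and averaged over the batch.
#'
#' @param Y ground-truth batch: a list of binary masks, or a single mask.
#' @param Yhat prediction batch matching `Y`: values in (0, 1).
#' @param weights `"loss_weights"` object; by default computed per image
#'   from its own mask.
#' @param eps clamp applied to predictions inside the logarithm.
#' @return non-negative scalar loss.
#' @export
weighted_bce <- function(Y, Yhat, weights = NULL, eps = 1e-7) {
  if (!is.list(Y)) { Y <- list(Y); Yhat <- list(Yhat) }
  if (length(Y) != length(Yhat)) stop("batch sizes of Y and Yhat differ")
  total <- 0
  for (i in seq_along(Y)) {
    y <- as.numeric(Y[[i]]); p <- as.numeric(Yhat[[i]])
    if (length(y) != length(p)) stop("shape mismatch between mask and prediction")
    w <- if (is.null(weights)) class_weights(y) else weights
    p <- pmin(pmax(p, eps), 1 - eps)
    ce <- -(y * log(p) + (1 - y) * log(1 - p))
    wm <- y * w$wT + (1 - y) * w$wF
    total <- total + sum(ce * wm)
  }
  total / length(Y)
}

#' Pixel-level confusion counts
#'
#' @param Y binary ground-truth mask.
#' @param Yhat_bin binary predicted mask of identical shape.
#' @return object of class `"confusion_counts"`: list with integer fields
#'   `TP`, `FP`, `FN`, `TN` summing to the pixel count.
#' @export
confusion_counts <- function(Y, Yhat_bin) {
  if (length(Y) != length(Yhat_bin)) stop("shape mismatch")
  y <- as.logical(Y); p <- as.logical(Yhat_bin)
  structure(list(TP = sum(y & p), FP = sum(!y & p),
                 FN = sum(y & !p), TN = sum(!y & !p)),
            class = "confusion_counts")
}

#' Combine confusion counts
#'
#' Adds counts element-wise, e.g. to pool per-image counts over a test set
#' (micro-averaging).
#' @param ... `"confusion_counts"` objects.
#' @return pooled `"confusion_counts"`.
#' @export
pool_counts <- function(...) {
  cs <- list(...)
  if (length(cs) == 1 && is.list(cs[[1]]) && !inherits(cs[[1]], "confusion_counts"))
    cs <- cs[[1]]
  out <- list(TP = 0, FP = 0, FN = 0, TN = 0)
  for (cc in cs) for (f in names(out)) out[[f]] <- out[[f]] + cc[[f]]
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("pixel confusion: TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Segmentation metric suite
#'
#' Computes recall, precision, F1, mIoU and their recall-weighted variants
#' from pixel confusion counts.  The recall-weighted metrics multiply the
#' base metric by recall, so a detector that misses foreground objects is
#' penalised twice: a model with recall 1 and precision 0.25 scores a
#' recall-weighted F1 of 0.40, while recall 0.4 with precision 0.4 scores
#' only 0.16 despite the identical plain F1.
#'
#' Conventions for degenerate counts: precision is 0 when nothing is
#' predicted positive (TP + FP = 0), and F1 is 0 when precision + recall
#' is 0.  This reproduces the all-zero rows reported for folds whose
#' training failed to converge.
#'
#' @param counts `"confusion_counts"` object (requires TP + FN > 0).
#' @return object of class `"seg_metrics"`: list with fields `recall`,
#'   `precision`, `f1`, `miou`, `rw_f1`, `rw_miou`, all in `[0, 1]`.
#' @examples
#' metric_suite(confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0)))
#' @export
metric_suite <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  if (TP + FN == 0)
    stop("no foreground pixels in ground truth: recall undefined")
  recall <- TP / (TP + FN)
  precision <- if (TP + FP == 0) 0 else TP / (TP + FP)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  miou <- TP / (TP + FP + FN)
  structure(list(recall = recall, precision = precision, f1 = f1,
                 miou = miou, rw_f1 = f1 * recall, rw_miou = miou * recall),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, digits = 4, ...) {
  v <- unlist(x)
  cat("segmentation metrics (pooled pixel counts):\n")
  print(round(v, digits))
  invisible(x)
}

#' Metrics straight from a recall/precision pair
#'
#' Convenience wrapper when only recall and precision are known (e.g. to
#' reproduce worked examples): derives F1, and the recall-weighted F1.
#' mIoU cannot be derived from recall and precision alone in general and
#' is returned as `NA` unless `recall == 1`, in which case
#' `mIoU = TP / (TP + FP) = precision`... see details.
#'
#' @details With recall 1 (FN = 0), `mIoU = TP / (TP + FP)` equals
#'   precision, so the recall-weighted mIoU equals precision as well.
#' @param recall,precision values in `[0, 1]`.
#' @return list with `f1`, `rw_f1`, and (when defined) `miou`, `rw_miou`.
#' @export
metrics_from_pr <- function(recall, precision) {
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  out <- list(f1 = f1, rw_f1 = f1 * recall)
  if (recall == 1) {
    out$miou <- precision
    out$rw_miou <- precision
  } else {
    out$miou <- NA_real_
    out$rw_miou <- NA_real_
  }
  out
}
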