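#' Per-layer kernel weight histograms
#'
#' Computes, for every convolutional node, the histogram of its kernel
#' weights (biases excluded) over `bins` uniform bins spanning
#' `[-max(|w|), +max(|w|)]` for that layer.  Each histogram is tagged
#' with the node's stage index and connection kind: `"feature"` for
#' feature-extraction convolutions (plain stage convs, MultiRes-block
#' branches, the stem) and `"skip"` for residual-path and shortcut
#' convolutions.  This reproduces, as data, the stacked weight-histogram
#' panels used to judge which encoder stages still learn features.
#'
#' @param fit `"tinyseg_fit"` object, or a weight list together with
#'   `model`.
#' @param model `"model_spec"` (required when `fit` is a weight list).
#' @param bins number of uniform bins (default 101).
#' @return list of class `"weight_histograms"`; each element has
#'   `layer`, `stage`, `kind`, `edges`, `counts`, and the raw `weights`
#'   vector.
#' @export
layer_histograms <- function(fit, model = NULL, bins = 101L) {
  if (inherits(fit, "tinyseg_fit")) {
    weights <- fit$weights; model <- fit$model
  } else {
    weights <- fit
    if (is.null(model)) stop("supply the model_spec alongside a weight list")
  }
  out <- list()
  for (n in conv_nodes(model)) {
    w <- weights[[n$id]]
    if (is.null(w)) stop("missing weights for conv node ", n$id)
    v <- as.numeric(w$K)
    lim <- max(abs(v))
    if (lim == 0) lim <- .Machine$double.eps
    edges <- seq(-lim, lim, length.out = bins + 1L)
    counts <- as.integer(table(cut(v, breaks = edges, include.lowest = TRUE)))
    out[[n$id]] <- list(layer = n$id, stage = n$stage,
                        kind = if (identical(n$kind, "skip")) "skip" else "feature",
                        edges = edges, counts = counts, weights = v)
  }
  class(out) <- "weight_histograms"
  out
}

#' @export
print.weight_histograms <- function(x, ...) {
  cat(sprintf("<weight_histograms> %d conv layers\n", length(x)))
  invisible(x)
}

#' Zero-concentration of a layer's kernel weights
#'
#' Fraction of kernel weights within `epsilon` of zero, computed from the
#' exact weights (not from binned counts).  A layer whose weights have
#' collapsed into this band contributes next to nothing to the features
#' it passes on; the statistic operationalises the visual judgment that
#' a histogram is "centred close to zero".
#'
#' @param h one element of [layer_histograms()], or a numeric vector of
#'   weights.
#' @param epsilon band half-width (default 0.01).
#' @return fraction in `[0, 1]`.
#' @examples
#' zero_concentration(c(-0.3, -0.01, 0, 0.02, 0.5), epsilon = 0.05)  # 3/5
#' @export
zero_concentration <- function(h, epsilon = 0.01) {
  stopifnot(epsilon > 0)
  v <- if (is.list(h)) h$weights else h
  mean(abs(v) <= epsilon)
}

#' Stage-utilization report
#'
#' Summarises layer utilization per encoder stage: a stage is declared
#' underutilized when the mean zero-concentration of its
#' feature-extraction convolutions exceeds `threshold`.  The suggested
#' reduced architecture is the shallowest family member whose retained
#' encoder stages are all utilized, mirroring how the Half and Quarter
#' variants were derived from the full networks.
#'
#' @param fit `"tinyseg_fit"`, or weight list plus `model`.
#' @param epsilon zero-band half-width (default 0.01).
#' @param threshold zero-concentration above which a stage counts as
#'   underutilized (default 0.9).
#' @param model `"model_spec"` when `fit` is a weight list.
#' @return object of class `"utilization_report"`: data frame with one
#'   row per encoder stage (`stage`, `zero_concentration`, `iqr`,
#'   `verdict`) and attributes `suggestion`, `epsilon`, `threshold`.
#' @export
utilization_report <- function(fit, epsilon = 0.01, threshold = 0.9,
                               model = NULL) {
  hs <- layer_histograms(fit, model)
  model <- if (inherits(fit, "tinyseg_fit")) fit$model else model
  depth <- arch_depth(model$name)
  enc_stages <- 0:depth
  rows <- lapply(enc_stages, function(s) {
    layers <- Filter(function(h) !is.na(h$stage) && h$stage == s &&
                       h$kind == "feature", hs)
    zc <- vapply(layers, zero_concentration, 0, epsilon = epsilon)
    allw <- unlist(lapply(layers, `[[`, "weights"))
    data.frame(stage = s, n_layers = length(layers),
               zero_concentration = mean(zc),
               iqr = stats::IQR(allw),
               verdict = if (mean(zc) > threshold) "underutilized" else "utilized",
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utilized <- df$stage[df$verdict == "utilized"]
  needed_depth <- if (length(utilized) == 0) 0L else max(utilized)
  fam <- if (model$name %in% c("unet", "half_unet")) "unet" else "multires"
  ladder <- if (fam == "unet")
    c(half_unet = 2L, unet = 4L)
  else
    c(quarter_multiresunet = 1L, half_multiresunet = 2L, multiresunet = 4L)
  ok <- ladder[ladder >= max(needed_depth, 1L)]
  suggestion <- if (length(ok) == 0) names(ladder)[length(ladder)] else names(ok)[1]
  structure(df, suggestion = suggestion, epsilon = epsilon,
            threshold = threshold, model = model$name,
            class = c("utilization_report", "data.frame"))
}

#' @export
print.utilization_report <- function(x, ...) {
  cat(sprintf("layer utilization of %s (epsilon = %g, threshold = %g):\n",
              attr(x, "model"), attr(x, "epsilon"), attr(x, "threshold")))
  print(as.data.frame(x))
  cat(sprintf("suggested architecture: %s\n", attr(x, "suggestion")))
  invisible(x)
}
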