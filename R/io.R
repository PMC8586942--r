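#' Save / load model weights
#'
#' Weight archives hold one entry per convolutional node, named by the
#' stable node id, each with the kernel array and bias vector, plus the
#' architecture name and input shape needed to rebuild the graph.
#'
#' @param fit `"tinyseg_fit"` or a weight list.
#' @param path file path (`.rds`).
#' @param model `"model_spec"` when `fit` is a bare weight list.
#' @return `path`, invisibly.
#' @export
save_weights <- function(fit, path, model = NULL) {
  if (inherits(fit, "tinyseg_fit")) {
    weights <- fit$weights; model <- fit$model
  } else weights <- fit
  obj <- list(arch = model$name, input_shape = model$input_shape,
              widths = model$widths, weights = weights)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_weights
#' @return for `load_weights`: list with `model` (rebuilt
#'   `"model_spec"`) and `weights`.
#' @export
load_weights <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$arch, input_shape = obj$input_shape,
                       widths = obj$widths)
  for (n in conv_nodes(model)) {
    w <- obj$weights[[n$id]]
    if (is.null(w) || !all(dim(w$K) == c(n$k, n$k, n$in_ch, n$out_ch)))
      stop("weight archive inconsistent with architecture at node ", n$id)
  }
  list(model = model, weights = obj$weights)
}

#' Total scalar count of a weight list
#'
#' @param weights weight list (per-node `K` and `b`).
#' @return number of stored scalars; equals [count_parameters()] of the
#'   matching model.
#' @export
weight_scalar_count <- function(weights) {
  sum(vapply(weights, function(w) length(w$K) + length(w$b), 0))
}

#' Read / write binary masks as 8-bit PNG
#'
#' Masks are stored with background 0 and foreground 255.
#'
#' @param mask binary matrix.
#' @param path PNG file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @return for `read_mask_png`: binary 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  (x > 0.5) * 1
}

#' Write an image matrix (values in `[0,1]`) as PNG
#' @param image numeric matrix or H x W x 3 array.
#' @param path PNG file path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
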