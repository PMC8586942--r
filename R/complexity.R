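#' Count trainable parameters of a model
#'
#' Sums `k^2 * in * out + out` (kernel weights plus biases) over every
#' convolutional node.  Pooling, upsampling, concatenation and addition
#' nodes carry no parameters.
#'
#' @param model `"model_spec"`.
#' @return integer parameter count.
#' @examples
#' count_parameters(build_model("quarter_multiresunet", c(64, 64, 3)))
#' @export
count_parameters <- function(model) {
  sum(vapply(conv_nodes(model),
             function(n) n$k^2 * n$in_ch * n$out_ch + n$out_ch, 0))
}

#' Count forward-pass floating-point operations
#'
#' FLOPs are the floating additions and multiplications needed for one
#' prediction.  A convolution producing an `h x w x out` tensor performs,
#' per output element, `k^2 * in` multiplications, `k^2 * in - 1`
#' additions and one bias addition, i.e. `2 * k^2 * in` operations
#' (multiply-accumulate counted as two).  Element-wise additions
#' contribute one operation per element; pooling, upsampling,
#' concatenation and activations contribute none.
#'
#' @param model `"model_spec"`.
#' @return numeric operation count (can exceed `.Machine$integer.max`).
#' @export
count_flops <- function(model) {
  total <- 0
  for (n in model$nodes) {
    sh <- model$shapes[[n$id]]
    if (n$op == "conv")
      total <- total + 2 * sh[1] * sh[2] * sh[3] * n$k^2 * n$in_ch
    else if (n$op == "add")
      total <- total + (length(n$inputs) - 1) * sh[1] * sh[2] * sh[3]
  }
  total
}

#' Receptive field of the output
#'
#' Propagates the standard receptive-field recursion `r <- r + (k - 1) * j`,
#' `j <- j * s` through the graph: convolutions widen by `(k - 1) * j`,
#' 2x2 pooling widens by `j` and doubles the jump, and 2x nearest
#' upsampling halves the jump.  At concatenation and addition nodes the
#' maximum over operands is taken.  The reported value is the widest
#' input extent that can influence one output pixel along any path.
#'
#' @param model `"model_spec"`.
#' @return receptive-field side length in input pixels.
#' @export
receptive_field <- function(model) {
  rf <- list(input = c(r = 1, j = 1))
  for (n in model$nodes) {
    if (n$op == "input") next
    ins <- do.call(rbind, lapply(n$inputs, function(i) rf[[i]]))
    r <- max(ins[, "r"]); j <- max(ins[, "j"])
    rf[[n$id]] <- switch(n$op,
      conv = c(r = r + (n$k - 1) * j, j = j),
      maxpool2 = c(r = r + j, j = j * 2),
      upsample2 = c(r = r, j = j / 2),
      c(r = r, j = j))
  }
  unname(rf[[model$output_id]]["r"])
}

#' Per-node complexity report
#'
#' @param model `"model_spec"`.
#' @return object of class `"complexity_report"`: data frame with one row
#'   per node (id, op, output shape, params, flops) plus attributes
#'   `totals` and `receptive_field`.
#' @export
complexity_report <- function(model) {
  rows <- lapply(model$nodes, function(n) {
    sh <- model$shapes[[n$id]]
    p <- if (n$op == "conv") n$k^2 * n$in_ch * n$out_ch + n$out_ch else 0
    f <- if (n$op == "conv") 2 * sh[1] * sh[2] * sh[3] * n$k^2 * n$in_ch
         else if (n$op == "add") (length(n$inputs) - 1) * sh[1] * sh[2] * sh[3]
         else 0
    data.frame(id = n$id, op = n$op, h = sh[1], w = sh[2], channels = sh[3],
               params = p, flops = f, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  structure(df,
            totals = c(params = sum(df$params), flops = sum(df$flops)),
            receptive_field = receptive_field(model),
            model = model$name,
            class = c("complexity_report", "data.frame"))
}

#' @export
print.complexity_report <- function(x, ...) {
  t <- attr(x, "totals")
  cat(sprintf("complexity of %s:\n", attr(x, "model")))
  cat(sprintf("  parameters     : %s (%.4f M)\n",
              format(t["params"], big.mark = ","), t["params"] / 1e6))
  cat(sprintf("  forward FLOPs  : %.1f B\n", t["flops"] / 1e9))
  cat(sprintf("  receptive field: %d px\n", as.integer(attr(x, "receptive_field"))))
  cat(sprintf("  (%d nodes; print the underlying data frame for the breakdown)\n",
              nrow(x)))
  invisible(x)
}
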