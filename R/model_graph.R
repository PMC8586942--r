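#' @useDynLib tinysegnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- layer-graph construction -------------------------------------------
#
# A model is a directed acyclic graph of layer nodes evaluated in list
# order.  Node ops: input, conv (k x k, stride 1, "same" zero padding,
# activation linear/relu/sigmoid), maxpool2, upsample2, concat, add,
# activation.  Spatial sizes and channel counts are tracked at build time
# so shape errors surface before any arithmetic happens.

new_graph <- function(input_shape) {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$shapes <- list()
  add_node(g, list(id = "input", op = "input", inputs = character(0)),
           shape = input_shape)
  g
}

add_node <- function(g, node, shape) {
  if (node$id %in% names(g$nodes)) stop("duplicate node id: ", node$id)
  g$nodes[[node$id]] <- node
  g$shapes[[node$id]] <- shape
  node$id
}

g_conv <- function(g, id, input, k, out_ch, activation = "linear",
                   stage = NA_integer_, kind = "feature") {
  sh <- g$shapes[[input]]
  add_node(g, list(id = id, op = "conv", inputs = input, k = as.integer(k),
                   stride = 1L, in_ch = sh[3], out_ch = as.integer(out_ch),
                   activation = activation, stage = stage, kind = kind),
           shape = c(sh[1], sh[2], out_ch))
}

g_pool <- function(g, id, input) {
  sh <- g$shapes[[input]]
  if (sh[1] %% 2 != 0 || sh[2] %% 2 != 0)
    stop("maxpool2 needs even spatial size, got ", sh[1], "x", sh[2])
  add_node(g, list(id = id, op = "maxpool2", inputs = input),
           shape = c(sh[1] / 2, sh[2] / 2, sh[3]))
}

g_upsample <- function(g, id, input) {
  sh <- g$shapes[[input]]
  add_node(g, list(id = id, op = "upsample2", inputs = input),
           shape = c(sh[1] * 2, sh[2] * 2, sh[3]))
}

g_concat <- function(g, id, inputs) {
  shs <- lapply(inputs, function(i) g$shapes[[i]])
  sp <- shs[[1]][1:2]
  for (s in shs) if (!all(s[1:2] == sp))
    stop("concat operands differ in spatial size")
  add_node(g, list(id = id, op = "concat", inputs = inputs),
           shape = c(sp, sum(vapply(shs, `[`, 0, 3))))
}

g_add <- function(g, id, inputs) {
  shs <- lapply(inputs, function(i) g$shapes[[i]])
  for (s in shs) if (!all(s == shs[[1]]))
    stop("add operands must have identical shapes")
  add_node(g, list(id = id, op = "add", inputs = inputs), shape = shs[[1]])
}

g_act <- function(g, id, input, activation) {
  add_node(g, list(id = id, op = "activation", inputs = input,
                   activation = activation), shape = g$shapes[[input]])
}

# ---- building blocks -----------------------------------------------------

# Plain U-net stage: two 3x3 convolutions, ReLU applied after the second
# (the stage equations place one activation at the stage output).
unet_stage <- function(g, prefix, input, width, stage) {
  a <- g_conv(g, paste0(prefix, "_conv1"), input, 3, width, "linear", stage)
  g_conv(g, paste0(prefix, "_conv2"), a, 3, width, "relu", stage)
}

#' MultiRes block subgraph
#'
#' Three chained 3x3 ReLU convolutions with output channels in the fixed
#' 1/6, 2/6, 3/6 proportions of the block width, concatenated and summed
#' element-wise with the block input (the residual shortcut).  When the
#' input channel count differs from the block width the shortcut is a
#' linear 1x1 projection so the addition is shape-consistent; when they
#' match, the input is added directly.
#'
#' @param g internal graph environment.
#' @param prefix node-id prefix.
#' @param input id of the input node.
#' @param width block output width; must be divisible by 6.
#' @param stage stage index recorded on the conv nodes.
#' @return id of the block output node (post-add, pre-activation).
#' @keywords internal
mrb_block <- function(g, prefix, input, width, stage) {
  if (width %% 6 != 0)
    stop("MultiRes block width must be divisible by 6, got ", width)
  b <- mrb_branch_channels(width)
  in_ch <- g$shapes[[input]][3]
  m1 <- g_conv(g, paste0(prefix, "_m1"), input, 3, b[1], "relu", stage, "feature")
  m2 <- g_conv(g, paste0(prefix, "_m2"), m1, 3, b[2], "relu", stage, "feature")
  m3 <- g_conv(g, paste0(prefix, "_m3"), m2, 3, b[3], "relu", stage, "feature")
  cc <- g_concat(g, paste0(prefix, "_concat"), c(m1, m2, m3))
  shortcut <- if (in_ch == width) input else
    g_conv(g, paste0(prefix, "_shortcut"), input, 1, width, "linear", stage, "skip")
  g_add(g, paste0(prefix, "_add"), c(cc, shortcut))
}

#' Standalone MultiRes block / residual path subgraphs
#'
#' Builds a single MultiRes block (or residual path) as a free-standing
#' model graph, mainly for inspection and testing: the returned object
#' works with [count_parameters()], [count_flops()], [forward()] and
#' [init_weights()] like any built model.
#'
#' @param width MultiRes block width (divisible by 6).
#' @param in_channels input channel count.
#' @param input_size spatial side of the toy input.
#' @return `"model_spec"` whose output node is the block output.
#' @examples
#' count_parameters(respath_subgraph(1))  # 4 * ((1*1+1) + (9*1+1)) = 48
#' @export
mrb_subgraph <- function(width, in_channels = width, input_size = 16L) {
  g <- new_graph(c(input_size, input_size, in_channels))
  out <- mrb_block(g, "mrb", "input", width, 0L)
  structure(list(name = "mrb_subgraph", nodes = g$nodes, shapes = g$shapes,
                 input_shape = c(input_size, input_size, in_channels),
                 output_shape = g$shapes[[out]], output_id = out),
            class = "model_spec")
}

#' @rdname mrb_subgraph
#' @param channels channel count preserved along the residual path.
#' @param repetitions basic-block repetitions; fixed at 4.
#' @export
respath_subgraph <- function(channels, repetitions = 4L, input_size = 16L) {
  g <- new_graph(c(input_size, input_size, channels))
  out <- respath_block(g, "respath", "input", 0L, repetitions = repetitions)
  structure(list(name = "respath_subgraph", nodes = g$nodes, shapes = g$shapes,
                 input_shape = c(input_size, input_size, channels),
                 output_shape = g$shapes[[out]], output_id = out),
            class = "model_spec")
}

#' Branch channels of a MultiRes block
#'
#' @param width block width, divisible by 6.
#' @return integer triple `(width/6, 2*width/6, 3*width/6)`.
#' @examples mrb_branch_channels(96)
#' @export
mrb_branch_channels <- function(width) {
  if (width %% 6 != 0)
    stop("MultiRes block width must be divisible by 6, got ", width)
  as.integer(c(width / 6, 2 * width / 6, 3 * width / 6))
}

# Residual path: four repetitions of f(X) = relu(conv1(X)) + relu(conv3(X)),
# channels preserved throughout.
respath_block <- function(g, prefix, input, stage, repetitions = 4L) {
  if (repetitions != 4L)
    stop("the residual path is fixed at 4 repetitions")
  ch <- g$shapes[[input]][3]
  x <- input
  for (r in seq_len(repetitions)) {
    c1 <- g_conv(g, sprintf("%s_r%d_conv1", prefix, r), x, 1, ch, "relu",
                 stage, "skip")
    c3 <- g_conv(g, sprintf("%s_r%d_conv3", prefix, r), x, 3, ch, "relu",
                 stage, "skip")
    x <- g_add(g, sprintf("%s_r%d_add", prefix, r), c(c1, c3))
  }
  x
}

# ---- architecture table --------------------------------------------------

ARCH_NAMES <- c("unet", "half_unet", "multiresunet",
                "half_multiresunet", "quarter_multiresunet")

arch_depth <- function(name) {
  switch(name, unet = 4L, half_unet = 2L, multiresunet = 4L,
         half_multiresunet = 2L, quarter_multiresunet = 1L,
         stop("unknown architecture: ", name))
}

#' Default per-stage channel widths
#'
#' Returns the channel-width table of one of the five architectures.  The
#' widths are recorded in a versioned YAML config shipped with the
#' package; they are declared correct because the resulting parameter and
#' FLOP counts reproduce the published complexity table for all five
#' networks at 512 x 512 input.
#'
#' @param name architecture name, one of
#'   `r paste0('"', paste(ARCH_NAMES, collapse = '", "'), '"')`.
#' @return named list: `encoder` widths (stage 0 .. bottleneck),
#'   `decoder` widths, and for the MultiRes family a `stem` width.
#' @export
default_widths <- function(name) {
  cfgfile <- system.file("extdata", "architectures.yaml",
                         package = "tinysegnet")
  cfg <- yaml::read_yaml(cfgfile)
  if (!name %in% names(cfg)) stop("unknown architecture: ", name)
  cfg[[name]]
}

#' Build one of the five segmentation architectures
#'
#' Constructs the layer graph of the requested architecture as an explicit
#' node list with validated shapes.  The U-net family uses plain
#' concatenation skip connections; the MultiRes family routes each skip
#' through a residual path and replaces plain stages with MultiRes
#' blocks.  Decoding upsamples with 2x nearest interpolation; the output
#' layer is a 1x1 sigmoid convolution to a single channel, so the
#' probability map has the input's spatial size.
#'
#' @param name architecture name (see [default_widths()]).
#' @param input_shape integer `(H, W, C)`; `H` and `W` must be divisible
#'   by `2^depth` (16 for the full networks, 4 for the Half variants, 2
#'   for Quarter MultiResUNet).
#' @param widths optional width table overriding [default_widths()].
#' @return object of class `"model_spec"`: list with `name`, `nodes`,
#'   `input_shape`, `output_shape`, `output_id`.
#' @examples
#' m <- build_model("quarter_multiresunet", input_shape = c(64, 64, 1))
#' m
#' @export
build_model <- function(name, input_shape = c(512L, 512L, 3L),
                        widths = NULL) {
  name <- match.arg(name, ARCH_NAMES)
  depth <- arch_depth(name)
  if (any(input_shape[1:2] %% 2^depth != 0))
    stop("input size must be divisible by ", 2^depth, " for ", name)
  w <- if (is.null(widths)) default_widths(name) else widths
  g <- new_graph(input_shape)
  out <- if (name %in% c("unet", "half_unet"))
    build_unet_family(g, w, depth)
  else
    build_multires_family(g, w, depth)
  final <- g_conv(g, "output", out, 1, 1, "sigmoid", stage = NA_integer_)
  structure(list(name = name, nodes = g$nodes, shapes = g$shapes,
                 input_shape = input_shape,
                 output_shape = g$shapes[[final]],
                 output_id = final, widths = w),
            class = "model_spec")
}

build_unet_family <- function(g, w, depth) {
  enc <- w$encoder
  dec <- w$decoder
  stopifnot(length(enc) == depth + 1, length(dec) == depth)
  skips <- character(depth)
  x <- unet_stage(g, "stage0", "input", enc[1], 0L)
  if (depth >= 1) skips[1] <- x
  for (i in seq_len(depth)) {
    p <- g_pool(g, sprintf("stage%d_pool", i), x)
    x <- unet_stage(g, sprintf("stage%d", i), p, enc[i + 1], i)
    if (i < depth) skips[i + 1] <- x
  }
  for (j in seq_len(depth)) {
    i <- depth + j
    up <- g_upsample(g, sprintf("stage%d_up", i), x)
    cc <- g_concat(g, sprintf("stage%d_concat", i),
                   c(skips[depth - j + 1], up))
    x <- unet_stage(g, sprintf("stage%d", i), cc, dec[j], i)
  }
  x
}

build_multires_family <- function(g, w, depth) {
  enc <- w$encoder
  dec <- w$decoder
  stopifnot(length(enc) == depth + 1, length(dec) == depth)
  stem <- g_conv(g, "stem", "input", 3, w$stem, "linear", 0L)
  skips <- character(depth)
  b <- mrb_block(g, "stage0_mrb", stem, enc[1], 0L)
  x <- g_act(g, "stage0_act", b, "relu")
  if (depth >= 1) skips[1] <- x
  for (i in seq_len(depth)) {
    p <- g_pool(g, sprintf("stage%d_pool", i), x)
    b <- mrb_block(g, sprintf("stage%d_mrb", i), p, enc[i + 1], i)
    x <- g_act(g, sprintf("stage%d_act", i), b, "relu")
    if (i < depth) skips[i + 1] <- x
  }
  for (j in seq_len(depth)) {
    i <- depth + j
    rp <- respath_block(g, sprintf("respath%d", depth - j),
                        skips[depth - j + 1], depth - j)
    up <- g_upsample(g, sprintf("stage%d_up", i), x)
    cc <- g_concat(g, sprintf("stage%d_concat", i), c(rp, up))
    b <- mrb_block(g, sprintf("stage%d_mrb", i), cc, dec[j], i)
    x <- g_act(g, sprintf("stage%d_act", i), b, "relu")
  }
  x
}

#' @export
print.model_spec <- function(x, ...) {
  nconv <- sum(vapply(x$nodes, function(n) n$op == "conv", TRUE))
  cat(sprintf("<model_spec> %s\n", x$name))
  cat(sprintf("  input  %s\n", paste(x$input_shape, collapse = " x ")))
  cat(sprintf("  output %s\n", paste(x$output_shape, collapse = " x ")))
  cat(sprintf("  %d nodes (%d conv layers), %s parameters\n",
              length(x$nodes), nconv,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- weights -------------------------------------------------------------

conv_nodes <- function(model) {
  Filter(function(n) n$op == "conv", model$nodes)
}

#' Initialise model weights
#'
#' Glorot-uniform kernels (`limit = sqrt(6 / (fan_in + fan_out))`) and
#' zero biases for every convolutional node.
#'
#' @param model `"model_spec"`.
#' @param seed optional integer seed.
#' @return named list: per conv node a list with kernel `K`
#'   (`k x k x in x out`) and bias `b` (`out`).
#' @export
init_weights <- function(model, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  ws <- list()
  for (n in conv_nodes(model)) {
    fan_in <- n$k^2 * n$in_ch
    fan_out <- n$k^2 * n$out_ch
    lim <- sqrt(6 / (fan_in + fan_out))
    K <- array(stats::runif(n$k^2 * n$in_ch * n$out_ch, -lim, lim),
               dim = c(n$k, n$k, n$in_ch, n$out_ch))
    ws[[n$id]] <- list(K = K, b = numeric(n$out_ch))
  }
  ws
}

zero_weights <- function(model) {
  ws <- list()
  for (n in conv_nodes(model))
    ws[[n$id]] <- list(K = array(0, c(n$k, n$k, n$in_ch, n$out_ch)),
                       b = numeric(n$out_ch))
  ws
}

# ---- forward pass --------------------------------------------------------

act_code <- function(a) switch(a, linear = 0L, relu = 1L, sigmoid = 2L,
                               stop("unknown activation: ", a))

as_hwc <- function(x, shape) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!all(dim(x) == shape))
    stop("input shape ", paste(dim(x), collapse = "x"),
         " does not match model input ", paste(shape, collapse = "x"))
  x
}

# Evaluate the graph; returns the cache environment (per-node outputs and
# pooling argmax indices) for use by the backward pass.
forward_cache <- function(model, image, weights) {
  cache <- new.env(parent = emptyenv())
  cache$out <- list()
  cache$poolidx <- list()
  cache$out[["input"]] <- as_hwc(image, model$input_shape)
  for (n in model$nodes) {
    if (n$op == "input") next
    ins <- lapply(n$inputs, function(i) cache$out[[i]])
    cache$out[[n$id]] <- switch(n$op,
      conv = {
        wt <- weights[[n$id]]
        if (is.null(wt)) stop("missing weights for conv node ", n$id)
        cpp_conv2d_fwd(ins[[1]], wt$K, wt$b, act_code(n$activation))
      },
      maxpool2 = {
        r <- cpp_maxpool2_fwd(ins[[1]])
        cache$poolidx[[n$id]] <- r$idx
        r$out
      },
      upsample2 = cpp_upsample2_fwd(ins[[1]]),
      concat = {
        d <- dim(ins[[1]])
        arr <- array(0, c(d[1], d[2], sum(vapply(ins, function(x) dim(x)[3], 0))))
        at <- 0L
        for (x in ins) {
          arr[, , at + seq_len(dim(x)[3])] <- x
          at <- at + dim(x)[3]
        }
        arr
      },
      add = Reduce(`+`, ins),
      activation = {
        x <- ins[[1]]
        if (n$activation == "relu") pmax(x, 0)
        else if (n$activation == "sigmoid") 1 / (1 + exp(-x))
        else x
      },
      stop("unknown op: ", n$op))
  }
  cache
}

#' Forward pass of a segmentation model
#'
#' Evaluates the layer graph on one image and returns the sigmoid
#' probability map (values strictly inside (0, 1), same spatial size as
#' the input).
#'
#' @param model `"model_spec"`.
#' @param image numeric matrix or `H x W x C` array matching
#'   `model$input_shape`.
#' @param weights weight list from [init_weights()] or a trained model.
#' @return `H x W` numeric matrix of foreground probabilities.
#' @export
forward <- function(model, image, weights) {
  cache <- forward_cache(model, image, weights)
  out <- cache$out[[model$output_id]]
  matrix(out, dim(out)[1], dim(out)[2])
}
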