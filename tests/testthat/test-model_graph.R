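toy_half_unet <- function(input_shape = c(64, 64, 1),
                          widths = list(encoder = c(8, 16, 32),
                                        decoder = c(16, 8))) {
  build_model("half_unet", input_shape = input_shape, widths = widths)
}

test_that("MultiRes block branch channels follow the 1/6, 2/6, 3/6 split", {
  expect_equal(mrb_branch_channels(6), c(1L, 2L, 3L))
  expect_equal(mrb_branch_channels(96), c(16L, 32L, 48L))
  expect_equal(sum(mrb_branch_channels(96)), 96)
  expect_error(mrb_branch_channels(16), "divisible by 6")
  # output channel count always equals the block width
  for (w in c(6, 12, 36, 90)) expect_equal(sum(mrb_branch_channels(w)), w)
})

test_that("toy half U-net parameter count equals a hand-summed ledger", {
  m <- toy_half_unet()
  # ledger: k^2*in*out + out over the node list, walked independently
  expect_equal(count_parameters(m), naive_param_ledger(m))
  # explicit hand sum for widths {8,16,32}, 1 input channel:
  hand <- (9 * 1 * 8 + 8) + (9 * 8 * 8 + 8) +        # stage 0
    (9 * 8 * 16 + 16) + (9 * 16 * 16 + 16) +         # encoder 1
    (9 * 16 * 32 + 32) + (9 * 32 * 32 + 32) +        # encoder 2 (bottleneck)
    (9 * (16 + 32) * 16 + 16) + (9 * 16 * 16 + 16) + # decoder 3
    (9 * (8 + 16) * 8 + 8) + (9 * 8 * 8 + 8) +       # decoder 4
    (1 * 8 * 1 + 1)                                  # final 1x1 sigmoid
  expect_equal(count_parameters(m), hand)
})

test_that("residual path has fixed repetitions and a closed-form ledger", {
  m <- build_model("quarter_multiresunet", input_shape = c(32, 32, 1),
                   widths = list(stem = 4, encoder = c(12, 12), decoder = c(12)))
  rp_convs <- Filter(function(n) n$op == "conv" && grepl("^respath", n$id),
                     m$nodes)
  expect_length(rp_convs, 8)            # 4 repetitions x (conv1 + conv3)
  c <- 12
  rp_params <- sum(vapply(rp_convs, function(n)
    n$k^2 * n$in_ch * n$out_ch + n$out_ch, 0))
  expect_equal(rp_params, 4 * ((1 * c * c + c) + (9 * c * c + c)))
})

test_that("standalone block subgraphs follow their closed-form ledgers", {
  # residual path: 4 * [(1*c*c + c) + (9*c*c + c)]
  for (c in c(1, 3, 12)) {
    rp <- respath_subgraph(c)
    expect_equal(count_parameters(rp), 4 * ((c * c + c) + (9 * c * c + c)))
    expect_equal(rp$output_shape[3], c)
  }
  expect_equal(count_parameters(respath_subgraph(1)), 48)
  expect_error(respath_subgraph(4, repetitions = 3), "4 repetitions")

  # MRB with matching input: no projection, channels preserved
  for (xc in c(6, 96)) {
    b <- mrb_subgraph(xc)
    expect_equal(b$output_shape[3], xc)
  }
  # mismatched input: projection shortcut appears, output width still t
  b <- mrb_subgraph(12, in_channels = 7)
  expect_equal(b$output_shape[3], 12)
  expect_true("mrb_shortcut" %in% names(b$nodes))
})

test_that("built models preserve spatial size and validate divisibility", {
  for (name in c("unet", "half_unet", "multiresunet",
                 "half_multiresunet", "quarter_multiresunet")) {
    depth <- switch(name, unet = 4, multiresunet = 4, half_unet = 2,
                    half_multiresunet = 2, quarter_multiresunet = 1)
    for (s in 2^depth * c(1, 2, 3)) {
      m <- build_model(name, input_shape = c(s, s, 3))
      expect_equal(m$output_shape[1:2], c(s, s))
      expect_equal(m$output_shape[3], 1)
    }
    expect_error(build_model(name, input_shape = c(2^depth + 1, 2^depth, 3)),
                 "divisible")
  }
  expect_error(build_model("segnet"), "arg")
})

test_that("quarter MultiResUNet has exactly one pooling and one upsampling", {
  m <- build_model("quarter_multiresunet", input_shape = c(64, 64, 3))
  ops <- vapply(m$nodes, `[[`, "", "op")
  expect_equal(sum(ops == "maxpool2"), 1)
  expect_equal(sum(ops == "upsample2"), 1)
})

test_that("final node is a sigmoid 1x1 conv to one channel in every model", {
  for (name in c("unet", "half_unet", "multiresunet",
                 "half_multiresunet", "quarter_multiresunet")) {
    m <- build_model(name, input_shape = c(16 * 4, 16 * 4, 3))
    out <- m$nodes[[m$output_id]]
    expect_equal(out$op, "conv")
    expect_equal(out$k, 1L)
    expect_equal(out$out_ch, 1L)
    expect_equal(out$activation, "sigmoid")
  }
})

test_that("forward pass has closed-form behaviour in degenerate cases", {
  m <- toy_half_unet(c(16, 16, 1))
  img <- matrix(runif(256), 16, 16)
  # all-zero weights: sigmoid(0) = 0.5 everywhere
  p <- forward(m, img, tinysegnet:::zero_weights(m))
  expect_true(all(p == 0.5))
  # output strictly inside (0,1) with random weights
  p <- forward(m, img, init_weights(m, seed = 1))
  expect_true(all(p > 0 & p < 1))
  # determinism given weights
  w <- init_weights(m, seed = 9)
  expect_identical(forward(m, img, w), forward(m, img, w))
  # shape mismatch rejected
  expect_error(forward(m, matrix(0, 8, 8), w), "shape")
})

test_that("single 1x1 conv model gives sigmoid(w*v + b) on constant input", {
  m <- toy_half_unet(c(16, 16, 1))
  # check the conv kernel directly instead: 1-px kernel closed form
  x <- array(0.3, c(4, 4, 1))
  K <- array(2, c(1, 1, 1, 1)); b <- 0.5
  out <- tinysegnet:::cpp_conv2d_fwd(x, K, b, 2L)
  expect_equal(as.numeric(out), rep(1 / (1 + exp(-(2 * 0.3 + 0.5))), 16),
               tolerance = 1e-6)
})

test_that("conv/pool/upsample kernels match scalar-loop oracles", {
  set.seed(5)
  for (r in 1:5) {
    x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
    K <- array(rnorm(3 * 3 * 3 * 4, sd = 0.3), c(3, 3, 3, 4))
    b <- rnorm(4)
    for (act in c(0L, 1L, 2L)) {
      fast <- tinysegnet:::cpp_conv2d_fwd(x, K, b, act)
      slow <- naive_conv2d(x, K, b, c("linear", "relu", "sigmoid")[act + 1])
      expect_equal(as.numeric(fast), as.numeric(slow), tolerance = 1e-5)
    }
    K1 <- array(rnorm(1 * 1 * 3 * 2), c(1, 1, 3, 2))
    fast <- tinysegnet:::cpp_conv2d_fwd(x, K1, rnorm(2) * 0, 0L)
    slow <- naive_conv2d(x, K1, c(0, 0), "linear")
    expect_equal(as.numeric(fast), as.numeric(slow), tolerance = 1e-5)

    mp <- tinysegnet:::cpp_maxpool2_fwd(x)
    expect_equal(as.numeric(mp$out), as.numeric(naive_maxpool2(x)))
    expect_equal(as.numeric(tinysegnet:::cpp_upsample2_fwd(x)),
                 as.numeric(naive_upsample2(x)))
  }
})

test_that("maxpool2 then upsample2 reproduces a constant image", {
  x <- array(0.7, c(8, 8, 2))
  y <- tinysegnet:::cpp_upsample2_fwd(tinysegnet:::cpp_maxpool2_fwd(x)$out)
  expect_equal(as.numeric(y), as.numeric(x))
})

test_that("full toy-graph forward equals a straight-line re-implementation", {
  # two-stage toy half U-net evaluated with naive scalar ops only
  m <- toy_half_unet(c(16, 16, 1), widths = list(encoder = c(4, 6, 8),
                                                 decoder = c(6, 4)))
  w <- init_weights(m, seed = 3)
  img <- matrix(runif(256), 16, 16)
  p_fast <- forward(m, img, w)

  x <- array(img, c(16, 16, 1))
  s0 <- naive_conv2d(naive_conv2d(x, w$stage0_conv1$K, w$stage0_conv1$b),
                     w$stage0_conv2$K, w$stage0_conv2$b, "relu")
  e1 <- naive_conv2d(naive_conv2d(naive_maxpool2(s0),
                                  w$stage1_conv1$K, w$stage1_conv1$b),
                     w$stage1_conv2$K, w$stage1_conv2$b, "relu")
  e2 <- naive_conv2d(naive_conv2d(naive_maxpool2(e1),
                                  w$stage2_conv1$K, w$stage2_conv1$b),
                     w$stage2_conv2$K, w$stage2_conv2$b, "relu")
  up3 <- naive_upsample2(e2)
  cc3 <- array(c(e1, up3), c(8, 8, dim(e1)[3] + dim(up3)[3]))
  d3 <- naive_conv2d(naive_conv2d(cc3, w$stage3_conv1$K, w$stage3_conv1$b),
                     w$stage3_conv2$K, w$stage3_conv2$b, "relu")
  up4 <- naive_upsample2(d3)
  cc4 <- array(c(s0, up4), c(16, 16, dim(s0)[3] + dim(up4)[3]))
  d4 <- naive_conv2d(naive_conv2d(cc4, w$stage4_conv1$K, w$stage4_conv1$b),
                     w$stage4_conv2$K, w$stage4_conv2$b, "relu")
  p_slow <- naive_conv2d(d4, w$output$K, w$output$b, "sigmoid")[, , 1]
  expect_equal(as.numeric(p_fast), as.numeric(p_slow), tolerance = 1e-5)
})

test_that("MultiRes block preserves channels under the additive shortcut", {
  for (xc in c(6, 12, 36)) {
    m <- build_model("quarter_multiresunet", input_shape = c(16, 16, 1),
                     widths = list(stem = xc, encoder = c(xc, xc),
                                   decoder = c(2 * xc)))
    # stage0 MRB input (stem output) has xc channels and output has xc:
    expect_equal(m$shapes[["stage0_mrb_add"]][3], xc)
    # in == width: the block must not contain a shortcut projection
    expect_false("stage0_mrb_shortcut" %in% names(m$nodes))
    # decoder block input 2*xc == width: plain shortcut again
    expect_equal(m$shapes[["stage2_mrb_add"]][3], 2 * xc)
  }
})

test_that("weight archives round-trip and count their scalars", {
  m <- toy_half_unet(c(16, 16, 1))
  w <- init_weights(m, seed = 2)
  expect_equal(weight_scalar_count(w), count_parameters(m))
  tf <- tempfile(fileext = ".rds")
  save_weights(w, tf, model = m)
  lw <- load_weights(tf)
  expect_equal(lw$weights, w)
  expect_equal(lw$model$name, m$name)
  unlink(tf)
})
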