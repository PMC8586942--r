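# Independent brute-force oracles used to cross-check the fast paths.
# These are deliberately naive (scalar loops, direct enumeration) and share
# no code with the package internals.

# Scalar-loop "same"-padded stride-1 convolution, cross-correlation form:
# out[i,j,o] = sum_{n,m,c} x[i+n-p, j+m-p, c] * K[n,m,c,o] + b[o]
naive_conv2d <- function(x, K, b, activation = "linear") {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(K)[1]; Cout <- dim(K)[4]
  p <- (k - 1) / 2
  out <- array(0, c(H, W, Cout))
  for (o in seq_len(Cout)) for (j in seq_len(W)) for (i in seq_len(H)) {
    acc <- b[o]
    for (c in seq_len(Cin)) for (m in seq_len(k)) for (n in seq_len(k)) {
      ii <- i + n - 1 - p; jj <- j + m - 1 - p
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, c] * K[n, m, c, o]
    }
    out[i, j, o] <- acc
  }
  if (activation == "relu") out <- pmax(out, 0)
  if (activation == "sigmoid") out <- 1 / (1 + exp(-out))
  out
}

naive_maxpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  out <- array(0, c(H / 2, W / 2, C))
  for (c in seq_len(C)) for (j in seq_len(W / 2)) for (i in seq_len(H / 2))
    out[i, j, c] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  out
}

naive_upsample2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  out <- array(0, c(2 * H, 2 * W, C))
  for (c in seq_len(C)) for (j in seq_len(W)) for (i in seq_len(H)) {
    out[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c] <- x[i, j, c]
  }
  out
}

# Direct per-pixel metric computation from two masks (no confusion-count
# data structure involved).
naive_metrics <- function(y, p) {
  y <- as.logical(y); p <- as.logical(p)
  tp <- sum(y & p); fp <- sum(!y & p); fn <- sum(y & !p)
  recall <- tp / (tp + fn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  miou <- tp / (tp + fp + fn)
  c(recall = recall, precision = precision, f1 = f1, miou = miou,
    rw_f1 = f1 * recall, rw_miou = miou * recall)
}

# Brute-force FLOP count: walk every output scalar of every conv and count
# its multiplications and additions one by one; add element-wise adds.
naive_flops <- function(model) {
  total <- 0
  for (n in model$nodes) {
    sh <- model$shapes[[n$id]]
    if (n$op == "conv") {
      per_scalar <- n$k * n$k * n$in_ch +      # multiplications
        (n$k * n$k * n$in_ch - 1) +            # additions in the sum
        1                                      # bias addition
      total <- total + sh[1] * sh[2] * sh[3] * per_scalar
    } else if (n$op == "add") {
      total <- total + (length(n$inputs) - 1) * prod(sh)
    }
  }
  total
}

# Hand-summed parameter ledger walking the node list.
naive_param_ledger <- function(model) {
  tot <- 0
  for (n in model$nodes)
    if (n$op == "conv")
      tot <- tot + n$k^2 * n$in_ch * n$out_ch + n$out_ch
  tot
}

# quick scene list for training smoke tests
tiny_scenes <- function(n, size = 32, seed = 42) {
  cfg <- scene_config(size = size, n_particles = c(1L, 2L),
                      diameter_px = c(3, 4),
                      max_foreground_fraction = 0.3)
  synth_dataset(n, cfg, seed = seed)
}
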