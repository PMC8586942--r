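#' Tile a photo and its mask into fixed-size crops
#'
#' Large source photos (1440 x 1440 by default) are cut into `tile` x
#' `tile` crops laid on a regular grid with `overlap` shared pixels
#' between adjacent tiles (stride `tile - overlap`).  The final row and
#' column of the grid are snapped to the image edge so that every source
#' pixel is covered by at least one tile.
#'
#' @param image numeric matrix (H x W) or array (H x W x C).
#' @param mask binary matrix of the same spatial size (optional).
#' @param tile tile side in pixels (default 512).
#' @param overlap shared border between adjacent tiles in pixels
#'   (default 100, i.e. stride 412).
#' @return object of class `"tile_set"`: list with `offsets_row`,
#'   `offsets_col` (0-based grid offsets) and `tiles`, a list of
#'   `list(row, col, image, mask)` entries.
#' @examples
#' img <- matrix(runif(600 * 600), 600, 600)
#' ts <- crop_tiles(img, tile = 512, overlap = 100)
#' length(ts$tiles)
#' @export
crop_tiles <- function(image, mask = NULL, tile = 512L, overlap = 100L) {
  dm <- dim(image)
  H <- dm[1]; W <- dm[2]
  if (H < tile || W < tile) stop("image smaller than tile size")
  stride <- tile - overlap
  if (stride <= 0) stop("overlap must be smaller than tile")
  offsets <- function(n) {
    off <- seq(0L, max(n - tile, 0L), by = stride)
    if (off[length(off)] + tile < n) off <- c(off, n - tile)
    unique(off)
  }
  orow <- offsets(H); ocol <- offsets(W)
  tiles <- list()
  slice <- function(x, r, c) {
    if (length(dim(x)) == 3) x[r + seq_len(tile), c + seq_len(tile), , drop = FALSE]
    else x[r + seq_len(tile), c + seq_len(tile), drop = FALSE]
  }
  for (r in orow) for (c in ocol) {
    tiles[[length(tiles) + 1L]] <- list(
      row = r, col = c,
      image = slice(image, r, c),
      mask = if (is.null(mask)) NULL else slice(mask, r, c))
  }
  structure(list(tile = tile, overlap = overlap, source_dim = c(H, W),
                 offsets_row = orow, offsets_col = ocol, tiles = tiles),
            class = "tile_set")
}

#' Reassemble a tile set into the source image
#'
#' Inverse of [crop_tiles()]: writes every tile back at its offset (later
#' tiles overwrite the overlap region, which is identical anyway), which
#' reproduces the source exactly.
#'
#' @param ts `"tile_set"` object.
#' @return numeric matrix of the original size.
#' @export
assemble_tiles <- function(ts) {
  out <- matrix(0, ts$source_dim[1], ts$source_dim[2])
  for (tl in ts$tiles)
    out[tl$row + seq_len(ts$tile), tl$col + seq_len(ts$tile)] <-
      tl$image
  out
}

#' Augmentation configuration
#'
#' Training-time augmentation: random translation up to a fraction of the
#' image size per axis, random rotation within +/- `max_rotation` degrees,
#' and random horizontal/vertical flips.  Empty space created by shifting
#' or rotation is filled with `fill` in the image (conventionally the
#' training-set mean pixel) and with 0 (background) in the mask.
#'
#' @param max_shift_fraction maximum |translation| per axis as a fraction
#'   of the image side (default 0.20).
#' @param max_rotation maximum |rotation| in degrees (default 45).
#' @param flip_h,flip_v allow horizontal / vertical flips.
#' @param fill image fill value for exposed pixels (dataset mean).
#' @return list of class `"augment_config"`.
#' @export
augment_config <- function(max_shift_fraction = 0.20, max_rotation = 45,
                           flip_h = TRUE, flip_v = TRUE, fill = 0.5) {
  stopifnot(max_shift_fraction >= 0, max_shift_fraction <= 1,
            max_rotation >= 0, max_rotation < 360)
  structure(list(max_shift_fraction = max_shift_fraction,
                 max_rotation = max_rotation,
                 flip_h = flip_h, flip_v = flip_v, fill = fill),
            class = "augment_config")
}

# Affine resample with nearest-neighbour lookup; `fill` outside the source.
# theta in degrees, shift in pixels; rotation about the image centre.
affine_nearest <- function(x, theta, shift_r, shift_c, flip_h, flip_v, fill) {
  H <- nrow(x); W <- ncol(x)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  gi <- matrix(seq_len(H), H, W)
  gj <- matrix(seq_len(W), H, W, byrow = TRUE)
  # inverse map: undo shift, then undo rotation, then undo flips
  i1 <- gi - shift_r; j1 <- gj - shift_c
  th <- -theta * pi / 180
  i2 <- cr + cos(th) * (i1 - cr) - sin(th) * (j1 - cc)
  j2 <- cc + sin(th) * (i1 - cr) + cos(th) * (j1 - cc)
  if (flip_h) j2 <- W + 1 - j2
  if (flip_v) i2 <- H + 1 - i2
  ii <- round(i2); jj <- round(j2)
  ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
  out <- matrix(fill, H, W)
  out[ok] <- x[cbind(ii[ok], jj[ok])]
  out
}

#' Apply a random geometric augmentation to an image/mask pair
#'
#' Draws one transform (shift, rotation, flips) and applies it identically
#' to the image and the mask.  The mask is resampled with nearest
#' neighbour and re-binarised, so 3-px objects keep crisp boundaries; its
#' exposed pixels are background (0).
#'
#' @param image numeric matrix (or H x W x C array; channels share the
#'   transform).
#' @param mask binary matrix of the same spatial size.
#' @param cfg [augment_config()].
#' @return list with transformed `image`, `mask`, and the drawn
#'   `transform` parameters.
#' @export
augment <- function(image, mask, cfg = augment_config()) {
  dm <- dim(image)
  H <- dm[1]; W <- dm[2]
  if (!all(dim(mask)[1:2] == c(H, W))) stop("image/mask size mismatch")
  tr <- list(
    theta = stats::runif(1, -cfg$max_rotation, cfg$max_rotation),
    shift_r = round(stats::runif(1, -cfg$max_shift_fraction,
                                 cfg$max_shift_fraction) * H),
    shift_c = round(stats::runif(1, -cfg$max_shift_fraction,
                                 cfg$max_shift_fraction) * W),
    flip_h = cfg$flip_h && stats::runif(1) < 0.5,
    flip_v = cfg$flip_v && stats::runif(1) < 0.5)
  ap <- function(x, fill) affine_nearest(x, tr$theta, tr$shift_r, tr$shift_c,
                                         tr$flip_h, tr$flip_v, fill)
  if (length(dm) == 3) {
    img <- array(0, dm)
    for (c in seq_len(dm[3])) img[, , c] <- ap(image[, , c], cfg$fill)
  } else img <- ap(image, cfg$fill)
  msk <- ap(mask, 0)
  msk <- (msk > 0.5) * 1
  list(image = img, mask = msk, transform = tr)
}

#' Synthetic sand-scene configuration
#'
#' Parameters of the synthetic fixture generator that emulates photos of
#' beach sand with a few microplastic particles: a granular textured
#' background plus a handful of compact bright or dark blobs of 3-10 px
#' diameter, jointly occupying less than 1% of the pixels.
#'
#' @param size image side in pixels.
#' @param n_particles integer range `c(min, max)` of particles per scene.
#' @param diameter_px particle diameter range in pixels (default 3-10,
#'   the reported microplastic size range).
#' @param intensity_bright,intensity_dark intensity ranges for bright and
#'   dark particles (each particle picks one polarity at random).
#' @param bg_mean,bg_sd background texture mean and amplitude.
#' @param granule_px approximate granule correlation length in pixels.
#' @param channels 1 for grayscale, 3 for RGB.
#' @param max_foreground_fraction rejection bound on the foreground share.
#' @return list of class `"scene_config"`.
#' @export
scene_config <- function(size = 128L, n_particles = c(3L, 8L),
                         diameter_px = c(3, 10),
                         intensity_bright = c(0.85, 1.0),
                         intensity_dark = c(0.0, 0.15),
                         bg_mean = 0.5, bg_sd = 0.08, granule_px = 3L,
                         channels = 1L,
                         max_foreground_fraction = 0.01) {
  stopifnot(diameter_px[1] >= 3, diameter_px[2] <= 10,
            size >= 8, channels %in% c(1L, 3L))
  structure(as.list(environment()), class = "scene_config")
}

# box-smoothed uniform noise: quick granular texture
granular_texture <- function(size, granule_px, mean, sd) {
  x <- matrix(stats::runif(size * size), size, size)
  passes <- max(1L, as.integer(granule_px) - 1L)
  for (p in seq_len(passes)) {
    # 3x3 box blur with replicated edges
    pad <- rbind(x[1, , drop = FALSE], x, x[size, , drop = FALSE])
    pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, size, drop = FALSE])
    x <- (pad[1:size, 1:size] + pad[1:size, 2:(size + 1)] + pad[1:size, 3:(size + 2)] +
          pad[2:(size + 1), 1:size] + pad[2:(size + 1), 2:(size + 1)] + pad[2:(size + 1), 3:(size + 2)] +
          pad[3:(size + 2), 1:size] + pad[3:(size + 2), 2:(size + 1)] + pad[3:(size + 2), 3:(size + 2)]) / 9
  }
  x <- (x - mean(x)) / stats::sd(x)
  mean + sd * x
}

#' Generate one synthetic sand-with-particles scene
#'
#' Renders a granular background and a few non-overlapping circular
#' particles of 3-10 px diameter into an image and its binary ground-truth
#' mask.  The generator is the stand-in for the (undeposited) microplastic
#' photo dataset: it reproduces the tiny-object geometry and the >99%
#' background class imbalance, not the photometric detail of real sand.
#'
#' @param cfg [scene_config()].
#' @param seed optional integer; when given the scene is reproducible.
#' @return list with `image` (H x W or H x W x C, values in `[0, 1]`),
#'   `mask` (H x W binary), and `particles` (data frame of centres,
#'   diameters, intensities).
#' @export
synth_scene <- function(cfg = scene_config(), seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  S <- cfg$size
  bg <- granular_texture(S, cfg$granule_px, cfg$bg_mean, cfg$bg_sd)
  bg <- pmin(pmax(bg, 0), 1)
  mask <- matrix(0, S, S)
  img <- bg
  n <- if (cfg$n_particles[1] == cfg$n_particles[2]) cfg$n_particles[1] else
    sample(cfg$n_particles[1]:cfg$n_particles[2], 1)
  budget <- cfg$max_foreground_fraction * S * S
  min_area <- cfg$n_particles[1] * ceiling(pi * (cfg$diameter_px[1] / 2)^2)
  if (min_area > budget)
    stop("particle area exceeds the foreground budget; relax scene_config")
  # draw diameters conditioned on the foreground budget: resample until the
  # upper-bound disk area of the whole set fits
  diams <- NULL
  for (try in 1:100) {
    d <- stats::runif(n, cfg$diameter_px[1], cfg$diameter_px[2])
    if (sum(ceiling(pi * (d / 2 + 0.5)^2)) <= budget) { diams <- d; break }
  }
  if (is.null(diams)) {
    n <- cfg$n_particles[1]
    diams <- rep(cfg$diameter_px[1], n)
  }
  centres <- matrix(numeric(0), 0, 2)
  parts <- data.frame(row = numeric(0), col = numeric(0),
                      diameter = numeric(0), intensity = numeric(0))
  placed <- 0L; tries <- 0L
  while (placed < n && tries < 200L) {
    tries <- tries + 1L
    d <- diams[placed + 1L]
    r <- d / 2
    cr <- stats::runif(1, r + 2, S - r - 1)
    cc <- stats::runif(1, r + 2, S - r - 1)
    if (nrow(centres) > 0 &&
        any(sqrt((centres[, 1] - cr)^2 + (centres[, 2] - cc)^2) < d + 2))
      next
    bright <- stats::runif(1) < 0.5
    val <- if (bright) stats::runif(1, cfg$intensity_bright[1], cfg$intensity_bright[2])
           else stats::runif(1, cfg$intensity_dark[1], cfg$intensity_dark[2])
    ii <- max(1, floor(cr - r)):min(S, ceiling(cr + r))
    jj <- max(1, floor(cc - r)):min(S, ceiling(cc + r))
    sub <- expand.grid(i = ii, j = jj)
    inside <- (sub$i - cr)^2 + (sub$j - cc)^2 <= r^2
    px <- sub[inside, , drop = FALSE]
    if (nrow(px) == 0) next
    mask[cbind(px$i, px$j)] <- 1
    img[cbind(px$i, px$j)] <- val
    centres <- rbind(centres, c(cr, cc))
    parts <- rbind(parts, data.frame(row = cr, col = cc, diameter = d,
                                     intensity = val))
    placed <- placed + 1L
  }
  if (cfg$channels == 3L) {
    arr <- array(0, c(S, S, 3))
    for (c in 1:3) arr[, , c] <- img
    img <- arr
  }
  list(image = img, mask = mask, particles = parts)
}

#' Generate a seeded synthetic dataset
#'
#' @param n number of scenes.
#' @param cfg [scene_config()].
#' @param seed base seed; scene `i` uses `seed + i`.
#' @return list of `n` scenes as returned by [synth_scene()].
#' @export
synth_dataset <- function(n, cfg = scene_config(), seed = 1L) {
  lapply(seq_len(n), function(i) synth_scene(cfg, seed = seed + i))
}

#' Five-fold cross-validation split
#'
#' Partitions `n` samples into `k` disjoint test sets covering the whole
#' dataset; within each fold the remaining samples are split into training
#' (72% of the dataset) and validation (8%) subsets, mirroring the
#' 72/8/20 protocol.
#'
#' @param n dataset size.
#' @param k number of folds (default 5).
#' @param val_fraction validation share of the full dataset (default 0.08).
#' @param seed optional integer seed for the shuffle.
#' @return list of `k` folds, each a list with integer index vectors
#'   `train`, `validation`, `test`; class `"fold_split"`.
#' @export
kfold_split <- function(n, k = 5L, val_fraction = 0.08, seed = NULL) {
  if (n < k) stop("need at least k samples")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  idx <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bounds <- c(0L, cumsum(sizes))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test <- idx[(bounds[f] + 1L):bounds[f + 1L]]
    rest <- setdiff(idx, test)
    nval <- round(val_fraction * n)
    validation <- rest[seq_len(min(nval, length(rest) - 1L))]
    train <- setdiff(rest, validation)
    folds[[f]] <- list(train = sort(train), validation = sort(validation),
                       test = sort(test))
  }
  structure(folds, class = "fold_split")
}
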