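# Training-time slice augmentation. Operations are applied in a fixed order:
# zoom, flips, rotation, intensity scale, intensity shift, additive Gaussian
# noise, min-max normalization to [0,1], resize to the network input size.
# Normalization is the last intensity operation, so augmented slices are
# always in [0,1] regardless of the intensity jitter.

#' Augmentation configuration
#'
#' @param zoom_range in-plane zoom factor range (default `c(0.8, 1.2)`,
#'   i.e. 80--120% of the original size).
#' @param flip_axes axes that may be mirrored, any subset of `c("y", "x")`;
#'   each listed axis is flipped independently with probability 1/2.
#' @param rotate_radians maximum absolute in-plane rotation (default 0.1
#'   radians; the angle is drawn uniformly from `[-rotate_radians,
#'   rotate_radians]`).
#' @param intensity_scale_range multiplicative intensity jitter range
#'   (default `c(0.8, 1.2)`).
#' @param intensity_shift_range additive intensity jitter range (default
#'   `c(0, 0.08)`).
#' @param noise_mean,noise_sd parameters of the additive Gaussian noise
#'   (defaults 0 and 0.04).
#' @param output_size target size `c(rows, cols)` after resizing (default
#'   `c(128, 128)`).
#' @return an object of class `bpr_augment_config`.
#' @export
augment_config <- function(zoom_range = c(0.8, 1.2),
                           flip_axes = c("y", "x"),
                           rotate_radians = 0.1,
                           intensity_scale_range = c(0.8, 1.2),
                           intensity_shift_range = c(0, 0.08),
                           noise_mean = 0,
                           noise_sd = 0.04,
                           output_size = c(128, 128)) {
  ordered_pair <- function(r, nm) assert_that(length(r) == 2 && r[1] <= r[2],
                                              "%s must be an ordered pair", nm)
  ordered_pair(zoom_range, "zoom_range")
  ordered_pair(intensity_scale_range, "intensity_scale_range")
  ordered_pair(intensity_shift_range, "intensity_shift_range")
  assert_that(all(flip_axes %in% c("y", "x")), "flip_axes must be subset of y, x")
  assert_that(rotate_radians >= 0, "rotate_radians must be >= 0")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  if (length(output_size) == 1L) output_size <- c(output_size, output_size)
  assert_that(all(output_size >= 1), "output_size must be positive")
  structure(list(zoom_range = as.numeric(zoom_range),
                 flip_axes = flip_axes,
                 rotate_radians = as.numeric(rotate_radians),
                 intensity_scale_range = as.numeric(intensity_scale_range),
                 intensity_shift_range = as.numeric(intensity_shift_range),
                 noise_mean = as.numeric(noise_mean),
                 noise_sd = as.numeric(noise_sd),
                 output_size = as.integer(output_size)),
            class = "bpr_augment_config")
}

# Draw one set of augmentation parameters (consumes the global RNG).
# Shared across all slices of one stack so relative anatomy is preserved.
draw_augment_params <- function(config) {
  list(zoom = stats::runif(1, config$zoom_range[1], config$zoom_range[2]),
       flip_y = "y" %in% config$flip_axes && stats::runif(1) < 0.5,
       flip_x = "x" %in% config$flip_axes && stats::runif(1) < 0.5,
       angle = stats::runif(1, -config$rotate_radians, config$rotate_radians),
       scale = stats::runif(1, config$intensity_scale_range[1],
                            config$intensity_scale_range[2]),
       shift = stats::runif(1, config$intensity_shift_range[1],
                            config$intensity_shift_range[2]))
}

# Zoom about the image center: resize by `factor`, then center-crop (>1) or
# center-pad with the image minimum (<1) back to the original size.
zoom_slice <- function(x, factor) {
  if (abs(factor - 1) < 1e-12) return(x)
  d <- dim(x)
  nd <- pmax(1L, as.integer(round(d * factor)))
  z <- EBImage::resize(x, w = nd[1], h = nd[2])
  z <- matrix(as.numeric(z), nd[1], nd[2])
  out <- matrix(min(x), d[1], d[2])
  take <- pmin(d, nd)
  src0 <- pmax(0L, (nd - d) %/% 2L)
  dst0 <- pmax(0L, (d - nd) %/% 2L)
  out[dst0[1] + seq_len(take[1]), dst0[2] + seq_len(take[2])] <-
    z[src0[1] + seq_len(take[1]), src0[2] + seq_len(take[2])]
  out
}

# Apply a fixed set of augmentation parameters (no RNG except noise, which
# consumes the global stream).
apply_augment <- function(slice, params, config) {
  x <- slice
  x <- zoom_slice(x, params$zoom)
  if (params$flip_y) x <- x[rev(seq_len(nrow(x))), , drop = FALSE]
  if (params$flip_x) x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
  if (abs(params$angle) > 1e-12) {
    r <- EBImage::rotate(x, params$angle * 180 / pi,
                         output.dim = dim(x), bg.col = min(x))
    x <- matrix(as.numeric(r), nrow(x), ncol(x))
  }
  x <- x * params$scale + params$shift
  if (config$noise_sd > 0)
    x <- x + stats::rnorm(length(x), config$noise_mean, config$noise_sd)
  x <- minmax_normalize(x)
  resize_slice(x, config$output_size)
}

# Bilinear resize to `size` = c(rows, cols); identity when already there.
resize_slice <- function(x, size) {
  if (all(dim(x) == size)) return(x)
  r <- EBImage::resize(x, w = size[1], h = size[2])
  matrix(as.numeric(r), size[1], size[2])
}

#' Augment one 2-D slice
#'
#' Applies, in order: random zoom, random y/x flips, random rotation,
#' random intensity scale and shift, additive Gaussian noise, min-max
#' normalization to `[0, 1]`, and resizing to `config$output_size`.
#' Randomness comes from the global RNG stream, so a fixed `set.seed()`
#' makes the result reproducible. A constant-valued slice normalizes to
#' all zeros.
#'
#' @param slice numeric matrix with finite values.
#' @param config an [augment_config()].
#' @return numeric matrix of size `config$output_size` with values in
#'   `[0, 1]`.
#' @export
augment_slice <- function(slice, config = augment_config()) {
  assert_that(is.matrix(slice) && all(is.finite(slice)),
              "slice must be a finite numeric matrix")
  apply_augment(slice, draw_augment_params(config), config)
}

# Inference-time preprocessing: min-max normalize and resize only.
preprocess_slice <- function(slice, size) {
  resize_slice(minmax_normalize(slice), size)
}
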