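# Multi-scale volumetric feature maps.
#
# Three derived 3D maps complement the normalized density: a multi-scale
# difference-of-Gaussians blobness map (scale-selective band-pass), the Sobel
# gradient magnitude in physical units (edges), and a multi-scale white/black
# top-hat map (local contrast against slowly varying background). All three
# are computed on the full normalized tomogram before windowing, so window
# borders see true context.

#' Feature extraction configuration
#'
#' @param scales strictly increasing positive voxel radii shared by the DoG
#'   and top-hat banks (default 1, 2, 4, 8).
#' @param k DoG sigma ratio (> 1). The conventional sqrt(2) is the default;
#'   set `k = 2` for the coarser band-pass variant.
#' @param scale_normalize multiply each DoG response by `s^2`
#'   (Laplacian-of-Gaussian scale normalization) before the across-scale
#'   argmax, balancing responses across particle sizes.
#' @param clip_percentiles two percentiles (in percent) to which aggregated
#'   feature maps are clipped, default `c(0.01, 99.99)`.
#' @param tophat_scale_power per-scale top-hat responses are multiplied by
#'   `s^tophat_scale_power` (default 1/2) to gently harmonize scales.
#' @return A `feature_config` list.
#' @export
feature_config <- function(scales = c(1, 2, 4, 8), k = sqrt(2),
                           scale_normalize = TRUE,
                           clip_percentiles = c(0.01, 99.99),
                           tophat_scale_power = 0.5) {
  if (length(scales) == 0) stop("scales must be non-empty")
  if (any(scales <= 0) || any(diff(scales) <= 0))
    stop("scales must be strictly increasing and positive")
  if (k <= 1) stop("DoG sigma ratio k must be > 1")
  if (length(clip_percentiles) != 2 || clip_percentiles[1] >= clip_percentiles[2])
    stop("clip_percentiles must be an increasing pair")
  structure(list(scales = scales, k = k, scale_normalize = scale_normalize,
                 clip_percentiles = clip_percentiles,
                 tophat_scale_power = tophat_scale_power),
            class = "feature_config")
}

# Truncated, normalized 1D Gaussian kernel (radius 4 sigma).
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable isotropic Gaussian smoothing with replicate boundaries.
gaussian_smooth <- function(arr, sigma) {
  k <- gaussian_kernel(sigma)
  .conv1d_axis(.conv1d_axis(.conv1d_axis(arr, k, 1L), k, 2L), k, 3L)
}

# Clip an array to its [lo, hi] percentile interval (percent units).
percentile_clip <- function(arr, percentiles = c(0.01, 99.99)) {
  q <- stats::quantile(as.vector(arr), percentiles / 100, names = FALSE)
  array(pmin(pmax(arr, q[1]), q[2]), dim = dim(arr))
}

#' Multi-scale difference-of-Gaussians blobness
#'
#' For every scale `s` the response is `G(ks) - G(s)` (optionally multiplied
#' by `s^2`); at each voxel the signed response of the scale with the maximum
#' absolute magnitude is kept, and the resulting map is clipped to the
#' configured percentile interval.
#'
#' @param v a normalized density [new_volume()].
#' @param cfg a [feature_config()].
#' @return A [new_volume()] blobness map with the input's metadata.
#' @export
dog_max <- function(v, cfg = feature_config()) {
  validate_volume(v)
  stopifnot(inherits(cfg, "feature_config"))
  best_val <- array(0, dim = dim(v$data))
  best_abs <- array(-1, dim = dim(v$data))
  for (s in cfg$scales) {
    d <- gaussian_smooth(v$data, cfg$k * s) - gaussian_smooth(v$data, s)
    if (cfg$scale_normalize) d <- d * s^2
    take <- abs(d) > best_abs
    best_val[take] <- d[take]
    best_abs[take] <- abs(d)[take]
  }
  with_data(v, percentile_clip(best_val, cfg$clip_percentiles))
}

#' 3D Sobel gradient magnitude in physical units
#'
#' Sobel derivatives along x, y and z (derivative stencil `(-1,0,1)` with
#' `(1,2,1)` smoothing on the two orthogonal axes, normalized by 1/32 so a
#' unit-slope ramp responds with exactly 1 per voxel), with replicate
#' boundaries. Each component is divided by the corresponding voxel size, so
#' the magnitude is expressed per Angstrom.
#'
#' @param v a [new_volume()].
#' @return A non-negative gradient-magnitude [new_volume()].
#' @export
sobel_gradient_magnitude <- function(v) {
  validate_volume(v)
  deriv <- c(-1, 0, 1)
  smooth <- c(1, 2, 1)
  sq <- array(0, dim = dim(v$data))
  for (axis in 1:3) {
    g <- v$data
    for (a in 1:3)
      g <- .conv1d_axis(g, if (a == axis) deriv else smooth, a)
    g <- g / 32 / v$voxel_size[axis]
    sq <- sq + g^2
  }
  with_data(v, sqrt(sq))
}

# Integer offsets of a discrete Euclidean ball of radius r voxels.
ball_offsets <- function(r) {
  ri <- as.integer(ceiling(r))
  g <- expand.grid(o1 = (-ri):ri, o2 = (-ri):ri, o3 = (-ri):ri)
  g <- g[g$o1^2 + g$o2^2 + g$o3^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

grey_open <- function(arr, offsets)
  .morph_minmax(.morph_minmax(arr, offsets, FALSE), offsets, TRUE)

grey_close <- function(arr, offsets)
  .morph_minmax(.morph_minmax(arr, offsets, TRUE), offsets, FALSE)

#' Multi-scale white and black top-hat maps
#'
#' For every scale `s` (ball structuring element of radius `s` voxels) the
#' white top-hat `I - open(I)` enhances bright blobs and the black top-hat
#' `close(I) - I` dark blobs. Per-scale responses are multiplied by
#' `s^tophat_scale_power` and aggregated with a voxel-wise maximum; the
#' combined map is the voxel-wise maximum of the two polarities. All three
#' aggregated maps are percentile-clipped.
#'
#' @param v a [new_volume()].
#' @param cfg a [feature_config()].
#' @return A list of [new_volume()]s: `white_max`, `black_max`, `combined`.
#' @export
tophat_multiscale <- function(v, cfg = feature_config()) {
  validate_volume(v)
  stopifnot(inherits(cfg, "feature_config"))
  white <- array(-Inf, dim = dim(v$data))
  black <- array(-Inf, dim = dim(v$data))
  for (s in cfg$scales) {
    off <- ball_offsets(s)
    w <- (v$data - grey_open(v$data, off)) * s^cfg$tophat_scale_power
    b <- (grey_close(v$data, off) - v$data) * s^cfg$tophat_scale_power
    white <- pmax(white, w)
    black <- pmax(black, b)
  }
  combined <- pmax(white, black)
  list(white_max = with_data(v, percentile_clip(white, cfg$clip_percentiles)),
       black_max = with_data(v, percentile_clip(black, cfg$clip_percentiles)),
       combined = with_data(v, percentile_clip(combined, cfg$clip_percentiles)))
}

#' Assemble the four-channel feature stack
#'
#' Stacks, in fixed order, the normalized density, the Sobel gradient
#' magnitude, the combined top-hat map and the DoG blobness map into a
#' channel-first array of shape `(4, nx, ny, nz)` sharing the volume's
#' spatial metadata. For a 64-voxel window this is the `(4, 64, 64, 64)`
#' network input.
#'
#' @param v_norm a percentile-normalized density [new_volume()].
#' @param cfg a [feature_config()].
#' @return An object of class `feature_stack` with fields `data` (4D array),
#'   `voxel_size`, `origin`, `axis_map`.
#' @export
build_feature_stack <- function(v_norm, cfg = feature_config()) {
  validate_volume(v_norm)
  gm <- sobel_gradient_magnitude(v_norm)
  th <- tophat_multiscale(v_norm, cfg)
  dg <- dog_max(v_norm, cfg)
  d <- dim(v_norm$data)
  channels <- list(v_norm$data, gm$data, th$combined$data, dg$data)
  if (!all(vapply(channels, function(x) identical(dim(x), d), logical(1))))
    stop("internal error: feature channel shape mismatch")
  stack <- array(0, dim = c(4L, d))
  for (c in 1:4) stack[c, , , ] <- channels[[c]]
  structure(list(data = stack, voxel_size = v_norm$voxel_size,
                 origin = v_norm$origin, axis_map = v_norm$axis_map),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<feature_stack> %d channels, %d x %d x %d voxels\n",
              d[1], d[2], d[3], d[4]))
  cat("  channels: [normalized, gradient magnitude, top-hat, DoG-max]\n")
  invisible(x)
}
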