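# Synthetic tomogram simulator.
#
# Generates density volumes with particles of known size classes at known
# centroids, the matching occupancy mask, and the ground-truth coordinate
# table, so the whole pipeline is testable without external data. Particle
# kernels default to solid spheres, which makes the occupancy-mask semantics
# exact: the mask labels precisely the voxels within each particle's radius.
# Noise is additive Gaussian; the default sigma equals the particle amplitude
# (power SNR ~ 1, an easy regime for smoke tests); sigma ~ 3.2 x amplitude
# gives the hard power-SNR ~ 0.1 regime typical of real tomograms. An
# optional missing-wedge filter emulates the anisotropic resolution loss of
# limited-tilt reconstruction.

#' Simulation configuration
#'
#' @param shape volume dimensions in voxels (length 3).
#' @param voxel_size Angstrom per voxel.
#' @param classes data.frame with columns `class_id`, `radius` (voxels),
#'   `amplitude`, `count`. Default: two size classes (radius 3 and 5).
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#'   The default 1 equals the default amplitude (power SNR ~ 1).
#' @param min_distance minimum pairwise centre distance in voxels; default
#'   twice the largest radius plus 2.
#' @param kernel `"sphere"` (solid, matches the mask exactly) or
#'   `"gaussian"` (soft profile with sd = radius/2, harder contrast).
#' @param missing_wedge optional half-angle in degrees; if set, the density
#'   is passed through [apply_missing_wedge()].
#' @param seed integer seed fixing the full generation.
#' @param max_attempts rejection-sampling budget per particle.
#' @param centres optional data.frame with columns `class_id`, `x`, `y`, `z`
#'   (0-based voxel coordinates) pinning particle positions explicitly; when
#'   given, placement sampling is skipped and `count` is ignored.
#' @return A `sim_config` list.
#' @export
sim_config <- function(shape = c(64, 64, 64), voxel_size = 1,
                       classes = data.frame(class_id = c(1L, 2L),
                                            radius = c(3, 5),
                                            amplitude = c(1, 1),
                                            count = c(6L, 4L)),
                       noise_sigma = 1, min_distance = NULL,
                       kernel = c("sphere", "gaussian"),
                       missing_wedge = NULL, seed = 1L,
                       max_attempts = 2000L, centres = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(all(c("class_id", "radius", "amplitude", "count") %in%
                  names(classes)))
  if (any(classes$radius <= 0)) stop("radii must be positive")
  if (any(classes$count < 0)) stop("counts must be non-negative")
  if (any(classes$class_id < 1)) stop("class ids must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (is.null(min_distance))
    min_distance <- 2 * max(classes$radius) + 2
  if (min_distance < 0) stop("min_distance must be non-negative")
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 classes = classes, noise_sigma = noise_sigma,
                 min_distance = min_distance, kernel = kernel,
                 missing_wedge = missing_wedge, seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts), centres = centres),
            class = "sim_config")
}

#' Simulate a tomogram with known ground truth
#'
#' Places particles by rejection sampling under the minimum-distance
#' constraint (class order, then particle order, is deterministic given the
#' seed), renders the density as the sum of particle kernels plus Gaussian
#' noise, labels the occupancy mask with each particle's class id, and
#' returns the planted centres. The same seed reproduces the outputs
#' bit-identically; the caller's RNG state is left untouched.
#'
#' @param cfg a [sim_config()].
#' @return A list: `density` ([new_volume()]), `mask` (label volume),
#'   `truth` (particle table, 0-based voxel coordinates).
#' @export
simulate_tomogram <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed)

  d <- cfg$shape
  density <- array(0, dim = d)
  mask <- array(0L, dim = d)
  centres <- matrix(numeric(0), ncol = 3)
  rows <- list()

  render <- function(c0, cls) {
    r <- cls$radius
    lo <- pmax(1L, as.integer(floor(c0 - r)))
    hi <- pmin(d, as.integer(ceiling(c0 + r)) + 2L)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    dist2 <- outer(outer((xs - 1 - c0[1])^2, (ys - 1 - c0[2])^2, `+`),
                   (zs - 1 - c0[3])^2, `+`)
    inside <- dist2 <= r^2
    contrib <- if (cfg$kernel == "sphere") cls$amplitude * inside
               else cls$amplitude * exp(-dist2 / (2 * (r / 2)^2))
    density[xs, ys, zs] <<- density[xs, ys, zs] + contrib
    sub <- mask[xs, ys, zs]
    sub[inside] <- as.integer(cls$class_id)
    mask[xs, ys, zs] <<- sub
  }

  if (!is.null(cfg$centres)) {
    for (ri in seq_len(nrow(cfg$centres))) {
      row <- cfg$centres[ri, ]
      cls <- cfg$classes[match(row$class_id, cfg$classes$class_id), ]
      if (is.na(cls$class_id))
        stop("pinned centre references unknown class ", row$class_id)
      c0 <- c(row$x, row$y, row$z)
      render(c0, cls)
      rows[[length(rows) + 1L]] <-
        data.frame(class_id = as.integer(row$class_id),
                   x = c0[1], y = c0[2], z = c0[3])
    }
  } else {
    for (ci in seq_len(nrow(cfg$classes))) {
      cls <- cfg$classes[ci, ]
      r <- cls$radius
      for (p in seq_len(cls$count)) {
        placed <- FALSE
        for (att in seq_len(cfg$max_attempts)) {
          c0 <- vapply(1:3, function(a)
            stats::runif(1, r + 1, d[a] - r - 2), numeric(1))
          if (nrow(centres) == 0 ||
              min(sqrt(rowSums(sweep(centres, 2, c0)^2))) >= cfg$min_distance) {
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place particle ", p, " of class ", cls$class_id,
               " within ", cfg$max_attempts, " attempts")
        centres <- rbind(centres, c0)
        render(c0, cls)
        rows[[length(rows) + 1L]] <-
          data.frame(class_id = as.integer(cls$class_id),
                     x = c0[1], y = c0[2], z = c0[3])
      }
    }
  }

  if (cfg$noise_sigma > 0)
    density <- density + stats::rnorm(length(density), 0, cfg$noise_sigma)
  dim(density) <- d

  truth <- if (length(rows) > 0) do.call(rbind, rows) else particle_table()
  rownames(truth) <- NULL
  vol <- new_volume(density, voxel_size = cfg$voxel_size)
  if (!is.null(cfg$missing_wedge))
    vol <- apply_missing_wedge(vol, cfg$missing_wedge)
  list(density = vol,
       mask = new_volume(mask, voxel_size = cfg$voxel_size),
       truth = validate_particles(truth))
}

#' Apply a missing-wedge filter in Fourier space
#'
#' Zeroes Fourier coefficients whose wave vector makes an angle larger than
#' `half_angle` with the x-y plane (measured toward the z axis, about a tilt
#' axis along y), emulating the unsampled wedge of limited-tilt tomography.
#' The filter is symmetric under k -> -k, so the output is real; energy never
#' increases, and a symmetric blob becomes elongated along z.
#'
#' @param v a [new_volume()].
#' @param half_angle wedge half-angle in degrees, in (0, 90]; at exactly 90
#'   no direction is unsampled and the volume passes through unchanged.
#' @return The filtered [new_volume()].
#' @export
apply_missing_wedge <- function(v, half_angle) {
  validate_volume(v)
  if (!is.numeric(half_angle) || half_angle <= 0 || half_angle > 90)
    stop("half_angle must be in (0, 90] degrees")
  d <- dim(v$data)
  f <- stats::fft(v$data)
  freq <- function(n) {
    k <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1))
    if (n == 1) 0 else k[seq_len(n)]
  }
  kx <- freq(d[1]); kz <- freq(d[3])
  # angle from the x-y plane toward z, rotation about the y tilt axis
  ang <- atan2(abs(rep(kz, each = d[1])), abs(rep(kx, times = d[3]))) * 180 / pi
  wedge_xz <- matrix(ang > half_angle, nrow = d[1])   # |angle| beyond the tilt range
  wedge_xz[1, 1] <- FALSE                             # keep the DC term
  keep <- array(TRUE, dim = d)
  for (j in seq_len(d[2])) keep[, j, ] <- !wedge_xz
  f[!keep] <- 0
  out <- Re(stats::fft(f, inverse = TRUE)) / prod(d)
  with_data(v, array(out, dim = d))
}
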