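# Context-padded subvolume gridding.
#
# A volume is tiled by disjoint core regions of `core` voxels per axis; each
# training/inference window extends the core by `pad` voxels of context on
# every face, so the window edge length is core + 2*pad (64 with the 48/8
# defaults). Windows are filled with zeros where they exit the volume. At
# stitch time only the core region of each window is written back, which makes
# the split/stitch round trip write-once and exact.

#' Grid specification
#'
#' @param core core region edge length in voxels (default 48).
#' @param pad context padding per face in voxels (default 8).
#' @param check_downscale if `TRUE`, require the window size to be divisible
#'   by 16 so it survives the segmentation network's four halving stages.
#' @return A list with `core`, `pad` and derived `window`.
#' @export
grid_spec <- function(core = 48L, pad = 8L, check_downscale = TRUE) {
  core <- as.integer(core); pad <- as.integer(pad)
  if (core <= 0L) stop("core must be positive")
  if (pad < 0L) stop("pad must be non-negative")
  window <- core + 2L * pad
  if (check_downscale && window %% 16L != 0L)
    stop("window (core + 2*pad = ", window, ") must be divisible by 16")
  list(core = core, pad = pad, window = window)
}

#' Grid bundle constructor
#'
#' One window of a gridded volume (or feature stack) plus the placement
#' metadata needed for exact stitching.
#'
#' @param grid 3D array `(w,w,w)` or 4D channel-first array `(C,w,w,w)`.
#' @param placement integer 0-based voxel offsets `(i,j,k)` of the core region
#'   in the source volume.
#' @param extents effective in-volume core sizes `(di,dj,dk)`.
#' @param pad context margin in voxels.
#' @param source_shape dimensions of the source volume.
#' @param voxel_size,origin,axis_map spatial metadata copied from the source.
#' @return An object of class `grid_bundle`.
#' @export
new_grid_bundle <- function(grid, placement, extents, pad, source_shape,
                            voxel_size = c(1, 1, 1), origin = c(0, 0, 0),
                            axis_map = c(1L, 2L, 3L)) {
  d <- dim(grid)
  sp <- if (length(d) == 4L) d[2:4] else d
  if (length(sp) != 3L || length(unique(sp)) != 1L)
    stop("grid spatial shape must be cubic (w,w,w)")
  placement <- as.integer(placement); extents <- as.integer(extents)
  pad <- as.integer(pad); source_shape <- as.integer(source_shape)
  if (any(placement < 0L)) stop("placement must be non-negative")
  if (any(placement + extents > source_shape))
    stop("placement + extents exceed source shape")
  if (any(pad + extents > sp[1]))
    stop("pad + extents exceed the window size")
  structure(list(grid = grid, placement = placement, extents = extents,
                 pad = pad, source_shape = source_shape,
                 voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin),
                 axis_map = as.integer(axis_map)),
            class = "grid_bundle")
}

#' @export
print.grid_bundle <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<grid_bundle> window %s at (%d,%d,%d), extents (%d,%d,%d), pad %d\n",
              paste(d, collapse = "x"),
              x$placement[1], x$placement[2], x$placement[3],
              x$extents[1], x$extents[2], x$extents[3], x$pad))
  invisible(x)
}

# Extract window [lo, lo+w) per axis from a 3D array, zero outside.
extract_window <- function(data, lo, w) {
  out <- array(0, dim = c(w, w, w))
  d <- dim(data)
  src_lo <- pmax(lo, 0L)
  src_hi <- pmin(lo + w, d)            # exclusive
  if (all(src_hi > src_lo)) {
    dst_lo <- src_lo - lo
    out[(dst_lo[1] + 1L):(dst_lo[1] + src_hi[1] - src_lo[1]),
        (dst_lo[2] + 1L):(dst_lo[2] + src_hi[2] - src_lo[2]),
        (dst_lo[3] + 1L):(dst_lo[3] + src_hi[3] - src_lo[3])] <-
      data[(src_lo[1] + 1L):src_hi[1],
           (src_lo[2] + 1L):src_hi[2],
           (src_lo[3] + 1L):src_hi[3]]
  }
  out
}

#' Split a volume or feature stack into grid bundles
#'
#' Tiles the volume with disjoint `core`-sized regions (the last tile per axis
#' may be truncated at the boundary) and extracts the padded window around
#' each. The number of bundles is `prod(ceiling(dim / core))`.
#'
#' @param v a [new_volume()] object or a [build_feature_stack()] result.
#' @param spec a [grid_spec()].
#' @return A list of `grid_bundle` objects.
#' @export
split_volume <- function(v, spec = grid_spec()) {
  is_stack <- inherits(v, "feature_stack")
  data <- if (is_stack) v$data else v$data
  d <- if (is_stack) dim(data)[2:4] else dim(data)
  core <- spec$core; pad <- spec$pad; w <- spec$window
  starts <- lapply(d, function(n) seq.int(0L, n - 1L, by = core))
  channels <- if (is_stack)
    lapply(seq_len(dim(data)[1]), function(c) array(data[c, , , ], dim = d))
  bundles <- list()
  for (k0 in starts[[3]]) for (j0 in starts[[2]]) for (i0 in starts[[1]]) {
    placement <- c(i0, j0, k0)
    extents <- pmin(core, d - placement)
    lo <- placement - pad
    if (is_stack) {
      C <- dim(data)[1]
      grid <- array(0, dim = c(C, w, w, w))
      for (c in seq_len(C))
        grid[c, , , ] <- extract_window(channels[[c]], lo, w)
    } else {
      grid <- extract_window(data, lo, w)
    }
    bundles[[length(bundles) + 1L]] <- new_grid_bundle(
      grid, placement, extents, pad, d,
      voxel_size = v$voxel_size, origin = v$origin, axis_map = v$axis_map)
  }
  bundles
}

#' Filter background-only training windows
#'
#' Keeps only input/mask window pairs whose mask window contains at least one
#' non-zero voxel. Intended for training set construction only; inference must
#' cover the full volume.
#'
#' @param inputs list of input `grid_bundle`s (density or feature windows).
#' @param masks list of label `grid_bundle`s paired with `inputs` by position.
#' @return A list with filtered `inputs` and `masks`.
#' @export
filter_nonzero <- function(inputs, masks) {
  if (length(inputs) != length(masks))
    stop("inputs and masks must have the same length")
  keep <- logical(length(inputs))
  for (n in seq_along(inputs)) {
    if (!identical(inputs[[n]]$placement, masks[[n]]$placement))
      stop("unpaired bundles: placement mismatch at position ", n)
    keep[n] <- max(masks[[n]]$grid) > 0
  }
  list(inputs = inputs[keep], masks = masks[keep])
}

#' Stitch grid bundles back into a full volume
#'
#' Writes only the central (non-padded, in-volume) core region of every window
#' into the output, so each output voxel is written exactly once. Errors if the
#' bundles do not tile the source shape disjointly.
#'
#' @param bundles list of `grid_bundle`s holding 3D grids (e.g. predictions).
#' @return A [new_volume()] with the bundles' source shape and metadata.
#' @export
stitch <- function(bundles) {
  if (length(bundles) == 0) stop("no bundles to stitch")
  shape <- bundles[[1]]$source_shape
  out <- array(0, dim = shape)
  seen <- array(FALSE, dim = shape)
  for (b in bundles) {
    if (!identical(b$source_shape, shape))
      stop("bundles disagree on source shape")
    if (length(dim(b$grid)) != 3L)
      stop("stitch expects 3D (single-channel) grids")
    p <- b$placement; e <- b$extents; pad <- b$pad
    ix <- (p[1] + 1L):(p[1] + e[1])
    iy <- (p[2] + 1L):(p[2] + e[2])
    iz <- (p[3] + 1L):(p[3] + e[3])
    if (any(seen[ix, iy, iz]))
      stop("overlapping core regions while stitching")
    out[ix, iy, iz] <- b$grid[(pad + 1L):(pad + e[1]),
                              (pad + 1L):(pad + e[2]),
                              (pad + 1L):(pad + e[3])]
    seen[ix, iy, iz] <- TRUE
  }
  if (!all(seen)) stop("bundles do not cover the full source shape")
  b1 <- bundles[[1]]
  new_volume(out, voxel_size = b1$voxel_size, origin = b1$origin,
             axis_map = b1$axis_map)
}

#' Save or load a grid bundle
#'
#' Bundles are stored as a gzip-compressed archive of named arrays with fixed
#' field names (`grid, i, j, k, di, dj, dk, pad, source_shape, voxel_size,
#' origin, axis_map`); the round trip is exact.
#'
#' @param b a `grid_bundle`.
#' @param path file path (conventionally `.rds`).
#' @return `save_bundle` returns `invisible(path)`; `load_bundle` the bundle.
#' @export
save_bundle <- function(b, path) {
  stopifnot(inherits(b, "grid_bundle"))
  saveRDS(list(grid = b$grid,
               i = b$placement[1], j = b$placement[2], k = b$placement[3],
               di = b$extents[1], dj = b$extents[2], dk = b$extents[3],
               pad = b$pad, source_shape = b$source_shape,
               voxel_size = b$voxel_size, origin = b$origin,
               axis_map = b$axis_map),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle file not found: ", path)
  x <- readRDS(path)
  required <- c("grid", "i", "j", "k", "di", "dj", "dk", "pad",
                "source_shape", "voxel_size", "origin", "axis_map")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    stop("bundle archive missing required fields: ",
         paste(missing, collapse = ", "))
  new_grid_bundle(x$grid, c(x$i, x$j, x$k), c(x$di, x$dj, x$dk), x$pad,
                  x$source_shape, x$voxel_size, x$origin, x$axis_map)
}
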