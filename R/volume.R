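#' Volume container for tomogram-scale 3D data
#'
#' A `tomo_volume` carries a 3D scalar array (density, labels, features or
#' predictions) together with the spatial metadata needed to write it back to
#' MRC without information loss: the voxel size in Angstrom along x/y/z, the
#' real-space origin in Angstrom, and the axis permutation recorded in the MRC
#' header (column/row/section axes). In memory the data are always held in
#' canonical order: an R array indexed `[x, y, z]` with x varying fastest, the
#' natural layout for both R and the MRC column convention. The axis map is
#' applied only at the I/O boundary.
#'
#' @param data 3D numeric array.
#' @param voxel_size numeric length-3, Angstrom per voxel along x, y, z. A
#'   scalar is recycled.
#' @param origin numeric length-3, Angstrom.
#' @param axis_map integer permutation of 1:3 giving the MRC column, row and
#'   section axes (1 = x, 2 = y, 3 = z). The canonical identity is `c(1,2,3)`.
#' @return An object of class `tomo_volume`.
#' @export
new_volume <- function(data, voxel_size = c(1, 1, 1), origin = c(0, 0, 0),
                       axis_map = c(1L, 2L, 3L)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  v <- structure(
    list(data = data,
         voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin),
         axis_map = as.integer(axis_map)),
    class = "tomo_volume")
  validate_volume(v)
}

validate_volume <- function(v) {
  stopifnot(inherits(v, "tomo_volume"))
  if (length(v$voxel_size) != 3L || any(!is.finite(v$voxel_size)) ||
      any(v$voxel_size <= 0))
    stop("voxel_size must be three positive finite values")
  if (length(v$origin) != 3L || any(!is.finite(v$origin)))
    stop("origin must be three finite values")
  if (!identical(sort(v$axis_map), 1:3))
    stop("axis_map must be a permutation of 1:3")
  d <- dim(v$data)
  if (length(d) != 3L || any(d < 1L))
    stop("data must have three positive dimensions")
  if (anyNA(v$data) || any(!is.finite(v$data)))
    stop("volume data contain non-finite values")
  v
}

#' @export
print.tomo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tomo_volume> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel size: %.4g x %.4g x %.4g A\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin: (%.4g, %.4g, %.4g) A; axis map: (%d,%d,%d)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$axis_map[1], x$axis_map[2], x$axis_map[3]))
  cat(sprintf("  range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname new_volume
#' @param x object to test.
#' @export
is_volume <- function(x) inherits(x, "tomo_volume")

# Clone a volume with new data but identical spatial metadata.
with_data <- function(v, data) {
  v$data <- data
  v
}
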