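# Tomogram standardization and label construction.
#
# Heterogeneous sources are brought to a common footing by (i) trilinear
# resampling to an isotropic target voxel size, (ii) percentile scaling with
# clipping into [0,1], (iii) dataset-specific z-offset correction of centroid
# annotations, and (iv) remapping per-dataset class ids into a unified id
# space while preserving the original occupancy (segmented shape) of every
# instance — no synthetic spheres are ever painted around centroids.

#' Resample a volume to an isotropic voxel size
#'
#' Trilinear interpolation in physical coordinates. Each output dimension is
#' `round(input_dim * input_voxel / target)`; sampling positions outside the
#' source grid are clamped to the edge so no artificial zeros enter at the
#' borders. A volume already at the target spacing is returned unchanged.
#'
#' @param v a [new_volume()] object.
#' @param target target voxel edge length in Angstrom.
#' @return A resampled [new_volume()] with voxel size `(target,target,target)`
#'   and the origin preserved.
#' @export
resample_isotropic <- function(v, target = 1) {
  validate_volume(v)
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("target voxel size must be a positive number")
  if (all(v$voxel_size == target)) {
    v$voxel_size <- rep(as.numeric(target), 3L)
    return(v)
  }
  d <- dim(v$data)
  out_dim <- pmax(1L, as.integer(round(d * v$voxel_size / target)))
  # fractional source indices of output voxel centres (0-based index space)
  src <- lapply(1:3, function(a)
    (seq_len(out_dim[a]) - 1) * target / v$voxel_size[a])
  data <- .trilinear_gather(v$data, src[[1]], src[[2]], src[[3]])
  new_volume(data, voxel_size = rep(as.numeric(target), 3L),
             origin = v$origin, axis_map = v$axis_map)
}

#' Percentile normalization with clipping
#'
#' Scales a density volume by its p-th percentile and clips into `[0, 1]`:
#' `V' = clip(V / p95(V), 0, 1)` for the default p = 95. The percentile is
#' computed over all finite voxels by default; set `nonzero_only = TRUE` to
#' restrict it to non-zero voxels (useful when reconstructions carry zero
#' padding slabs, or for noise-free synthetic volumes whose background is
#' exactly zero).
#'
#' @param v a [new_volume()] density volume.
#' @param percentile percentile in (0, 100], default 95.
#' @param nonzero_only compute the percentile over non-zero voxels only.
#' @return The normalized volume, values in `[0, 1]`.
#' @export
percentile_normalize <- function(v, percentile = 95, nonzero_only = FALSE) {
  validate_volume(v)
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]")
  x <- as.vector(v$data)
  if (nonzero_only) x <- x[x != 0]
  if (length(x) == 0)
    stop("degenerate input: no voxels available for the percentile")
  p <- as.numeric(stats::quantile(x, percentile / 100, names = FALSE))
  if (p <= 0)
    stop("degenerate input: percentile reference is non-positive (",
         signif(p, 4), ")")
  with_data(v, array(pmin(pmax(v$data / p, 0), 1), dim = dim(v$data)))
}

#' Dataset-specific coordinate offset rules
#'
#' Known z-offsets (in voxels) reconciling annotation and reconstruction
#' coordinate frames: the SHREC-style simulated sets centre a thinner ground
#' truth model inside the full reconstruction, so annotation slice 0 sits at a
#' positive reconstruction slice.
#'
#' @param extra named integer vector of additional `dataset = offset` entries.
#' @return Named numeric vector of z-offsets.
#' @export
offset_rule <- function(extra = NULL) {
  rule <- c(shrec2020 = 156, shrec2021 = 166, default = 0)
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))))
      stop("extra offsets must be named")
    rule <- c(extra, rule[setdiff(names(rule), names(extra))])
  }
  rule
}

#' Align particle coordinates to the reconstruction frame
#'
#' Adds the dataset's z-offset to every coordinate; x, y and class are
#' unchanged. Offsets are applied to coordinate tables only, never to masks.
#'
#' @param tab a particle table.
#' @param dataset dataset tag, must be present in `rule`.
#' @param rule named offset vector from [offset_rule()].
#' @return The shifted particle table.
#' @export
align_coordinates <- function(tab, dataset, rule = offset_rule()) {
  tab <- validate_particles(tab)
  key <- tolower(dataset)
  if (!key %in% names(rule))
    stop("unknown dataset tag '", dataset, "'; known: ",
         paste(names(rule), collapse = ", "))
  tab$z <- tab$z + rule[[key]]
  tab
}

#' Read a class-map file
#'
#' YAML (or JSON) file of the form `mapping: {orig_id: unified_id}` plus
#' `excluded: [ids]`, describing how a dataset's native class ids fold into
#' the unified id space. Excluded ids (vesicles, membranes, ...) map to
#' background.
#'
#' @param path YAML file path.
#' @return A list with integer-named `mapping` and integer `excluded`.
#' @export
read_class_map <- function(path) {
  if (!file.exists(path)) stop("class map file not found: ", path)
  y <- yaml::read_yaml(path)
  mapping <- y$mapping
  if (is.null(mapping)) stop("class map must contain a 'mapping' section")
  class_map(stats::setNames(as.integer(unlist(mapping)), names(mapping)),
            excluded = as.integer(unlist(y$excluded)))
}

#' Class-map constructor
#'
#' @param mapping named integer vector: names are original ids, values the
#'   unified ids (>= 0).
#' @param excluded integer vector of original ids dropped to background.
#' @return A `class_map` list.
#' @export
class_map <- function(mapping, excluded = integer()) {
  if (is.null(names(mapping))) stop("mapping must be named by original id")
  mapping <- stats::setNames(as.integer(mapping), names(mapping))
  if (any(mapping < 0L)) stop("unified ids must be >= 0")
  structure(list(mapping = mapping, excluded = as.integer(excluded)),
            class = "class_map")
}

#' Remap a multiclass label mask into the unified id space
#'
#' Replaces voxel values according to the class map; excluded ids become
#' background (0). The occupancy shape of every instance is untouched — this
#' is a pure per-voxel relabeling with no dilation, erosion or synthetic
#' geometry — and the spatial metadata are preserved.
#'
#' @param mask integer-valued label [new_volume()].
#' @param cm a [class_map()].
#' @return The remapped label volume.
#' @export
remap_class_mask <- function(mask, cm) {
  validate_volume(mask)
  stopifnot(inherits(cm, "class_map"))
  vals <- as.integer(mask$data)
  if (any(vals != mask$data)) stop("mask must be integer-valued")
  present <- sort(unique(vals))
  present <- present[present != 0L]
  known <- c(as.integer(names(cm$mapping)), cm$excluded)
  unmapped <- setdiff(present, known)
  if (length(unmapped) > 0)
    stop("unmapped class id(s) in mask: ", paste(unmapped, collapse = ", "))
  lut_keys <- c(0L, cm$excluded, as.integer(names(cm$mapping)))
  lut_vals <- c(0L, rep(0L, length(cm$excluded)), unname(cm$mapping))
  # match() takes the first hit, so excluded ids take precedence over mapping
  out <- lut_vals[match(vals, lut_keys)]
  with_data(mask, array(out, dim = dim(mask$data)))
}

#' Collapse a multiclass mask to a binary foreground mask
#'
#' All particle labels become 1; background stays 0. Excluded classes must
#' already have been removed by [remap_class_mask()].
#'
#' @param mask integer-valued label [new_volume()].
#' @return A `{0,1}` label volume.
#' @export
binarize_mask <- function(mask) {
  validate_volume(mask)
  with_data(mask, array(as.integer(mask$data > 0), dim = dim(mask$data)))
}
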