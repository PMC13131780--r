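# From dense label volumes to particle coordinates and detection scores.
#
# Per predicted class, connected components (18-connectivity by default: the
# 6 face plus 12 edge neighbours, corners excluded) are extracted, components
# below a minimum voxel count are discarded, and each surviving component
# contributes its unweighted voxel centroid as a particle coordinate.
# Predictions are scored against ground truth by optimal one-to-one Hungarian
# assignment of Euclidean distances under a cutoff d_max.

connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(o1 = -1:1, o2 = -1:1, o3 = -1:1))
  nz <- rowSums(g != 0)
  keep <- switch(as.character(connectivity),
                 `6` = nz == 1, `18` = nz >= 1 & nz <= 2, `26` = nz >= 1)
  g[keep, , drop = FALSE]
}

#' Connected components of a label volume
#'
#' @param labels integer-valued label [new_volume()] (0 = background).
#' @param connectivity 6 (faces), 18 (faces + edges, default) or 26 (all
#'   neighbours).
#' @return An object of class `component_set`: a data.frame with one row per
#'   component (`class_id`, `comp_id`, `size`, `x`, `y`, `z` — centroid in
#'   0-based voxel coordinates) plus the component id volume as attribute
#'   `label_map`.
#' @export
connected_components <- function(labels, connectivity = 18L) {
  validate_volume(labels)
  vals <- labels$data
  if (any(vals != round(vals)))
    stop("labels must be integer-valued")
  iv <- array(as.integer(round(vals)), dim = dim(vals))
  lab <- .label_components(iv, connectivity_offsets(as.integer(connectivity)))
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    out <- data.frame(class_id = integer(), comp_id = integer(),
                      size = integer(), x = numeric(), y = numeric(),
                      z = numeric())
  } else {
    d <- dim(lab)
    comp <- factor(lab[idx], levels = sort(unique(lab[idx])))
    cls <- iv[idx]
    i1 <- (idx - 1L) %% d[1]
    i2 <- ((idx - 1L) %/% d[1]) %% d[2]
    i3 <- (idx - 1L) %/% (d[1] * d[2])
    out <- data.frame(
      class_id = as.integer(tapply(cls, comp, function(v) v[1])),
      comp_id = as.integer(levels(comp)),
      size = as.integer(table(comp)),
      x = as.numeric(tapply(i1, comp, mean)),
      y = as.numeric(tapply(i2, comp, mean)),
      z = as.numeric(tapply(i3, comp, mean)))
    rownames(out) <- NULL
  }
  structure(out, label_map = lab, class = c("component_set", "data.frame"))
}

#' Remove components below a minimum size
#'
#' The boundary is inclusive: components with `size >= min_size` survive.
#'
#' @param cs a [connected_components()] result.
#' @param min_size minimum voxel count (default 5).
#' @return The filtered `component_set`.
#' @export
size_filter <- function(cs, min_size = 5L) {
  stopifnot(inherits(cs, "component_set"))
  if (min_size < 0) stop("min_size must be >= 0")
  keep <- cs$size >= min_size
  out <- cs[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label_map = attr(cs, "label_map"),
            class = c("component_set", "data.frame"))
}

#' Component centroids as a particle table
#'
#' @param cs a [connected_components()] (possibly [size_filter()]ed) result.
#' @return A particle table with one row per component, coordinates in
#'   0-based voxels.
#' @export
centroids <- function(cs) {
  stopifnot(inherits(cs, "component_set"))
  particle_table(class_id = cs$class_id, x = cs$x, y = cs$y, z = cs$z)
}

# Optimal one-to-one assignment on a cost matrix where entries above d_max
# were replaced by `invalid`. Returns data.frame(pred, gt, distance) of
# valid matched pairs.
match_points <- function(pm, gm, d_max, invalid) {
  np <- nrow(pm); ng <- nrow(gm)
  if (np == 0 || ng == 0)
    return(data.frame(pred = integer(), gt = integer(), distance = numeric()))
  D2 <- outer(rowSums(pm^2), rep(1, ng)) +
    outer(rep(1, np), rowSums(gm^2)) - 2 * pm %*% t(gm)
  D2[!is.finite(D2) | D2 < 0] <- 0
  D <- sqrt(D2)
  cost <- D
  cost[cost > d_max] <- invalid
  if (np <= ng) {
    assign <- .solve_assignment(cost)
    pairs <- data.frame(pred = seq_len(np), gt = assign)
  } else {
    assign <- .solve_assignment(t(cost))
    pairs <- data.frame(pred = assign, gt = seq_len(ng))
  }
  # exact per-pair distances (the outer-product form carries rounding dust)
  pairs$distance <- sqrt(rowSums((pm[pairs$pred, , drop = FALSE] -
                                    gm[pairs$gt, , drop = FALSE])^2))
  pairs[pairs$distance <= d_max, , drop = FALSE]
}

#' Hungarian matching of predicted and ground-truth particles
#'
#' Builds the Euclidean distance matrix, invalidates entries above `d_max`
#' (set to `1e6 * d_max`), solves the optimal one-to-one assignment, and
#' counts pairs within `d_max` as true positives. With `per_class = TRUE`
#' matching is restricted to equal class ids (multiclass evaluation);
#' otherwise coordinates are pooled (binary evaluation).
#'
#' @param pred,gt particle tables.
#' @param d_max distance cutoff in voxels (default 5).
#' @param per_class match within classes instead of pooled.
#' @return An object of class `match_result`: list with `tp`, `fp`, `fn`,
#'   `matched_pairs` (data.frame pred/gt/distance), `precision`, `recall`,
#'   `f1`, `miss_rate`, `ad` (mean matched distance; `NA` when tp = 0) and
#'   `mh` (multiple hits, structurally 0 under one-to-one assignment).
#' @export
hungarian_match <- function(pred, gt, d_max = 5, per_class = FALSE) {
  pred <- validate_particles(pred)
  gt <- validate_particles(gt)
  if (d_max <= 0) stop("d_max must be positive")
  invalid <- 1e6 * d_max
  pm_all <- as.matrix(pred[c("x", "y", "z")])
  gm_all <- as.matrix(gt[c("x", "y", "z")])
  if (per_class) {
    pairs <- data.frame(pred = integer(), gt = integer(), distance = numeric())
    for (cls in sort(unique(c(pred$class_id, gt$class_id)))) {
      pi <- which(pred$class_id == cls)
      gi <- which(gt$class_id == cls)
      sub <- match_points(pm_all[pi, , drop = FALSE],
                          gm_all[gi, , drop = FALSE], d_max, invalid)
      if (nrow(sub) > 0)
        pairs <- rbind(pairs, data.frame(pred = pi[sub$pred], gt = gi[sub$gt],
                                         distance = sub$distance))
    }
  } else {
    pairs <- match_points(pm_all, gm_all, d_max, invalid)
  }
  tp <- nrow(pairs)
  fp <- nrow(pred) - tp
  fn <- nrow(gt) - tp
  m <- metrics_from_counts(tp, fp, fn)
  structure(list(tp = tp, fp = fp, fn = fn, matched_pairs = pairs,
                 precision = m$precision, recall = m$recall, f1 = m$f1,
                 miss_rate = m$miss_rate,
                 ad = if (tp > 0) mean(pairs$distance) else NA_real_,
                 mh = 0L),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  AD %.3f voxels\n",
              x$precision, x$recall, x$f1, x$ad))
  invisible(x)
}

#' Detection metrics from raw counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `f1 = 2PR/(P+R)`,
#' `miss_rate = 1 - recall`. Undefined ratios (zero denominators) are
#' reported as `NA`, never as 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return A list with `precision`, `recall`, `f1`, `miss_rate`.
#' @export
metrics_from_counts <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       miss_rate = if (!is.na(recall)) 1 - recall else NA_real_)
}
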