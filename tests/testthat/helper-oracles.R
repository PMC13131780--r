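# Independent reference implementations used as oracles. These deliberately
# use brute-force formulations (dense convolution, flood fill, exhaustive
# assignment enumeration) that share no code with the package internals.

# Dense 3D Gaussian convolution with replicate boundary, via the full outer
# product kernel and explicit looping over kernel taps.
oracle_gaussian <- function(arr, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k1 <- exp(-x^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k3 <- outer(outer(k1, k1), k1)
  d <- dim(arr)
  out <- array(0, d)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  for (a in seq_along(x)) for (b in seq_along(x)) for (c in seq_along(x)) {
    w <- k3[a, b, c]
    if (w == 0) next
    out <- out + w * arr[clamp(seq_len(d[1]) + x[a], d[1]),
                         clamp(seq_len(d[2]) + x[b], d[2]),
                         clamp(seq_len(d[3]) + x[c], d[3])]
  }
  out
}

# Flood-fill connected components on an integer array; same-value neighbours
# under the given connectivity are merged. Returns an integer label array.
oracle_flood_fill <- function(vol, connectivity) {
  d <- dim(vol)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(offs != 0)
  offs <- offs[switch(as.character(connectivity),
                      `6` = nz == 1, `18` = nz >= 1 & nz <= 2,
                      `26` = nz >= 1), , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (vol[x, y, z] <= 0 || lab[x, y, z] != 0L) next
    cur <- cur + 1L
    queue <- list(c(x, y, z))
    lab[x, y, z] <- cur
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (q in seq_len(nrow(offs))) {
        n <- p + offs[q, ]
        if (any(n < 1) || any(n > d)) next
        if (lab[n[1], n[2], n[3]] == 0L &&
            vol[n[1], n[2], n[3]] == vol[p[1], p[2], p[3]]) {
          lab[n[1], n[2], n[3]] <- cur
          queue[[length(queue) + 1L]] <- n
        }
      }
    }
  }
  lab
}

# Canonicalize a component labeling to a comparable form: for each component,
# the sorted list of member voxel indices, sorted by first member.
canon_components <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0) return(list())
  sp <- unname(split(idx, lab[idx]))
  sp <- lapply(sp, sort)
  sp[order(vapply(sp, `[`, numeric(1), 1))]
}

# Exhaustive optimal one-to-one assignment under the invalidated-cost
# objective: enumerate all injective maps from the smaller point set into the
# larger, minimizing total cost with entries > d_max replaced by the large
# constant. Returns list(tp, total_distance) of the best assignment.
oracle_assignment <- function(pred, gt, d_max) {
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0 || ng == 0) return(list(tp = 0L, dist = 0))
  D <- as.matrix(stats::dist(rbind(pred, gt)))[seq_len(np),
                                               np + seq_len(ng), drop = FALSE]
  invalid <- 1e6 * d_max
  C <- ifelse(D > d_max, invalid, D)
  swap <- np > ng
  if (swap) C <- t(C)
  n <- nrow(C); m <- ncol(C)
  perms <- function(v, k) {
    if (k == 0) return(list(integer()))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i], k - 1))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best <- Inf; best_tp <- 0L; best_dist <- Inf
  for (asg in perms(seq_len(m), n)) {
    cost <- sum(C[cbind(seq_len(n), asg)])
    if (cost < best - 1e-12) {
      best <- cost
      valid <- C[cbind(seq_len(n), asg)] < invalid
      best_tp <- sum(valid)
      best_dist <- sum(C[cbind(seq_len(n), asg)][valid])
    }
  }
  list(tp = as.integer(best_tp), dist = best_dist)
}

# Number of lattice points within Euclidean distance r of the origin.
oracle_ball_count <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(-ri:ri, -ri:ri, -ri:ri)
  sum(g[[1]]^2 + g[[2]]^2 + g[[3]]^2 <= r^2)
}

# Shared reduced-scale simulation + feature extraction used by the training
# smoke tests: one 32^3 window per volume.
smoke_volume <- function(seed) {
  cfg <- sim_config(shape = c(32, 32, 32),
                    classes = data.frame(class_id = c(1L, 2L),
                                         radius = c(3, 5),
                                         amplitude = c(1, 1),
                                         count = c(2L, 1L)),
                    noise_sigma = 1, seed = seed)
  sim <- simulate_tomogram(cfg)
  vn <- percentile_normalize(sim$density)
  st <- build_feature_stack(vn)
  sp <- grid_spec(core = 32, pad = 0)
  list(x = split_volume(st, sp)[[1]],
       y = split_volume(binarize_mask(sim$mask), sp)[[1]],
       truth = sim$truth)
}
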