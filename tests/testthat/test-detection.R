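# Detection post-processing: component extraction under 6/18/26-connectivity
# (vs a flood-fill oracle), size filtering, centroids, Hungarian matching
# (vs exhaustive assignment), and the published metric arithmetic.

test_that("connectivity semantics distinguish face, edge and corner contact", {
  a <- array(0L, c(4, 4, 4))
  a[1, 1, 1] <- 1L; a[2, 1, 1] <- 1L            # face-adjacent
  cs <- connected_components(new_volume(a), 18)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$size, 2L)

  b <- array(0L, c(4, 4, 4))
  b[1, 1, 1] <- 1L; b[2, 2, 2] <- 1L            # corner-adjacent only
  expect_equal(nrow(connected_components(new_volume(b), 18)), 2)
  expect_equal(nrow(connected_components(new_volume(b), 26)), 1)
  expect_equal(nrow(connected_components(new_volume(b), 6)), 2)

  e <- array(0L, c(4, 4, 4))
  e[1, 1, 1] <- 1L; e[2, 2, 1] <- 1L            # edge-adjacent
  expect_equal(nrow(connected_components(new_volume(e), 6)), 2)
  expect_equal(nrow(connected_components(new_volume(e), 18)), 1)
})

test_that("components equal the flood-fill oracle on random label fixtures", {
  set.seed(30)
  for (rep in 1:100) {
    vol <- array(sample(0:2, 512, TRUE, prob = c(0.6, 0.25, 0.15)),
                 c(8, 8, 8))
    conn <- sample(c(6L, 18L, 26L), 1)
    cs <- connected_components(new_volume(vol), conn)
    got <- canon_components(attr(cs, "label_map"))
    want <- canon_components(oracle_flood_fill(vol, conn))
    expect_identical(got, want)
  }
})

test_that("size filtering is inclusive and monotone", {
  a <- array(0L, c(20, 20, 20))
  a[1, 1, 1] <- 1L                               # size 1
  a[5:9, 5, 5] <- 1L                             # size 5
  a[12:16, 12:16, 12:14] <- 2L                   # size 50 (wait: 5*5*2)
  a[12:16, 12:16, 16:17] <- 2L
  cs <- connected_components(new_volume(a), 18)
  expect_equal(nrow(size_filter(cs, 0)), nrow(cs))
  kept <- size_filter(cs, 5)
  expect_setequal(kept$size, setdiff(cs$size, 1L))
  counts <- vapply(0:60, function(m) nrow(size_filter(cs, m)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("centroids are unweighted voxel means in 0-based coordinates", {
  a <- array(0L, c(12, 12, 12))
  a[4, 5, 6] <- 1L                               # 0-based (3, 4, 5)
  cs <- connected_components(new_volume(a), 18)
  ct <- centroids(cs)
  expect_equal(unlist(ct[1, c("x", "y", "z")], use.names = FALSE), c(3, 4, 5))

  b <- array(0L, c(21, 21, 21))
  b[10:12, 10:12, 10:12] <- 2L                   # cube centred at (10,10,10)
  ct2 <- centroids(connected_components(new_volume(b), 18))
  expect_equal(unlist(ct2[1, c("x", "y", "z")], use.names = FALSE),
               c(10, 10, 10))

  # L-shaped component: voxels (0,0,0),(1,0,0),(2,0,0),(2,1,0) 0-based
  l <- array(0L, c(5, 5, 5))
  l[1, 1, 1] <- 1L; l[2, 1, 1] <- 1L; l[3, 1, 1] <- 1L; l[3, 2, 1] <- 1L
  ct3 <- centroids(connected_components(new_volume(l), 18))
  expect_equal(unlist(ct3[1, c("x", "y", "z")], use.names = FALSE),
               c(mean(c(0, 1, 2, 2)), mean(c(0, 0, 0, 1)), 0))
})

test_that("perfect and empty predictions give the degenerate match results", {
  set.seed(31)
  gt <- particle_table(rep(1L, 7), runif(7, 0, 50), runif(7, 0, 50),
                       runif(7, 0, 50))
  same <- hungarian_match(gt, gt, d_max = 5)
  expect_equal(same$tp, 7)
  expect_equal(same$fp, 0)
  expect_equal(same$fn, 0)
  expect_equal(same$precision, 1)
  expect_equal(same$recall, 1)
  expect_equal(same$f1, 1)
  expect_equal(same$ad, 0)

  none <- hungarian_match(particle_table(), gt, d_max = 5)
  expect_equal(none$tp, 0)
  expect_equal(none$fp, 0)
  expect_equal(none$fn, 7)
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
  expect_true(is.na(none$ad))
})

test_that("matching equals exhaustive assignment on all small instances", {
  set.seed(32)
  for (rep in 1:40) {
    np <- sample(0:6, 1); ng <- sample(0:6, 1)
    pred <- particle_table(rep(1L, np), runif(np, 0, 12), runif(np, 0, 12),
                           runif(np, 0, 12))
    gt <- particle_table(rep(1L, ng), runif(ng, 0, 12), runif(ng, 0, 12),
                         runif(ng, 0, 12))
    res <- hungarian_match(pred, gt, d_max = 5)
    orc <- oracle_assignment(as.matrix(pred[c("x", "y", "z")]),
                             as.matrix(gt[c("x", "y", "z")]), 5)
    expect_equal(res$tp, orc$tp)
    if (res$tp > 0)
      expect_equal(sum(res$matched_pairs$distance), orc$dist,
                   tolerance = 1e-9)
    # count identities
    expect_equal(res$tp + res$fp, np)
    expect_equal(res$tp + res$fn, ng)
    # symmetry: swapping roles swaps FP and FN, preserves TP and AD
    swp <- hungarian_match(gt, pred, d_max = 5)
    expect_equal(swp$tp, res$tp)
    expect_equal(swp$fp, res$fn)
    expect_equal(swp$fn, res$fp)
    expect_equal(swp$ad, res$ad, tolerance = 1e-9)
  }
})

test_that("jitter below half the cutoff keeps every point matched", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 8
    # well separated points so nearest neighbours stay unique
    base <- expand.grid(x = c(10, 30), y = c(10, 30), z = c(10, 30))
    gt <- particle_table(rep(1L, n), base$x, base$y, base$z)
    jit <- gt
    eps <- matrix(runif(3 * n, -1.4, 1.4), n)    # |jitter| < 2.5 = d_max/2
    jit$x <- jit$x + eps[, 1]; jit$y <- jit$y + eps[, 2]
    jit$z <- jit$z + eps[, 3]
    res <- hungarian_match(jit, gt, d_max = 5)
    expect_equal(res$tp, n)
  }
})

test_that("per-class matching never pairs across classes", {
  gt <- particle_table(c(1L, 2L), c(0, 0.5), c(0, 0), c(0, 0))
  pred <- particle_table(c(2L, 1L), c(0, 0.5), c(0, 0), c(0, 0))
  pooled <- hungarian_match(pred, gt, d_max = 5)
  expect_equal(pooled$tp, 2)
  perclass <- hungarian_match(pred, gt, d_max = 5, per_class = TRUE)
  expect_equal(perclass$tp, 2)           # still matchable within class
  far <- particle_table(c(2L, 1L), c(100, 100.5), c(0, 0), c(0, 0))
  expect_equal(hungarian_match(far, gt, d_max = 5, per_class = TRUE)$tp, 0)
})

test_that("metric arithmetic reproduces the published operating points", {
  m1 <- metrics_from_counts(1420, 14, 145)
  expect_equal(round(m1$precision, 3), 0.990)
  expect_equal(round(m1$recall, 3), 0.907)
  expect_equal(round(m1$f1, 3), 0.947)

  m2 <- metrics_from_counts(2622, 104, 160)
  expect_equal(round(m2$precision, 4), 0.9618)
  expect_equal(round(m2$recall, 4), 0.9425)
  expect_equal(round(m2$f1, 4), 0.9521)
  expect_equal(round(m2$miss_rate, 4), 0.0575)

  m3 <- metrics_from_counts(482, 68, 16)
  expect_equal(round(m3$precision, 3), 0.876)
  expect_equal(round(m3$recall, 3), 0.968)
  expect_equal(round(m3$f1, 2), 0.92)

  z <- metrics_from_counts(0, 0, 0)
  expect_true(is.na(z$precision) && is.na(z$recall) && is.na(z$f1) &&
              is.na(z$miss_rate))
})
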