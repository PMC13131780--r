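# Network building blocks: merging/expanding, window machinery, attention
# against a dense oracle, block/residual structure, loss and optimizer
# helpers, forward shape contracts, and gradient correctness by finite
# differences.

tiny_cfg <- function(K = 3, Cin = 2)
  swin3d_config(num_classes = K, in_channels = Cin, hidden_dim = 4,
                depths = c(2, 2, 2, 2), heads = c(1, 1, 2, 2), head_dim = 3,
                dropout = 0)

test_that("patch merging satisfies its shape and identity contracts", {
  set.seed(40)
  x <- array(rnorm(32 * 8^3), c(32, 8, 8, 8))
  C_out <- 48
  W <- matrix(rnorm(32 * 8 * C_out, sd = 0.1), 32 * 8, C_out)
  y <- patch_merge(x, W, rep(0, C_out), rep(1, C_out), rep(0, C_out))
  expect_equal(dim(y), c(C_out, 4, 4, 4))

  # block flatten is invertible: with an identity projection and no norm the
  # output tokens are exactly the flattened blocks
  xs <- array(rnorm(4 * 4^3), c(4, 4, 4, 4))
  Wi <- diag(4 * 8)
  ym <- patch_merge(xs, Wi, rep(0, 32), rep(1, 32), rep(0, 32),
                    normalize = FALSE)
  expect_equal(dim(ym), c(32, 2, 2, 2))
  # coarse voxel (1,1,1) collects the 2^3 block in raster order
  blk <- as.vector(vapply(0:7, function(s) {
    i <- s %% 2; j <- (s %/% 2) %% 2; k <- s %/% 4
    xs[, i + 1, j + 1, k + 1]
  }, numeric(4)))
  expect_equal(ym[, 1, 1, 1], blk)
  # un-flattening reproduces the input exactly
  back <- array(0, dim(xs))
  for (s in 0:7) {
    i <- s %% 2; j <- (s %/% 2) %% 2; k <- s %/% 4
    back[, i + 1, j + 1, k + 1] <- ym[s * 4 + 1:4, 1, 1, 1]
  }
  expect_equal(back[, 1:2, 1:2, 1:2], xs[, 1:2, 1:2, 1:2])

  expect_error(patch_merge(array(0, c(4, 5, 4, 4)), Wi, rep(0, 32),
                           rep(1, 32), rep(0, 32)), "divisible")
})

test_that("patch expansion mirrors merging in shape", {
  set.seed(41)
  C <- 16
  x <- array(rnorm(C * 4^3), c(C, 4, 4, 4))
  W <- matrix(rnorm(C * (C / 2) * 8, sd = 0.1), C, (C / 2) * 8)
  y <- patch_expand(x, W, rep(0, (C / 2) * 8), rep(1, C / 2), rep(0, C / 2))
  expect_equal(dim(y), c(C / 2, 8, 8, 8))
  # expand then merge restores the shape (not the values)
  W2 <- matrix(rnorm((C / 2) * 8 * C, sd = 0.1), (C / 2) * 8, C)
  z <- patch_merge(y, W2, rep(0, C), rep(1, C), rep(0, C))
  expect_equal(dim(z), dim(x))
})

test_that("window partition and reverse are exact inverses", {
  set.seed(42)
  for (win in list(c(2L, 2L, 2L), c(4L, 2L, 2L))) {
    x <- array(rnorm(5 * 4 * 4 * 4), c(5, 4, 4, 4))
    w <- window_partition(x, win)
    expect_equal(dim(w), c(prod(c(4, 4, 4) %/% win), prod(win), 5))
    expect_equal(window_reverse(w, win, c(4, 4, 4)), x)
  }
  # window equal to the full extent gives a single window
  x <- array(rnorm(3 * 2 * 2 * 2), c(3, 2, 2, 2))
  w <- window_partition(x, c(2L, 2L, 2L))
  expect_equal(dim(w)[1], 1)
})

test_that("relative position bias depends only on the token offset", {
  win <- c(2L, 2L, 2L)
  tab <- matrix(rnorm(27 * 2), 27, 2)
  B <- relative_position_bias(tab, win)
  expect_equal(dim(B), c(8, 8, 2))
  # exhaustive: equal offsets imply equal bias
  coords <- expand.grid(0:1, 0:1, 0:1)
  for (i in 1:8) for (j in 1:8) for (ii in 1:8) for (jj in 1:8) {
    if (all(coords[i, ] - coords[j, ] == coords[ii, ] - coords[jj, ]))
      expect_equal(B[i, j, ], B[ii, jj, ])
  }
  expect_true(all(relative_position_bias(matrix(0, 27, 2), win) == 0))
  expect_error(relative_position_bias(matrix(0, 25, 2), win), "rows")
})

test_that("window attention matches a dense brute-force computation", {
  set.seed(43)
  C <- 6; h <- 2; d <- 4; Tn <- 8; nw <- 4
  params <- list(Wqkv = matrix(rnorm(C * 3 * h * d, sd = 0.3), C, 3 * h * d),
                 bqkv = rnorm(3 * h * d, sd = 0.1),
                 Wo = matrix(rnorm(h * d * C, sd = 0.3), h * d, C),
                 bo = rnorm(C, sd = 0.1))
  tab <- matrix(rnorm(27 * h, sd = 0.2), 27, h)
  tok <- array(rnorm(nw * Tn * C), c(nw, Tn, C))
  got <- window_attention(tok, params, tab, c(2, 2, 2), h, d)

  B <- relative_position_bias(tab, c(2, 2, 2))
  for (w in seq_len(nw)) {
    X <- tok[w, , ]
    qkv <- X %*% params$Wqkv + matrix(params$bqkv, Tn, 3 * h * d, byrow = TRUE)
    O <- matrix(0, Tn, h * d)
    for (hh in seq_len(h)) {
      cq <- (hh - 1) * d + 1:d
      Q <- qkv[, cq]; K <- qkv[, h * d + cq]; V <- qkv[, 2 * h * d + cq]
      S <- Q %*% t(K) / sqrt(d) + B[, , hh]
      A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
      O[, cq] <- A %*% V
    }
    want <- O %*% params$Wo + matrix(params$bo, Tn, C, byrow = TRUE)
    expect_lt(max(abs(got[w, , ] - want)) / max(abs(want)), 1e-5)
  }
})

test_that("degenerate attention cases behave as softmax dictates", {
  set.seed(44)
  C <- 4; h <- 1; d <- 4
  params <- list(Wqkv = matrix(rnorm(C * 3 * d, sd = 0.4), C, 3 * d),
                 bqkv = rep(0, 3 * d),
                 Wo = diag(C), bo = rep(0, C))
  # single-token window: softmax over one logit is 1, output = V projection
  tok1 <- array(rnorm(2 * 1 * C), c(2, 1, C))
  got1 <- window_attention(tok1, params, matrix(0, 1, 1), c(1, 1, 1), h, d)
  v1 <- tok1[1, 1, ] %*% params$Wqkv
  expect_equal(got1[1, 1, ], as.vector(v1[, 2 * d + 1:d]), tolerance = 1e-10)

  # all-equal tokens, zero bias: uniform attention, output = mean of V
  tok2 <- array(rep(rnorm(C), each = 8), c(1, 8, C))
  got2 <- window_attention(tok2, params, matrix(0, 27, 1), c(2, 2, 2), h, d)
  v2 <- tok2[1, 1, ] %*% params$Wqkv
  for (t in 1:8)
    expect_equal(got2[1, t, ], as.vector(v2[, 2 * d + 1:d]), tolerance = 1e-10)
})

test_that("shifted-window masks match the wrap-around oracle", {
  # no shift: nothing masked
  m0 <- shifted_window_mask(c(4, 4, 4), c(2, 2, 2), c(0, 0, 0))
  expect_true(all(m0 == 0))

  # 1D analogue embedded in 3D: extent 4, window 2, shift 1 along x only
  m1 <- shifted_window_mask(c(4, 2, 2), c(2, 2, 2), c(1, 0, 0))
  # exactly the pairs wrapping x = 3 -> x = 0 are masked
  expect_true(any(m1 < 0))
  # brute force over original coordinates
  wi <- tomopick:::window_info(c(4, 2, 2), c(2, 2, 2), c(1, 0, 0))
  check_mask_oracle <- function(dims, window, shift) {
    wi <- tomopick:::window_info(dims, window, shift)
    N <- prod(dims)
    vox <- 0:(N - 1)
    cc <- cbind(vox %% dims[1], (vox %/% dims[1]) %% dims[2],
                vox %/% (dims[1] * dims[2]))
    s <- sweep(cc, 2, shift)
    s <- s %% matrix(dims, N, 3, byrow = TRUE)
    wid <- (s[, 1] %/% window[1]) +
      (dims[1] %/% window[1]) * ((s[, 2] %/% window[2]) +
      (dims[2] %/% window[2]) * (s[, 3] %/% window[3]))
    tid <- (s[, 1] %% window[1]) + window[1] * ((s[, 2] %% window[2]) +
      window[2] * (s[, 3] %% window[3]))
    mask <- if (is.null(wi$mask))
      array(0, c(max(wid) + 1, prod(window), prod(window))) else wi$mask
    for (w in sort(unique(wid))) {
      members <- which(wid == w)
      members <- members[order(tid[members])]
      co <- cc[members, , drop = FALSE]
      for (a in seq_along(members)) for (b in seq_along(members)) {
        # pair is genuinely adjacent iff not wrapped: along every axis the
        # original coordinates lie within one window span without crossing
        # the volume boundary through the cyclic shift
        wrapped <- any(abs(co[a, ] - co[b, ]) >= window)
        expect_equal(mask[w + 1, a, b] < 0, wrapped,
                     info = sprintf("dims=%s w=%d a=%d b=%d",
                                    paste(dims, collapse = ","), w, a, b))
      }
    }
  }
  check_mask_oracle(c(4, 2, 2), c(2, 2, 2), c(1, 0, 0))
  check_mask_oracle(c(4, 4, 4), c(2, 2, 2), c(1, 1, 1))
})

test_that("a swin block is shape-preserving and residual at zero weights", {
  set.seed(45)
  C <- 4
  p <- tomopick:::block_params(C, heads = 1, head_dim = 4, mlp_ratio = 4,
                               window = c(2L, 2L, 2L))
  x <- array(rnorm(C * 4^3), c(C, 4, 4, 4))
  y <- swin_block(x, p, c(2L, 2L, 2L), c(0L, 0L, 0L), heads = 1, head_dim = 4)
  expect_equal(dim(y), dim(x))
  ys <- swin_block(x, p, c(2L, 2L, 2L), c(1L, 1L, 1L), heads = 1,
                   head_dim = 4)
  expect_equal(dim(ys), dim(x))

  # zero attention-output and MLP-output weights: pure residual identity
  p0 <- p
  p0$Wo[] <- 0; p0$bo[] <- 0; p0$W2[] <- 0; p0$b2[] <- 0
  y0 <- swin_block(x, p0, c(2L, 2L, 2L), c(0L, 0L, 0L), heads = 1,
                   head_dim = 4)
  expect_equal(y0, x, tolerance = 1e-12)

  # MLP hidden width is mlp_ratio x C
  for (C2 in c(32, 64)) {
    pb <- tomopick:::block_params(C2, 2, 8, 4, c(2L, 2L, 2L))
    expect_equal(dim(pb$W1), c(C2, 4 * C2))
  }
})

test_that("skip fusion is symmetric and reduces to Norm at zero skip", {
  set.seed(46)
  C <- 6
  a <- array(rnorm(C * 8), c(C, 2, 2, 2))
  b <- array(rnorm(C * 8), c(C, 2, 2, 2))
  g <- runif(C, 0.5, 1.5); be <- rnorm(C)
  expect_equal(skip_fuse(a, b, g, be), skip_fuse(b, a, g, be))
  expect_equal(dim(skip_fuse(a, b, g, be)), dim(a))
  z <- array(0, dim(a))
  ref <- tomopick:::ln_fwd(tomopick:::tok_from_grid(a), g, be)$y
  expect_equal(skip_fuse(a, z, g, be),
               tomopick:::grid_from_tok(ref, c(2, 2, 2)))
  expect_error(skip_fuse(a, array(0, c(C, 4, 2, 2)), g, be), "matching")
})

test_that("the forward pass honours its shape contracts", {
  cfg <- tiny_cfg(K = 3, Cin = 2)
  m <- swin3d_model(cfg, seed = 5)
  x <- array(rnorm(2 * 32^3), c(2, 32, 32, 32))
  z <- swin3d_forward(m, x)
  expect_equal(dim(z), c(3, 32, 32, 32))
  # bottleneck reached 2^3 (four halvings of 32); probabilities normalize
  p <- tomopick:::softmax_rows(tomopick:::tok_from_grid(z))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  expect_error(swin3d_forward(m, array(0, c(2, 24, 24, 24))), "divisible")
})

test_that("a 64-voxel window with 13 classes yields (13, 64, 64, 64) logits", {
  cfg <- swin3d_config(num_classes = 13, in_channels = 4, hidden_dim = 8,
                       depths = c(2, 2, 2, 2), heads = c(1, 1, 1, 1),
                       head_dim = 8, dropout = 0)
  m <- swin3d_model(cfg, seed = 6)
  x <- array(rnorm(4 * 64^3), c(4, 64, 64, 64))
  z <- swin3d_forward(m, x)
  expect_equal(dim(z), c(13, 64, 64, 64))
})

test_that("relabeling class channels permutes the logits identically", {
  cfg <- tiny_cfg(K = 4, Cin = 2)
  m <- swin3d_model(cfg, seed = 7)
  x <- array(rnorm(2 * 32^3), c(2, 32, 32, 32))
  z <- swin3d_forward(m, x)
  perm <- c(3L, 1L, 4L, 2L)
  m2 <- m
  m2$params$final$head$W <- m$params$final$head$W[, perm]
  m2$params$final$head$b <- m$params$final$head$b[perm]
  z2 <- swin3d_forward(m2, x)
  expect_equal(z2, z[perm, , , ], tolerance = 1e-12)
})

test_that("weighted cross-entropy matches hand-evaluated cases", {
  z <- matrix(0, 2, 2)                     # probabilities (0.5, 0.5)
  expect_equal(weighted_cross_entropy(z, c(0L, 1L)), log(2))
  zt <- matrix(c(30, 0, 0, 30), 2, 2, byrow = TRUE)
  expect_lt(weighted_cross_entropy(zt, c(0L, 1L)), 1e-8)

  # doubling one class weight doubles that class's contribution (3 voxels)
  z3 <- matrix(rnorm(6), 3, 2)
  y3 <- c(0L, 1L, 1L)
  p <- exp(z3) / rowSums(exp(z3))
  hand <- function(w) mean(w[y3 + 1] * -log(p[cbind(1:3, y3 + 1)]))
  expect_equal(weighted_cross_entropy(z3, y3, c(1, 1)), hand(c(1, 1)))
  expect_equal(weighted_cross_entropy(z3, y3, c(1, 2)), hand(c(1, 2)))
  contrib1 <- hand(c(0, 1)); contrib2 <- hand(c(0, 2))
  expect_equal(contrib2, 2 * contrib1)

  expect_error(weighted_cross_entropy(z, c(0L, 2L)), "0..K-1")
})

test_that("class weights follow inverse frequency with guards", {
  expect_equal(class_weights_from_counts(c(50, 50)), c(1, 1))
  expect_equal(class_weights_from_counts(c(90, 10)), c(0.2, 1.8))
  w <- class_weights_from_counts(c(100, 0, 50))
  expect_true(all(is.finite(w)))
  expect_equal(mean(w), 1)
  expect_error(class_weights_from_counts(c(0, 0)), "degenerate")
})

test_that("gradient clipping rescales only above the threshold", {
  expect_equal(clip_gradients(c(0.3, 0.4), 1), c(0.3, 0.4))
  expect_equal(clip_gradients(c(3, 4), 1), c(0.6, 0.8))
  set.seed(47)
  g <- list(a = matrix(rnorm(20, sd = 3), 4), b = list(c = rnorm(5, sd = 3)))
  cl <- clip_gradients(g, 0.7)
  nrm <- sqrt(tomopick:::grad_reduce(cl, 0))
  expect_lte(nrm, 0.7 + 1e-12)
  # direction preserved: one global scale factor across all leaves
  ratio <- cl$a[1, 1] / g$a[1, 1]
  expect_equal(cl$a / g$a, array(ratio, dim(g$a)))
  expect_equal(cl$b$c / g$b$c, rep(ratio, 5))
})

test_that("prediction thresholds the posterior as specified", {
  expect_error(infer_config(1.1), "conf_threshold")
  # softmax of logits (0, 1, 2): (0.090, 0.245, 0.665)
  p <- exp(0:2) / sum(exp(0:2))
  expect_equal(round(p, 3), c(0.090, 0.245, 0.665))

  cfg <- tiny_cfg(K = 3, Cin = 2)
  m <- swin3d_model(cfg, seed = 8)
  # overwrite the head so logits are exactly (0, 1, 2) everywhere
  m$params$final$head$W[] <- 0
  m$params$final$head$b <- c(0, 1, 2)
  x <- array(rnorm(2 * 32^3), c(2, 32, 32, 32))
  lab07 <- predict_window(m, x, infer_config(0.7))
  expect_true(all(lab07 == 0))             # max posterior 0.665 < 0.7
  lab06 <- predict_window(m, x, infer_config(0.6))
  expect_true(all(lab06 == 2))
  lab0 <- predict_window(m, x, infer_config(0))
  expect_true(all(lab0 == 2))              # pure argmax
})

test_that("network gradients agree with finite differences", {
  cfg <- tiny_cfg(K = 3, Cin = 2)
  m <- swin3d_model(cfg, seed = 3)
  tp <- asNamespace("tomopick")
  dims <- c(32, 32, 32)
  set.seed(48)
  x <- array(rnorm(2 * prod(dims)), c(2, dims))
  y <- sample(0:2, prod(dims), TRUE)
  w <- c(0.5, 1.5, 1.0)
  tok <- tp$tok_from_grid(x)
  fw <- tp$net_fwd(m$params, cfg, tok, dims, m$env, training = FALSE)
  ce <- tp$ce_fwd(fw$logits, y, w)
  gr <- tp$net_bwd(m$params, cfg, tp$ce_bwd(ce), fw$cache)

  lossfun <- function(params)
    tp$ce_fwd(tp$net_fwd(params, cfg, tok, dims, m$env, FALSE)$logits, y,
              w)$loss
  get_at <- function(p, path) {
    for (k in path) {
      if (grepl("^[0-9]+$", k)) k <- as.integer(k)
      p <- p[[k]]
    }
    p
  }
  set_at <- function(p, path, val) {
    k <- path[1]
    if (grepl("^[0-9]+$", k)) k <- as.integer(k)
    if (length(path) == 1) { p[[k]] <- val; return(p) }
    p[[k]] <- set_at(p[[k]], path[-1], val)
    p
  }
  paths <- list()
  collect <- function(p, pre) {
    if (is.list(p)) {
      for (n in seq_along(p)) {
        nn <- if (!is.null(names(p))) names(p)[n] else as.character(n)
        collect(p[[n]], c(pre, nn))
      }
    } else paths[[length(paths) + 1]] <<- list(path = pre, n = length(p))
  }
  collect(m$params, character())
  set.seed(49)
  eps <- 1e-5
  for (si in sample(length(paths), 12)) {
    pth <- paths[[si]]$path
    i <- sample(paths[[si]]$n, 1)
    base <- get_at(m$params, pth)
    up <- base; up[i] <- up[i] + eps
    dn <- base; dn[i] <- dn[i] - eps
    fd <- (lossfun(set_at(m$params, pth, up)) -
             lossfun(set_at(m$params, pth, dn))) / (2 * eps)
    an <- get_at(gr, pth)[i]
    expect_lt(abs(fd - an), 1e-6 + 1e-3 * (abs(fd) + abs(an)),
              label = paste("grad at", paste(pth, collapse = "/"), i))
  }
})

test_that("training is seed-deterministic and loss decreases on a separable task", {
  set.seed(50)
  mk <- function(seed) {
    set.seed(seed)
    lab <- array(0L, c(32, 32, 32))
    lab[8:14, 8:14, 8:14] <- 1L
    x <- array(rnorm(2 * 32^3, sd = 0.3), c(2, 32, 32, 32))
    x[1, , , ] <- x[1, , , ] + 2 * lab
    x[2, , , ] <- x[2, , , ] - lab
    list(x = x, y = lab)
  }
  pairs <- lapply(1:3, mk)
  cfg <- tiny_cfg(K = 2, Cin = 2)
  tr <- train_config(epochs = 4, lr = 3e-3, batch_size = 2, seed = 13)
  f1 <- swin3d_fit(lapply(pairs, `[[`, "x"), lapply(pairs, `[[`, "y"),
                   cfg, tr)
  f2 <- swin3d_fit(lapply(pairs, `[[`, "x"), lapply(pairs, `[[`, "y"),
                   cfg, tr)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_lt(f1$history$loss[4], f1$history$loss[1])
})

test_that("checkpoints are written, loadable and resumable", {
  dir <- withr::local_tempdir()
  lab <- array(0L, c(32, 32, 32)); lab[10:16, 10:16, 10:16] <- 1L
  set.seed(51)
  x <- array(rnorm(2 * 32^3), c(2, 32, 32, 32))
  cfg <- tiny_cfg(K = 2, Cin = 2)
  tr <- train_config(epochs = 2, lr = 1e-3, seed = 14, checkpoint_dir = dir)
  fit <- swin3d_fit(list(x), list(lab), cfg, tr,
                    validation = list(inputs = list(x), masks = list(lab)))
  files <- list.files(dir, pattern = "^epoch_")
  expect_length(files, 2)
  ck <- readRDS(file.path(dir, files[2]))
  expect_named(ck, c("params", "optimizer", "history", "best_val", "config",
                     "training", "epoch"), ignore.order = TRUE)
  m2 <- load_checkpoint(file.path(dir, files[2]))
  expect_s3_class(m2, "swin3d")
  resumed <- swin3d_fit(list(x), list(lab), cfg,
                        train_config(epochs = 1, lr = 1e-3, seed = 15),
                        model = m2)
  expect_equal(nrow(resumed$history), 3)
})
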