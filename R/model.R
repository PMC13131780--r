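# The 3D shifted-window transformer U-Net.
#
# Four encoder stages (patch merge then swin blocks, widths doubling from
# hidden_dim), a mirrored decoder (patch expand, additive skip fusion, swin
# blocks), a final expansion back to full resolution and a 1x1x1 linear head
# producing per-voxel class logits. A half-width stem embedding maps the 4
# input channels to hidden_dim/2 at full resolution so that the four doubling
# merges yield the hidden_dim -> 2h -> 4h -> 8h width schedule. Q/K/V are
# projected to heads*head_dim per stage (decoupled from the stage width), and
# the attention output is projected back, which reconciles the head counts
# with the doubling widths. Training is Adam on class-weighted cross-entropy
# with global-norm gradient clipping; everything is driven by a single seed.

#' Model configuration
#'
#' @param num_classes number of semantic classes K including background.
#' @param in_channels input channels (4 for the standard feature stack).
#' @param hidden_dim base embedding width (stage widths are
#'   `hidden_dim * 2^(stage-1)`); must be even.
#' @param depths even block counts per stage (regular/shifted alternation).
#' @param heads attention heads per stage.
#' @param head_dim per-head dimension.
#' @param window 3D attention window (default `c(2,2,2)`).
#' @param mlp_ratio MLP expansion factor.
#' @param dropout dropout rate in the MLP path (training only).
#' @param skip_style skip fusion style; only `"additive"` is provided.
#' @return A `swin3d_config` list.
#' @export
swin3d_config <- function(num_classes, in_channels = 4L, hidden_dim = 32L,
                          depths = c(2L, 6L, 6L, 2L),
                          heads = c(3L, 6L, 12L, 24L), head_dim = 32L,
                          window = c(2L, 2L, 2L), mlp_ratio = 4,
                          dropout = 0.1, skip_style = "additive") {
  if (missing(num_classes) || num_classes < 2)
    stop("num_classes (including background) must be >= 2")
  if (hidden_dim %% 2L != 0L) stop("hidden_dim must be even")
  if (length(depths) != 4L || length(heads) != 4L)
    stop("depths and heads must have length 4 (four stages)")
  if (any(depths %% 2L != 0L))
    stop("stage depths must be even (regular/shifted alternation)")
  if (skip_style != "additive") stop("only additive skip fusion is provided")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(num_classes = as.integer(num_classes),
                 in_channels = as.integer(in_channels),
                 hidden_dim = as.integer(hidden_dim),
                 depths = as.integer(depths), heads = as.integer(heads),
                 head_dim = as.integer(head_dim),
                 window = as.integer(window), mlp_ratio = mlp_ratio,
                 dropout = dropout, skip_style = skip_style,
                 downscale = c(2L, 2L, 2L, 2L)),
            class = "swin3d_config")
}

stage_widths <- function(cfg) cfg$hidden_dim * 2L^(0:3)

block_params <- function(C, heads, head_dim, mlp_ratio, window) {
  hd <- heads * head_dim
  nrel <- prod(2L * window - 1L)
  mC <- as.integer(mlp_ratio * C)
  list(ln1_g = rep(1, C), ln1_b = rep(0, C),
       Wqkv = matrix(trunc_normal(C * 3 * hd), C, 3 * hd),
       bqkv = rep(0, 3 * hd),
       Wo = matrix(trunc_normal(hd * C), hd, C),
       bo = rep(0, C),
       bias = matrix(0, nrel, heads),
       ln2_g = rep(1, C), ln2_b = rep(0, C),
       W1 = matrix(trunc_normal(C * mC), C, mC), b1 = rep(0, mC),
       W2 = matrix(trunc_normal(mC * C), mC, C), b2 = rep(0, C))
}

#' Initialize the parameter tree of a model configuration
#'
#' Weights are truncated-normal (sd 0.02), biases zero, layer norms identity,
#' relative-position bias tables zero; fully determined by the RNG state.
#'
#' @param cfg a [swin3d_config()].
#' @return Nested list of parameter arrays.
#' @export
swin3d_init_params <- function(cfg) {
  w <- stage_widths(cfg)
  stem_dim <- cfg$hidden_dim %/% 2L
  p <- list()
  p$stem <- list(W = matrix(trunc_normal(cfg$in_channels * stem_dim),
                            cfg$in_channels, stem_dim),
                 b = rep(0, stem_dim))
  prev <- stem_dim
  p$enc <- vector("list", 4L)
  for (s in 1:4) {
    blocks <- lapply(seq_len(cfg$depths[s]), function(i)
      block_params(w[s], cfg$heads[s], cfg$head_dim, cfg$mlp_ratio,
                   cfg$window))
    p$enc[[s]] <- list(
      merge = list(W = matrix(trunc_normal(prev * 8L * w[s]), prev * 8L, w[s]),
                   b = rep(0, w[s]), g = rep(1, w[s]), beta = rep(0, w[s])),
      blocks = blocks)
    prev <- w[s]
  }
  p$dec <- vector("list", 3L)
  for (s in 3:1) {
    blocks <- lapply(seq_len(cfg$depths[s]), function(i)
      block_params(w[s], cfg$heads[s], cfg$head_dim, cfg$mlp_ratio,
                   cfg$window))
    p$dec[[s]] <- list(
      expand = list(W = matrix(trunc_normal(w[s + 1] * w[s] * 8L),
                               w[s + 1], w[s] * 8L),
                    b = rep(0, w[s] * 8L), g = rep(1, w[s]),
                    beta = rep(0, w[s])),
      fuse = list(g = rep(1, w[s]), beta = rep(0, w[s])),
      blocks = blocks)
  }
  p$final <- list(
    expand = list(W = matrix(trunc_normal(w[1] * stem_dim * 8L),
                             w[1], stem_dim * 8L),
                  b = rep(0, stem_dim * 8L), g = rep(1, stem_dim),
                  beta = rep(0, stem_dim)),
    head = list(W = matrix(trunc_normal(stem_dim * cfg$num_classes),
                           stem_dim, cfg$num_classes),
                b = rep(0, cfg$num_classes)))
  p
}

# memoized window info per (dims, shift)
get_wi <- function(env, dims, window, shift) {
  key <- paste(c(dims, shift), collapse = "_")
  if (is.null(env$wi[[key]]))
    env$wi[[key]] <- window_info(dims, window, shift)
  env$wi[[key]]
}

stage_blocks_fwd <- function(x, blocks, dims, cfg, s, env, training) {
  caches <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    shift <- if (b %% 2L == 0L) cfg$window %/% 2L else c(0L, 0L, 0L)
    wi <- get_wi(env, dims, cfg$window, shift)
    r <- block_fwd(x, blocks[[b]], wi, cfg$heads[s], cfg$head_dim,
                   cfg$mlp_ratio, cfg$dropout, training)
    x <- r$y
    caches[[b]] <- list(cache = r, wi = wi)
  }
  list(y = x, caches = caches)
}

stage_blocks_bwd <- function(dy, caches, blocks, cfg, s) {
  grads <- vector("list", length(blocks))
  for (b in rev(seq_along(blocks))) {
    r <- block_bwd(dy, caches[[b]]$cache, blocks[[b]], caches[[b]]$wi,
                   cfg$heads[s], cfg$head_dim)
    dy <- r$dx
    grads[[b]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

# Full forward pass on one window: x tokens (N x C_in) at spatial dims.
net_fwd <- function(params, cfg, x, dims, env, training = FALSE) {
  if (any(dims %% 16L != 0L))
    stop("input spatial size must be divisible by 16 (four halvings)")
  cache <- list(dims0 = dims)
  st <- lin_fwd(x, params$stem$W, params$stem$b)
  cache$stem <- st
  h <- st$y
  enc_out <- vector("list", 4L)
  enc_cache <- vector("list", 4L)
  C_prev <- ncol(h)
  for (s in 1:4) {
    m <- merge_fwd(h, C_prev, dims, params$enc[[s]]$merge, 2L)
    dims <- m$coarse_dims
    bl <- stage_blocks_fwd(m$y, params$enc[[s]]$blocks, dims, cfg, s, env,
                           training)
    h <- bl$y
    C_prev <- ncol(h)
    enc_out[[s]] <- h
    enc_cache[[s]] <- list(merge = m, blocks = bl$caches, dims = dims)
  }
  cache$enc <- enc_cache
  dec_cache <- vector("list", 3L)
  for (s in 3:1) {
    e <- expand_fwd(h, dims, params$dec[[s]]$expand, 2L)
    dims <- e$fine_dims
    f <- fuse_fwd(e$y, enc_out[[s]], params$dec[[s]]$fuse)
    bl <- stage_blocks_fwd(f$y, params$dec[[s]]$blocks, dims, cfg, s, env,
                           training)
    h <- bl$y
    dec_cache[[s]] <- list(expand = e, fuse = f, blocks = bl$caches,
                           dims = dims)
  }
  cache$dec <- dec_cache
  fe <- expand_fwd(h, dims, params$final$expand, 2L)
  ge <- gelu_fwd(fe$y)
  hd <- lin_fwd(ge$y, params$final$head$W, params$final$head$b)
  cache$final <- list(expand = fe, gelu = ge, head = hd)
  list(logits = hd$y, cache = cache)
}

net_bwd <- function(params, cfg, dlogits, cache) {
  g <- list()
  hb <- lin_bwd(dlogits, cache$final$head, params$final$head$W)
  dge <- gelu_bwd(hb$dx, cache$final$gelu)
  feb <- expand_bwd(dge, cache$final$expand, params$final$expand)
  g$final <- list(expand = list(W = feb$dW, b = feb$db, g = feb$dg,
                                beta = feb$dbeta),
                  head = list(W = hb$dW, b = hb$db))
  dy <- feb$dx
  g$dec <- vector("list", 3L)
  denc_acc <- vector("list", 4L)
  for (s in 1:3) {
    dc <- cache$dec[[s]]
    bb <- stage_blocks_bwd(dy, dc$blocks, params$dec[[s]]$blocks, cfg, s)
    fb <- fuse_bwd(bb$dx, dc$fuse, params$dec[[s]]$fuse)
    denc_acc[[s]] <- fb$denc
    eb <- expand_bwd(fb$ddec, dc$expand, params$dec[[s]]$expand)
    g$dec[[s]] <- list(expand = list(W = eb$dW, b = eb$db, g = eb$dg,
                                     beta = eb$dbeta),
                       fuse = list(g = fb$dg, beta = fb$dbeta),
                       blocks = bb$grads)
    dy <- eb$dx
  }
  g$enc <- vector("list", 4L)
  for (s in 4:1) {
    ec <- cache$enc[[s]]
    if (!is.null(denc_acc[[s]])) dy <- dy + denc_acc[[s]]
    bb <- stage_blocks_bwd(dy, ec$blocks, params$enc[[s]]$blocks, cfg, s)
    mb <- merge_bwd(bb$dx, ec$merge, params$enc[[s]]$merge)
    g$enc[[s]] <- list(merge = list(W = mb$dW, b = mb$db, g = mb$dg,
                                    beta = mb$dbeta),
                       blocks = bb$grads)
    dy <- mb$dx
  }
  sb <- lin_bwd(dy, cache$stem, params$stem$W)
  g$stem <- list(W = sb$dW, b = sb$db)
  # return in the same member order as the parameter tree
  list(stem = g$stem, enc = g$enc, dec = g$dec, final = g$final)
}

# NOTE on the decoder backward order: g$dec must be filled before the encoder
# backward because skip gradients (denc_acc) feed the encoder stages.

#' Forward pass: per-voxel class logits for one window
#'
#' @param model a `swin3d` model (see [swin3d_model()]).
#' @param x input window: channel-first array `(C_in, D, H, W)` with spatial
#'   dims divisible by 16, or a `grid_bundle` holding one.
#' @return Logits array `(K, D, H, W)`.
#' @export
swin3d_forward <- function(model, x) {
  stopifnot(inherits(model, "swin3d"))
  if (inherits(x, "grid_bundle")) x <- x$grid
  d <- dim(x)
  if (length(d) != 4L || d[1] != model$config$in_channels)
    stop("expected a (", model$config$in_channels, ", D, H, W) array")
  tok <- tok_from_grid(x)
  r <- net_fwd(model$params, model$config, tok, d[2:4], model$env,
               training = FALSE)
  grid_from_tok(r$logits, d[2:4])
}

# ---- loss, weights, clipping ------------------------------------------------

softmax_rows <- function(z) {
  m <- z[, 1]
  if (ncol(z) > 1) for (k in 2:ncol(z)) m <- pmax(m, z[, k])
  e <- exp(z - m)
  e / rowSums(e)
}

#' Class-weighted voxel-wise cross-entropy
#'
#' `loss = mean_v w[y_v] * (-log p_{v, y_v})` with `p = softmax(logits)`;
#' weights address the severe background/particle imbalance.
#'
#' @param logits `(K, D, H, W)` array or `N x K` matrix of per-voxel logits.
#' @param labels integer labels in `0..K-1` (array or vector), 0 = background.
#' @param weights per-class weights (length K); default all 1.
#' @return Scalar loss (non-negative).
#' @export
weighted_cross_entropy <- function(logits, labels, weights = NULL) {
  ce_fwd(logits, labels, weights)$loss
}

ce_fwd <- function(logits, labels, weights = NULL) {
  if (is.array(logits) && length(dim(logits)) == 4L)
    logits <- tok_from_grid(logits)
  K <- ncol(logits)
  y <- as.integer(as.vector(labels))
  if (any(y < 0L | y >= K))
    stop("labels must lie in 0..K-1 (K = ", K, ")")
  if (length(y) != nrow(logits))
    stop("labels length does not match the number of voxels")
  if (is.null(weights)) weights <- rep(1, K)
  if (length(weights) != K) stop("weights must have length K")
  p <- softmax_rows(logits)
  N <- nrow(logits)
  iy <- cbind(seq_len(N), y + 1L)
  wv <- weights[y + 1L]
  loss <- mean(wv * (-log(pmax(p[iy], 1e-12))))
  list(loss = loss, p = p, iy = iy, wv = wv, N = N)
}

ce_bwd <- function(cache) {
  dz <- cache$p * cache$wv / cache$N
  dz[cache$iy] <- dz[cache$iy] - cache$wv / cache$N
  dz
}

#' Inverse-frequency class weights from voxel counts
#'
#' `w_k` proportional to `N_total / (K * max(N_k, 1))`, normalized to mean 1
#' so the learning-rate semantics are stable; absent classes stay finite via
#' the `max(., 1)` guard.
#'
#' @param counts non-negative voxel counts per class (length K, background
#'   first).
#' @return Numeric weights of length K with mean 1.
#' @export
class_weights_from_counts <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("degenerate input: all class counts are zero")
  K <- length(counts)
  w <- sum(counts) / (K * pmax(counts, 1))
  w / mean(w)
}

#' Global-norm gradient clipping
#'
#' If the global L2 norm over all gradient arrays exceeds `tau`, every array
#' is rescaled by `tau / norm`; direction is preserved and the post-clip norm
#' never exceeds `tau`.
#'
#' @param grads numeric vector/array or arbitrarily nested list of them.
#' @param tau positive clipping threshold.
#' @return Clipped gradients with the same structure.
#' @export
clip_gradients <- function(grads, tau) {
  if (tau <= 0) stop("tau must be positive")
  ss <- grad_reduce(grads, 0)
  nrm <- sqrt(ss)
  if (nrm <= tau) return(grads)
  grad_scale(grads, tau / nrm)
}

grad_reduce <- function(g, acc) {
  if (is.list(g)) {
    for (el in g) acc <- grad_reduce(el, acc)
    acc
  } else acc + sum(g * g)
}

grad_scale <- function(g, f) {
  if (is.list(g)) lapply(g, grad_scale, f = f) else g * f
}

grad_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
            else seq_along(a)
    for (k in keys) out[[k]] <- grad_map2(a[[k]], b[[k]], f)
    out
  } else f(a, b)
}

grad_zero_like <- function(g) grad_scale(g, 0)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- grad_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- grad_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- grad_map2(state$m, state$v,
                   function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- grad_map2(params, upd, `-`)
  list(params = params, state = state)
}

# ---- model object, fitting, prediction --------------------------------------

#' Create an (untrained) segmentation model
#'
#' @param config a [swin3d_config()].
#' @param seed RNG seed for the parameter initialization.
#' @return An object of class `swin3d`.
#' @export
swin3d_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "swin3d_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  structure(list(config = config, params = swin3d_init_params(config),
                 env = new.env(parent = emptyenv()),
                 history = data.frame(epoch = integer(), loss = numeric(),
                                      val_loss = numeric()),
                 class_weights = NULL, trained = FALSE, seed = as.integer(seed)),
            class = "swin3d")
}

#' Training configuration
#'
#' @param epochs number of passes over the training windows.
#' @param lr Adam learning rate.
#' @param batch_size windows per optimizer step (gradients averaged).
#' @param grad_clip global-norm clipping threshold.
#' @param class_weights per-class weights, or `NULL` to derive
#'   inverse-frequency weights from the corpus voxel counts.
#' @param seed seed governing shuffling and dropout.
#' @param checkpoint_dir if non-`NULL`, a per-epoch checkpoint (model state,
#'   optimizer state, loss history, best validation record and a full config
#'   snapshot) is written here.
#' @param verbose print per-epoch losses.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 10L, lr = 1e-4, batch_size = 2L,
                         grad_clip = 1, class_weights = NULL, seed = 1L,
                         checkpoint_dir = NULL, verbose = FALSE) {
  if (grad_clip <= 0) stop("grad_clip must be positive")
  if (!is.null(class_weights) && any(class_weights < 0))
    stop("class weights must be non-negative")
  if (!is.null(class_weights) && all(class_weights == 0))
    stop("at least one class weight must be positive")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), grad_clip = grad_clip,
                 class_weights = class_weights, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir, verbose = isTRUE(verbose)),
            class = "train_config")
}

bundle_grid <- function(x) if (inherits(x, "grid_bundle")) x$grid else x

#' Fit the segmentation network on paired feature/label windows
#'
#' Optimizes class-weighted cross-entropy with Adam and global-norm gradient
#' clipping. One seed governs initialization, shuffling and dropout, so a
#' rerun with the same inputs reproduces the loss curve exactly.
#'
#' @param inputs list of feature windows (`grid_bundle`s or `(C,D,H,W)`
#'   arrays).
#' @param masks list of paired label windows (`grid_bundle`s or `(D,H,W)`
#'   integer arrays with labels in `0..K-1`).
#' @param config a [swin3d_config()].
#' @param training a [train_config()].
#' @param validation optional `list(inputs=, masks=)` held-out pairs scored
#'   after every epoch.
#' @param model optionally resume from an existing `swin3d` object.
#' @return A fitted `swin3d` object with `history`, `class_weights` and the
#'   configs recorded.
#' @export
swin3d_fit <- function(inputs, masks, config, training = train_config(),
                       validation = NULL, model = NULL) {
  if (length(inputs) == 0) stop("empty training set")
  if (length(inputs) != length(masks))
    stop("inputs and masks must have equal length")
  stopifnot(inherits(config, "swin3d_config"))
  K <- config$num_classes

  xs <- lapply(inputs, bundle_grid)
  ys <- lapply(masks, bundle_grid)
  dims <- dim(xs[[1]])[2:4]
  tok_x <- lapply(xs, tok_from_grid)
  lab_y <- lapply(ys, function(y) as.integer(as.vector(y)))
  for (y in lab_y) if (any(y < 0L | y >= K))
    stop("mask labels must lie in 0..K-1")

  cw <- training$class_weights
  if (is.null(cw)) {
    counts <- numeric(K)
    for (y in lab_y) counts <- counts + tabulate(y + 1L, nbins = K)
    cw <- class_weights_from_counts(counts)
  }

  if (is.null(model)) model <- swin3d_model(config, seed = training$seed)
  params <- model$params
  env <- model$env

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(training$seed + 1L)

  opt <- NULL
  history <- model$history
  best_val <- Inf
  n <- length(tok_x)
  for (epoch in seq_len(training$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    i <- 1L
    while (i <= n) {
      idx <- ord[i:min(i + training$batch_size - 1L, n)]
      gacc <- NULL
      bl <- 0
      for (s in idx) {
        fw <- net_fwd(params, config, tok_x[[s]], dims, env, training = TRUE)
        ce <- ce_fwd(fw$logits, lab_y[[s]], cw)
        bl <- bl + ce$loss
        gr <- net_bwd(params, config, ce_bwd(ce), fw$cache)
        gacc <- if (is.null(gacc)) gr else grad_map2(gacc, gr, `+`)
      }
      gacc <- grad_scale(gacc, 1 / length(idx))
      gacc <- clip_gradients(gacc, training$grad_clip)
      if (is.null(opt))
        opt <- list(t = 0L, m = grad_zero_like(gacc), v = grad_zero_like(gacc))
      st <- adam_step(params, gacc, opt, training$lr)
      params <- st$params
      opt <- st$state
      losses <- c(losses, bl / length(idx))
      i <- i + training$batch_size
    }
    val_loss <- NA_real_
    if (!is.null(validation)) {
      vx <- lapply(validation$inputs, bundle_grid)
      vy <- lapply(validation$masks, bundle_grid)
      vl <- numeric(0)
      for (s in seq_along(vx)) {
        fw <- net_fwd(params, config, tok_from_grid(vx[[s]]),
                      dim(vx[[s]])[2:4], env, training = FALSE)
        vl <- c(vl, ce_fwd(fw$logits, as.integer(as.vector(vy[[s]])), cw)$loss)
      }
      val_loss <- mean(vl)
      if (val_loss < best_val) best_val <- val_loss
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = mean(losses),
                                         val_loss = val_loss))
    if (training$verbose)
      message(sprintf("epoch %d: loss %.5f%s", epoch, mean(losses),
                      if (!is.na(val_loss))
                        sprintf(", val %.5f", val_loss) else ""))
    if (!is.null(training$checkpoint_dir)) {
      dir.create(training$checkpoint_dir, showWarnings = FALSE,
                 recursive = TRUE)
      saveRDS(list(params = params, optimizer = opt, history = history,
                   best_val = if (is.finite(best_val)) best_val else NA_real_,
                   config = config, training = training, epoch = epoch),
              file.path(training$checkpoint_dir,
                        sprintf("epoch_%03d.rds", epoch)))
    }
  }
  model$params <- params
  model$history <- history
  model$class_weights <- cw
  model$trained <- TRUE
  model$training <- training
  model$optimizer <- opt
  model
}

#' Load a training checkpoint as a model
#'
#' @param path checkpoint file written during [swin3d_fit()].
#' @return A `swin3d` object (resumable via the `model` argument of
#'   [swin3d_fit()]).
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- swin3d_model(ck$config, seed = ck$training$seed)
  m$params <- ck$params
  m$history <- ck$history
  m$trained <- TRUE
  m$training <- ck$training
  m$optimizer <- ck$optimizer
  m
}

#' Inference configuration
#'
#' @param conf_threshold global confidence threshold tau in `[0, 1]` applied
#'   to the maximum posterior; voxels below it are set to background.
#' @return An `infer_config` list.
#' @export
infer_config <- function(conf_threshold = 0.5) {
  if (conf_threshold < 0 || conf_threshold > 1)
    stop("conf_threshold must be in [0, 1]")
  structure(list(conf_threshold = conf_threshold), class = "infer_config")
}

#' Predict the label grid for one window
#'
#' Softmax posteriors followed by argmax; voxels whose maximum posterior is
#' below the confidence threshold become background. In binary mode (K = 2)
#' the particle posterior is thresholded directly.
#'
#' @param model a fitted `swin3d`.
#' @param x feature window (`(C,D,H,W)` array or `grid_bundle`).
#' @param ic an [infer_config()].
#' @return Integer label array `(D, H, W)`.
#' @export
predict_window <- function(model, x, ic = infer_config()) {
  stopifnot(inherits(model, "swin3d"), inherits(ic, "infer_config"))
  if (inherits(x, "grid_bundle")) x <- x$grid
  d <- dim(x)
  tok <- tok_from_grid(x)
  r <- net_fwd(model$params, model$config, tok, d[2:4], model$env,
               training = FALSE)
  p <- softmax_rows(r$logits)
  K <- ncol(p)
  if (K == 2L) {
    lab <- as.integer(p[, 2] >= ic$conf_threshold)
  } else {
    lab <- max.col(p, ties.method = "first") - 1L
    lab[p[cbind(seq_len(nrow(p)), lab + 1L)] < ic$conf_threshold] <- 0L
  }
  array(lab, dim = d[2:4])
}

# ---- S3 methods -------------------------------------------------------------

count_params <- function(p) {
  if (is.list(p)) sum(vapply(p, count_params, numeric(1))) else length(p)
}

#' @export
print.swin3d <- function(x, ...) {
  cfg <- x$config
  w <- stage_widths(cfg)
  cat("<swin3d> 3D shifted-window transformer U-Net\n")
  cat(sprintf("  classes: %d, input channels: %d\n",
              cfg$num_classes, cfg$in_channels))
  cat(sprintf("  stage widths: %s; depths: %s; heads: %s (head dim %d)\n",
              paste(w, collapse = "/"), paste(cfg$depths, collapse = "/"),
              paste(cfg$heads, collapse = "/"), cfg$head_dim))
  cat(sprintf("  window: %s; parameters: %s; %s\n",
              paste(cfg$window, collapse = "x"),
              format(count_params(x$params), big.mark = ","),
              if (x$trained) sprintf("trained (%d epochs, final loss %.4f)",
                                     nrow(x$history),
                                     x$history$loss[nrow(x$history)])
              else "untrained"))
  invisible(x)
}

#' @export
summary.swin3d <- function(object, ...) {
  print(object)
  cat("  parameter counts by component:\n")
  for (nm in names(object$params))
    cat(sprintf("    %-6s %s\n", nm,
                format(count_params(object$params[[nm]]), big.mark = ",")))
  if (!is.null(object$class_weights))
    cat("  class weights:", paste(signif(object$class_weights, 4),
                                  collapse = ", "), "\n")
  if (nrow(object$history) > 0) {
    cat("  loss history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.swin3d <- function(object, ...) object$params

#' @export
plot.swin3d <- function(x, ...) {
  if (nrow(x$history) == 0) stop("no training history to plot")
  plot(x$history$epoch, x$history$loss, type = "b", pch = 16,
       xlab = "epoch", ylab = "loss", main = "training loss", ...)
  if (any(!is.na(x$history$val_loss))) {
    graphics::lines(x$history$epoch, x$history$val_loss, type = "b",
                    col = "red3", pch = 1)
    graphics::legend("topright", c("train", "validation"),
                     col = c("black", "red3"), pch = c(16, 1), bty = "n")
  }
  invisible(x)
}

#' Predict labels for windows, bundles or a whole feature stack
#'
#' @param object a fitted `swin3d`.
#' @param newdata a `(C,D,H,W)` array, a `grid_bundle`, a list of bundles,
#'   or a `feature_stack` (split, predicted window-wise and stitched back
#'   into a label volume).
#' @param tau confidence threshold (see [infer_config()]).
#' @param spec [grid_spec()] used when `newdata` is a `feature_stack`.
#' @param ... unused.
#' @return Label array, label bundle(s), or a label [new_volume()],
#'   matching the input form.
#' @export
predict.swin3d <- function(object, newdata, tau = 0.5, spec = grid_spec(),
                           ...) {
  ic <- infer_config(tau)
  if (inherits(newdata, "feature_stack")) {
    bundles <- split_volume(newdata, spec)
    preds <- lapply(bundles, function(b) {
      nb <- b
      nb$grid <- predict_window(object, b, ic)
      nb
    })
    return(stitch(preds))
  }
  if (inherits(newdata, "grid_bundle")) {
    nb <- newdata
    nb$grid <- predict_window(object, newdata, ic)
    return(nb)
  }
  if (is.list(newdata)) {
    return(lapply(newdata, function(b) predict(object, b, tau = tau)))
  }
  predict_window(object, newdata, ic)
}
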