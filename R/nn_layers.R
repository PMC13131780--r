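# Neural-network primitives for the 3D shifted-window transformer.
#
# Feature maps are held as token matrices (N x C, one row per voxel) in
# canonical raster order (x fastest). Every primitive has a forward returning
# `list(y, cache)` and a matching backward returning input and parameter
# gradients; gradients are verified against finite differences in the tests.
# Window machinery (partition permutations, relative-position bias indices,
# shifted-window masks) is precomputed per spatial shape and reused.

MASK_NEG <- -1e4  # additive logit for forbidden token pairs (< 1e-6 weight)

row_scale <- function(x, v) x * rep(v, each = nrow(x))  # per-column scale

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

# ---- linear ----------------------------------------------------------------

lin_fwd <- function(x, W, b) {
  y <- x %*% W
  y <- y + rep(b, each = nrow(y))
  list(y = y, x = x)
}

lin_bwd <- function(dy, cache, W) {
  list(dx = dy %*% t(W),
       dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

# ---- layer norm (over channels, per token) ---------------------------------

ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- row_scale(xhat, g) + rep(b, each = nrow(x))
  list(y = y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- row_scale(dy, g)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                       xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# ---- GELU (exact, Phi-based) ----------------------------------------------

gelu_fwd <- function(x) {
  ph <- stats::pnorm(x)
  list(y = x * ph, x = x, ph = ph)
}

gelu_bwd <- function(dy, cache) {
  dy * (cache$ph + cache$x * stats::dnorm(cache$x))
}

# ---- dropout ---------------------------------------------------------------

drop_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

drop_bwd <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# ---- window bookkeeping ----------------------------------------------------

# Relative-position bias index matrix for a window: entry (i, j) is the
# 1-based row of the bias table for the 3D offset between tokens i and j.
# The table has (2w1-1)(2w2-1)(2w3-1) rows.
rel_bias_index <- function(window) {
  w <- as.integer(window)
  t_id <- 0:(prod(w) - 1)
  tx <- t_id %% w[1]
  ty <- (t_id %/% w[1]) %% w[2]
  tz <- t_id %/% (w[1] * w[2])
  off1 <- outer(tx, tx, `-`) + w[1] - 1L
  off2 <- outer(ty, ty, `-`) + w[2] - 1L
  off3 <- outer(tz, tz, `-`) + w[3] - 1L
  idx <- off1 + (2L * w[1] - 1L) * (off2 + (2L * w[2] - 1L) * off3) + 1L
  storage.mode(idx) <- "integer"
  idx
}

#' Relative position bias for a 3D attention window
#'
#' Expands a learnable bias table (one row per discrete 3D offset within the
#' window, one column per head) into the per-head `(T, T)` bias matrices added
#' to the attention logits; the `(i, j)` entry depends only on the offset
#' between tokens i and j.
#'
#' @param bias_table numeric matrix `((2w1-1)(2w2-1)(2w3-1), heads)`.
#' @param window integer length-3 window dimensions.
#' @return Array `(T, T, heads)` with `T = prod(window)`.
#' @export
relative_position_bias <- function(bias_table, window) {
  idx <- rel_bias_index(window)
  T <- nrow(idx)
  h <- ncol(bias_table)
  if (nrow(bias_table) != prod(2L * as.integer(window) - 1L))
    stop("bias table must have (2w-1)^3 rows for this window")
  out <- array(0, dim = c(T, T, h))
  for (k in seq_len(h)) out[, , k] <- matrix(bias_table[idx, k], T, T)
  out
}

# Windowing info for a spatial shape: the permutation between canonical raster
# order and (token-major, window-minor) order, plus the shifted-window mask.
# Shifted coordinates are s = (c - shift) mod n; region ids follow the
# standard three-segment construction per axis evaluated at s, so only token
# pairs wrapped across the volume boundary are masked.
window_info <- function(dims, window, shift = c(0L, 0L, 0L)) {
  dims <- as.integer(dims); window <- as.integer(window)
  shift <- as.integer(shift)
  if (any(dims %% window != 0L))
    stop("window (", paste(window, collapse = "x"),
         ") must divide spatial dims (", paste(dims, collapse = "x"), ")")
  N <- prod(dims)
  Tn <- prod(window)
  nw <- N %/% Tn
  vox <- 0:(N - 1)
  cx <- vox %% dims[1]
  cy <- (vox %/% dims[1]) %% dims[2]
  cz <- vox %/% (dims[1] * dims[2])
  seg <- function(s, n, w, d) {
    # region segments [0, n-w), [n-w, n-d), [n-d, n) of the shifted axis
    r <- integer(length(s))
    r[s >= n - w] <- 1L
    if (d > 0L) r[s >= n - d] <- 2L
    r
  }
  reg <- integer(N)
  winid <- integer(N); tokid <- integer(N)
  nwpa <- dims %/% window
  co <- list(cx, cy, cz)
  wl <- list(); tl <- list()
  for (a in 1:3) {
    s <- (co[[a]] - shift[a]) %% dims[a]
    wl[[a]] <- s %/% window[a]
    tl[[a]] <- s %% window[a]
    reg <- reg * 3L + seg(s, dims[a], window[a], shift[a])
  }
  w_id <- wl[[1]] + nwpa[1] * (wl[[2]] + nwpa[2] * wl[[3]])
  t_id <- tl[[1]] + window[1] * (tl[[2]] + window[2] * tl[[3]])
  prow <- t_id * nw + w_id + 1L
  orig <- integer(N)
  orig[prow] <- seq_len(N)     # permuted row -> canonical row
  mask <- NULL
  if (any(shift > 0L)) {
    R <- matrix(0L, nw, Tn)
    R[cbind(w_id + 1L, t_id + 1L)] <- reg
    if (any(apply(R, 1, function(r) length(unique(r))) > 1L)) {
      mask <- array(0, dim = c(nw, Tn, Tn))
      for (i in seq_len(Tn)) for (j in seq_len(Tn))
        mask[, i, j] <- ifelse(R[, i] != R[, j], MASK_NEG, 0)
    }
  }
  list(dims = dims, window = window, shift = shift, nw = nw, T = Tn,
       orig = orig, bidx = rel_bias_index(window), mask = mask)
}

#' Additive mask for shifted-window attention
#'
#' For a cyclic shift by `shift` voxels per axis, token pairs that end up in
#' the same window only through wrap-around at the volume boundary receive a
#' large negative additive logit (-1e4); genuinely adjacent pairs receive 0.
#' With zero shift no pair is masked.
#'
#' @param dims spatial dimensions (length 3), each divisible by `window`.
#' @param window window dimensions (length 3).
#' @param shift per-axis cyclic shift (conventionally `window / 2`).
#' @return Array `(n_windows, T, T)` of additive logits (all zeros collapse
#'   to an explicit zero array).
#' @export
shifted_window_mask <- function(dims, window, shift = window %/% 2) {
  wi <- window_info(dims, window, shift)
  if (is.null(wi$mask)) array(0, dim = c(wi$nw, wi$T, wi$T)) else wi$mask
}

#' Partition a channel-first feature volume into attention windows
#'
#' @param x array `(C, d1, d2, d3)` with each spatial dim divisible by the
#'   window.
#' @param window window dimensions (length 3).
#' @return Array `(n_windows, T, C)` of window token blocks (raster window
#'   order, raster token order).
#' @export
window_partition <- function(x, window) {
  d <- dim(x)
  if (length(d) != 4L) stop("expected a (C, d1, d2, d3) array")
  wi <- window_info(d[2:4], window)
  tok <- t(matrix(x, nrow = d[1]))          # N x C canonical order
  tokp <- tok[wi$orig, , drop = FALSE]      # token-major, window-minor
  out <- array(0, dim = c(wi$nw, wi$T, d[1]))
  for (t in seq_len(wi$T))
    out[, t, ] <- tokp[((t - 1L) * wi$nw + 1L):(t * wi$nw), , drop = FALSE]
  out
}

#' @rdname window_partition
#' @param windows array `(n_windows, T, C)` from [window_partition()].
#' @param dims original spatial dimensions (length 3).
#' @return `window_reverse` returns the `(C, d1, d2, d3)` array.
#' @export
window_reverse <- function(windows, window, dims) {
  dw <- dim(windows)
  C <- dw[3]
  wi <- window_info(dims, window)
  tokp <- matrix(0, wi$nw * wi$T, C)
  for (t in seq_len(wi$T))
    tokp[((t - 1L) * wi$nw + 1L):(t * wi$nw), ] <- windows[, t, ]
  tok <- matrix(0, nrow(tokp), C)
  tok[wi$orig, ] <- tokp
  array(t(tok), dim = c(C, dims))
}

# ---- windowed multi-head attention -----------------------------------------
#
# xp: tokens in permuted (token-major) order, rows (t-1)*nw + w. bias_table
# ((2w-1)^3 x heads), mask NULL or (nw, T, T) additive.

attn_fwd <- function(xp, p, wi, heads, head_dim) {
  nw <- wi$nw; Tn <- wi$T
  qkv <- xp %*% p$Wqkv
  qkv <- qkv + rep(p$bqkv, each = nrow(qkv))
  hd <- heads * head_dim
  scale <- 1 / sqrt(head_dim)
  O <- matrix(0, nrow(xp), hd)
  hc <- vector("list", heads)
  rows <- function(t) ((t - 1L) * nw + 1L):(t * nw)
  for (h in seq_len(heads)) {
    cq <- (h - 1L) * head_dim + seq_len(head_dim)
    Q <- qkv[, cq, drop = FALSE]
    K <- qkv[, hd + cq, drop = FALSE]
    V <- qkv[, 2L * hd + cq, drop = FALSE]
    S <- array(0, dim = c(nw, Tn, Tn))
    for (i in seq_len(Tn)) {
      Qi <- Q[rows(i), , drop = FALSE]
      for (j in seq_len(Tn)) {
        s <- rowSums(Qi * K[rows(j), , drop = FALSE]) * scale +
          p$bias[wi$bidx[i, j], h]
        S[, i, j] <- s
      }
    }
    if (!is.null(wi$mask)) S <- S + wi$mask
    Sm <- matrix(S, nw * Tn, Tn)          # rows (w, i), cols j
    rmax <- Sm[, 1]
    for (j in seq_len(Tn)[-1]) rmax <- pmax(rmax, Sm[, j])
    E <- exp(Sm - rmax)
    A <- E / rowSums(E)
    Aarr <- array(A, dim = c(nw, Tn, Tn))
    for (i in seq_len(Tn)) {
      acc <- matrix(0, nw, head_dim)
      for (j in seq_len(Tn))
        acc <- acc + Aarr[, i, j] * V[rows(j), , drop = FALSE]
      O[rows(i), cq] <- acc
    }
    hc[[h]] <- list(Q = Q, K = K, V = V, A = Aarr)
  }
  y <- O %*% p$Wo
  y <- y + rep(p$bo, each = nrow(y))
  list(y = y, xp = xp, O = O, hc = hc)
}

attn_bwd <- function(dy, cache, p, wi, heads, head_dim) {
  nw <- wi$nw; Tn <- wi$T
  hd <- heads * head_dim
  scale <- 1 / sqrt(head_dim)
  rows <- function(t) ((t - 1L) * nw + 1L):(t * nw)
  dWo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dO <- dy %*% t(p$Wo)
  dqkv <- matrix(0, nrow(dy), 3L * hd)
  dbias <- matrix(0, nrow(p$bias), ncol(p$bias))
  for (h in seq_len(heads)) {
    cq <- (h - 1L) * head_dim + seq_len(head_dim)
    ch <- cache$hc[[h]]
    A <- ch$A
    dA <- array(0, dim = c(nw, Tn, Tn))
    dV <- matrix(0, nw * Tn, head_dim)
    for (i in seq_len(Tn)) {
      dOi <- dO[rows(i), cq, drop = FALSE]
      for (j in seq_len(Tn)) {
        dA[, i, j] <- rowSums(dOi * ch$V[rows(j), , drop = FALSE])
        dV[rows(j), ] <- dV[rows(j), ] + A[, i, j] * dOi
      }
    }
    Am <- matrix(A, nw * Tn, Tn)
    dAm <- matrix(dA, nw * Tn, Tn)
    dSm <- Am * (dAm - rowSums(dAm * Am))
    dS <- array(dSm, dim = c(nw, Tn, Tn))
    dQ <- matrix(0, nw * Tn, head_dim)
    dK <- matrix(0, nw * Tn, head_dim)
    for (i in seq_len(Tn)) {
      Qi <- ch$Q[rows(i), , drop = FALSE]
      acc <- matrix(0, nw, head_dim)
      for (j in seq_len(Tn)) {
        dSij <- dS[, i, j]
        acc <- acc + dSij * ch$K[rows(j), , drop = FALSE]
        dK[rows(j), ] <- dK[rows(j), ] + dSij * Qi
        dbias[wi$bidx[i, j], h] <- dbias[wi$bidx[i, j], h] + sum(dSij)
      }
      dQ[rows(i), ] <- acc * scale
    }
    dK <- dK * scale
    dqkv[, cq] <- dQ
    dqkv[, hd + cq] <- dK
    dqkv[, 2L * hd + cq] <- dV
  }
  list(dx = dqkv %*% t(p$Wqkv),
       dWqkv = crossprod(cache$xp, dqkv),
       dbqkv = colSums(dqkv),
       dWo = dWo, dbo = dbo, dbias = dbias)
}

#' Windowed multi-head self-attention (functional form)
#'
#' Computes `Softmax(Q K' / sqrt(d) + B + M) V` independently within each
#' window, with Q, K, V obtained from a single linear projection of the
#' tokens and B the relative-position bias. Exposed functionally for oracle
#' testing; the network uses the same kernel internally.
#'
#' @param tokens array `(n_windows, T, C)`.
#' @param params list with `Wqkv (C x 3*heads*head_dim)`, `bqkv`,
#'   `Wo (heads*head_dim x C)`, `bo`.
#' @param bias_table matrix `((2w1-1)(2w2-1)(2w3-1), heads)`.
#' @param window window dimensions (length 3, `prod(window) == T`).
#' @param heads,head_dim attention geometry.
#' @param mask optional `(n_windows, T, T)` additive mask.
#' @return Array `(n_windows, T, C)` of attended tokens.
#' @export
window_attention <- function(tokens, params, bias_table, window, heads,
                             head_dim, mask = NULL) {
  dw <- dim(tokens)
  nw <- dw[1]; Tn <- dw[2]; C <- dw[3]
  if (Tn != prod(window)) stop("prod(window) must equal the token count")
  if (!is.null(mask) && !all(dim(mask) == c(nw, Tn, Tn)))
    stop("mask shape mismatch: expected (", nw, ",", Tn, ",", Tn, ")")
  xp <- matrix(0, nw * Tn, C)
  for (t in seq_len(Tn)) xp[((t - 1L) * nw + 1L):(t * nw), ] <- tokens[, t, ]
  wi <- list(nw = nw, T = Tn, bidx = rel_bias_index(window), mask = mask)
  p <- list(Wqkv = params$Wqkv, bqkv = params$bqkv, Wo = params$Wo,
            bo = params$bo, bias = bias_table)
  y <- attn_fwd(xp, p, wi, heads, head_dim)$y
  out <- array(0, dim = dw)
  for (t in seq_len(Tn)) out[, t, ] <- y[((t - 1L) * nw + 1L):(t * nw), ]
  out
}

# ---- patch merge / expand ---------------------------------------------------
#
# Block gather: for downscale s, coarse voxel (X,Y,Z) collects the s^3 fine
# voxels in raster block order; gather/scatter are pure index permutations, so
# their gradients are the inverse permutations.

block_gather_index <- function(dims, s) {
  dims <- as.integer(dims)
  if (any(dims %% s != 0L)) stop("spatial dims must be divisible by ", s)
  cd <- dims %/% s
  Nc <- prod(cd)
  vox <- 0:(prod(dims) - 1)
  fx <- vox %% dims[1]
  fy <- (vox %/% dims[1]) %% dims[2]
  fz <- vox %/% (dims[1] * dims[2])
  coarse <- (fx %/% s) + cd[1] * ((fy %/% s) + cd[2] * (fz %/% s))
  sub <- (fx %% s) + s * ((fy %% s) + s * (fz %% s))
  # fine row -> (coarse row, block slot)
  ord <- order(coarse * (s^3) + sub)
  list(ord = ord, coarse_dims = cd, n_coarse = Nc, block = s^3)
}

#' Patch merging: learnable volumetric downsampling
#'
#' Flattens non-overlapping `s^3` blocks of a `(C, d1, d2, d3)` feature volume
#' into tokens of length `C*s^3`, projects them linearly to `C_out` channels
#' and layer-normalizes, halving (for s = 2) each spatial dimension.
#'
#' @param x channel-first 4D array.
#' @param W projection matrix `(C*s^3, C_out)`; `b` its bias.
#' @param b,g,beta bias and layer-norm scale/shift (length `C_out`).
#' @param s downscale factor per axis (default 2).
#' @param normalize apply the layer norm (identity-testing can disable it).
#' @return Channel-first array `(C_out, d1/s, d2/s, d3/s)`.
#' @export
patch_merge <- function(x, W, b, g, beta, s = 2L, normalize = TRUE) {
  r <- merge_fwd(tok_from_grid(x), dim(x)[1], dim(x)[2:4],
                 list(W = W, b = b, g = g, beta = beta), s, normalize)
  grid_from_tok(r$y, r$coarse_dims)
}

tok_from_grid <- function(x) t(matrix(x, nrow = dim(x)[1]))
grid_from_tok <- function(tok, dims) array(t(tok), dim = c(ncol(tok), dims))

merge_fwd <- function(tok, C, dims, p, s = 2L, normalize = TRUE) {
  gi <- block_gather_index(dims, s)
  flat <- matrix(t(tok[gi$ord, , drop = FALSE]), nrow = gi$n_coarse,
                 byrow = TRUE)             # n_coarse x (C * s^3)
  l <- lin_fwd(flat, p$W, p$b)
  if (normalize) {
    n <- ln_fwd(l$y, p$g, p$beta)
    y <- n$y
  } else n <- NULL
  list(y = if (normalize) y else l$y, lin = l, ln = n, gi = gi, C = C,
       coarse_dims = gi$coarse_dims)
}

merge_bwd <- function(dy, cache, p, normalize = TRUE) {
  if (normalize) {
    nb <- ln_bwd(dy, cache$ln, p$g)
    dl <- nb$dx
  } else {
    nb <- list(dg = 0 * p$g, db = 0 * p$beta)
    dl <- dy
  }
  lb <- lin_bwd(dl, cache$lin, p$W)
  gi <- cache$gi
  dflat <- lb$dx
  dtok_perm <- matrix(t(dflat), ncol = cache$C, byrow = TRUE)
  dtok <- matrix(0, nrow(dtok_perm), cache$C)
  dtok[gi$ord, ] <- dtok_perm
  list(dx = dtok, dW = lb$dW, db = lb$db, dg = nb$dg, dbeta = nb$db)
}

#' Patch expansion: learnable volumetric upsampling
#'
#' Projects each coarse token linearly to `C_out * s^3` values, scatters the
#' `s^3` slots into the fine raster block, and layer-normalizes the resulting
#' fine tokens, multiplying each spatial dimension by `s`.
#'
#' @param x channel-first 4D array `(C, d1, d2, d3)`.
#' @param W projection `(C, C_out*s^3)`; `b` its bias.
#' @param b,g,beta bias and layer-norm parameters (length `C_out`).
#' @param s upscale factor (default 2).
#' @return Channel-first array `(C_out, d1*s, d2*s, d3*s)`.
#' @export
patch_expand <- function(x, W, b, g, beta, s = 2L) {
  r <- expand_fwd(tok_from_grid(x), dim(x)[2:4],
                  list(W = W, b = b, g = g, beta = beta), s)
  grid_from_tok(r$y, r$fine_dims)
}

expand_fwd <- function(tok, dims, p, s = 2L) {
  fine_dims <- as.integer(dims) * s
  gi <- block_gather_index(fine_dims, s)
  l <- lin_fwd(tok, p$W, p$b)              # n_coarse x (C_out * s^3)
  C_out <- ncol(l$y) %/% (s^3)
  fine_perm <- matrix(t(l$y), ncol = C_out, byrow = TRUE)
  fine <- matrix(0, nrow(fine_perm), C_out)
  fine[gi$ord, ] <- fine_perm
  n <- ln_fwd(fine, p$g, p$beta)
  list(y = n$y, lin = l, ln = n, gi = gi, C_out = C_out,
       fine_dims = fine_dims, s = s)
}

expand_bwd <- function(dy, cache, p) {
  nb <- ln_bwd(dy, cache$ln, p$g)
  dfine_perm <- nb$dx[cache$gi$ord, , drop = FALSE]
  dproj <- matrix(t(dfine_perm), nrow = nrow(cache$lin$x),
                  byrow = TRUE)
  lb <- lin_bwd(dproj, cache$lin, p$W)
  list(dx = lb$dx, dW = lb$dW, db = lb$db, dg = nb$dg, dbeta = nb$db)
}

#' Additive skip fusion
#'
#' `Norm(F_dec + F_enc)` with a learnable layer norm: the default (and only)
#' skip style, symmetric in its two arguments.
#'
#' @param f_dec,f_enc token matrices or channel-first arrays of equal shape.
#' @param g,beta layer-norm scale and shift (length C).
#' @return Fused features with the same shape as the inputs.
#' @export
skip_fuse <- function(f_dec, f_enc, g, beta) {
  if (!identical(dim(f_dec), dim(f_enc)))
    stop("skip fusion requires matching shapes")
  as_grid <- length(dim(f_dec)) == 4L
  a <- if (as_grid) tok_from_grid(f_dec) else f_dec
  b <- if (as_grid) tok_from_grid(f_enc) else f_enc
  y <- ln_fwd(a + b, g, beta)$y
  if (as_grid) grid_from_tok(y, dim(f_dec)[2:4]) else y
}

fuse_fwd <- function(dec, enc, p) {
  n <- ln_fwd(dec + enc, p$g, p$beta)
  list(y = n$y, ln = n)
}

fuse_bwd <- function(dy, cache, p) {
  nb <- ln_bwd(dy, cache$ln, p$g)
  list(ddec = nb$dx, denc = nb$dx, dg = nb$dg, dbeta = nb$db)
}

# ---- swin block -------------------------------------------------------------
#
# Pre-norm residual: x + Attn(LN(x)) then x + MLP(LN(x)), attention windowed
# (regular or shifted per block parity), MLP expanding by mlp_ratio with GELU
# and optional dropout.

block_fwd <- function(x, p, wi, heads, head_dim, mlp_ratio, dropout,
                      training) {
  n1 <- ln_fwd(x, p$ln1_g, p$ln1_b)
  xp <- n1$y[wi$orig, , drop = FALSE]
  at <- attn_fwd(xp, p, wi, heads, head_dim)
  ya <- matrix(0, nrow(x), ncol(x))
  ya[wi$orig, ] <- at$y
  x1 <- x + ya
  n2 <- ln_fwd(x1, p$ln2_g, p$ln2_b)
  l1 <- lin_fwd(n2$y, p$W1, p$b1)
  ge <- gelu_fwd(l1$y)
  dr <- drop_fwd(ge$y, dropout, training)
  l2 <- lin_fwd(dr$y, p$W2, p$b2)
  y <- x1 + l2$y
  list(y = y, n1 = n1, at = at, n2 = n2, l1 = l1, ge = ge, dr = dr, l2 = l2)
}

block_bwd <- function(dy, cache, p, wi, heads, head_dim) {
  lb2 <- lin_bwd(dy, cache$l2, p$W2)
  dge <- drop_bwd(lb2$dx, cache$dr)
  dl1 <- gelu_bwd(dge, cache$ge)
  lb1 <- lin_bwd(dl1, cache$l1, p$W1)
  nb2 <- ln_bwd(lb1$dx, cache$n2, p$ln2_g)
  dx1 <- dy + nb2$dx
  dya <- dx1[wi$orig, , drop = FALSE]
  ab <- attn_bwd(dya, cache$at, p, wi, heads, head_dim)
  dn1 <- matrix(0, nrow(dy), ncol(dy))
  dn1[wi$orig, ] <- ab$dx
  nb1 <- ln_bwd(dn1, cache$n1, p$ln1_g)
  grads <- list(ln1_g = nb1$dg, ln1_b = nb1$db,
                Wqkv = ab$dWqkv, bqkv = ab$dbqkv,
                Wo = ab$dWo, bo = ab$dbo, bias = ab$dbias,
                ln2_g = nb2$dg, ln2_b = nb2$db,
                W1 = lb1$dW, b1 = lb1$db, W2 = lb2$dW, b2 = lb2$db)
  list(dx = dx1 + nb1$dx, grads = grads)
}

#' One 3D shifted-window transformer block (functional form)
#'
#' Pre-normalized residual structure: layer norm, windowed multi-head
#' self-attention (regular or cyclically shifted), residual add; then layer
#' norm, a GELU MLP expanding the channels by `mlp_ratio`, residual add.
#'
#' @param x channel-first 4D array `(C, d1, d2, d3)`.
#' @param params block parameter list (see [swin3d_init_params()]).
#' @param window window dimensions; `shift` per-axis cyclic shift.
#' @param shift,heads,head_dim attention geometry.
#' @param mlp_ratio MLP expansion factor (default 4).
#' @return Array of the same shape as `x`.
#' @export
swin_block <- function(x, params, window, shift = c(0L, 0L, 0L), heads,
                       head_dim, mlp_ratio = 4) {
  d <- dim(x)
  wi <- window_info(d[2:4], window, shift)
  y <- block_fwd(tok_from_grid(x), params, wi, heads, head_dim, mlp_ratio,
                 dropout = 0, training = FALSE)$y
  grid_from_tok(y, d[2:4])
}
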