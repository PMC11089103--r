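# Low-level neural-network primitives with hand-derived backward passes.
#
# Conventions used throughout:
#   * a feature grid is a numeric array dim c(H, W, C);
#   * a token matrix is N x C with N = H*W, token n <-> (h, w) in
#     column-major order, so `matrix(grid, H * W, C)` and
#     `array(tokens, c(H, W, C))` convert losslessly;
#   * every *_fwd returns list(out, cache); every *_bwd takes the upstream
#     gradient plus the cache and returns list(dx, grads) where grads is a
#     named list matching the parameter names.

grid_to_tokens <- function(x) {
  d <- dim(x)
  list(tok = matrix(x, d[1L] * d[2L], d[3L]), H = d[1L], W = d[2L])
}

tokens_to_grid <- function(tok, H, W) {
  array(tok, c(H, W, ncol(tok)))
}

# add a length-C bias to every row of an N x C matrix
add_bias <- function(m, b) {
  m + rep(b, each = nrow(m))
}

scale_cols <- function(m, s) {
  m * rep(s, each = nrow(m))
}

## ---- im2col / col2im -------------------------------------------------------

conv_out_dim <- function(n, K, S, P) {
  floor((n + 2 * P - K) / S) + 1L
}

# Unfold K x K patches (stride S, zero padding P) of an H x W x C array into
# a (Ho*Wo) x (K*K*C) matrix. Column order: kh fastest, then kw, then channel,
# i.e. the column-major flattening of each K x K x C patch.
im2col <- function(x, K, S, P) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  Ho <- conv_out_dim(H, K, S, P)
  Wo <- conv_out_dim(W, K, S, P)
  if (Ho < 1L || Wo < 1L) stop("input too small for merge: ",
                               H, "x", W, " with K=", K, ", S=", S, ", P=", P)
  Hp <- H + 2L * P; Wp <- W + 2L * P
  pad <- array(0, c(Hp, Wp, C))
  pad[P + seq_len(H), P + seq_len(W), ] <- x
  oh <- (seq_len(Ho) - 1L) * S + 1L
  ow <- (seq_len(Wo) - 1L) * S + 1L
  base <- outer(oh, (ow - 1L) * Hp, "+")                 # Ho x Wo start index
  off  <- outer(seq_len(K) - 1L, (seq_len(K) - 1L) * Hp, "+")  # K x K offsets
  idx  <- outer(as.vector(base), as.vector(off), "+")    # (Ho*Wo) x K^2
  out <- matrix(0, Ho * Wo, K * K * C)
  plane <- Hp * Wp
  for (c in seq_len(C)) {
    pc <- pad[, , c]
    out[, (c - 1L) * K * K + seq_len(K * K)] <- pc[idx]
  }
  list(cols = out, H = H, W = W, C = C, Ho = Ho, Wo = Wo,
       idx = idx, Hp = Hp, Wp = Wp, K = K, P = P)
}

# Scatter-add the gradient of im2col back onto the input grid.
col2im <- function(dcols, meta) {
  K <- meta$K; C <- meta$C
  dpad <- array(0, c(meta$Hp, meta$Wp, C))
  for (c in seq_len(C)) {
    dp <- matrix(0, meta$Hp, meta$Wp)
    cblock <- dcols[, (c - 1L) * K * K + seq_len(K * K), drop = FALSE]
    for (k in seq_len(K * K)) {
      # for a fixed intra-patch offset every output position touches a
      # distinct input pixel, so vectorised += is race-free
      dp[meta$idx[, k]] <- dp[meta$idx[, k]] + cblock[, k]
    }
    dpad[, , c] <- dp
  }
  P <- meta$P
  dpad[P + seq_len(meta$H), P + seq_len(meta$W), , drop = FALSE]
}

## ---- dense / conv layers ---------------------------------------------------

linear_fwd <- function(x, W, b) {
  list(out = add_bias(x %*% W, b), cache = list(x = x, W = W))
}

linear_bwd <- function(dout, cache) {
  list(dx = dout %*% t(cache$W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# 2-D convolution as im2col + matrix multiply. W is (K*K*Cin) x Cout.
conv2d_fwd <- function(x, W, b, K, S, P) {
  ic <- im2col(x, K, S, P)
  out_mat <- add_bias(ic$cols %*% W, b)
  list(out = array(out_mat, c(ic$Ho, ic$Wo, ncol(W))),
       cache = list(ic = ic, W = W))
}

conv2d_bwd <- function(dout, cache) {
  ic <- cache$ic
  dmat <- matrix(dout, ic$Ho * ic$Wo, dim(dout)[3L])
  dW <- crossprod(ic$cols, dmat)
  db <- colSums(dmat)
  dx <- col2im(dmat %*% t(cache$W), ic)
  list(dx = dx, dW = dW, db = db)
}

# Depthwise 3x3 convolution, stride 1, zero padding 1. W is array c(3, 3, C).
dwconv3_fwd <- function(x, W, b) {
  d <- dim(x); H <- d[1L]; Wd <- d[2L]; C <- d[3L]
  pad <- array(0, c(H + 2L, Wd + 2L, C))
  pad[1L + seq_len(H), 1L + seq_len(Wd), ] <- x
  out <- array(rep(b, each = H * Wd), c(H, Wd, C))
  for (kh in 1:3) for (kw in 1:3) {
    win <- pad[kh:(kh + H - 1L), kw:(kw + Wd - 1L), , drop = FALSE]
    out <- out + win * rep(W[kh, kw, ], each = H * Wd)
  }
  list(out = out, cache = list(pad = pad, W = W, H = H, Wd = Wd, C = C))
}

dwconv3_bwd <- function(dout, cache) {
  H <- cache$H; Wd <- cache$Wd; C <- cache$C
  dW <- array(0, c(3, 3, C))
  dpad <- array(0, dim(cache$pad))
  for (kh in 1:3) for (kw in 1:3) {
    win <- cache$pad[kh:(kh + H - 1L), kw:(kw + Wd - 1L), , drop = FALSE]
    dW[kh, kw, ] <- colSums(matrix(win * dout, H * Wd, C))
    dpad[kh:(kh + H - 1L), kw:(kw + Wd - 1L), ] <-
      dpad[kh:(kh + H - 1L), kw:(kw + Wd - 1L), , drop = FALSE] +
      dout * rep(cache$W[kh, kw, ], each = H * Wd)
  }
  list(dx = dpad[1L + seq_len(H), 1L + seq_len(Wd), , drop = FALSE],
       dW = dW,
       db = colSums(matrix(dout, H * Wd, C)))
}

## ---- normalisation / activation -------------------------------------------

layernorm_fwd <- function(x, gamma, beta, eps) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = add_bias(scale_cols(xhat, gamma), beta),
       cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

layernorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dxhat <- scale_cols(dout, cache$gamma)
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx,
       dgamma = colSums(dout * xhat),
       dbeta = colSums(dout))
}

# exact GELU: x * Phi(x)
gelu_fwd <- function(x) {
  list(out = x * pnorm(x), cache = list(x = x))
}

gelu_bwd <- function(dout, cache) {
  x <- cache$x
  list(dx = dout * (pnorm(x) + x * dnorm(x)))
}

softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# inverted dropout; `mask` drawn from the session RNG so training stays seeded
dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = list(mask = NULL)))
  mask <- (matrix(runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache$mask)) list(dx = dout) else list(dx = dout * cache$mask)
}

## ---- resizing --------------------------------------------------------------

# 1-D bilinear interpolation matrix (half-pixel centres, no corner alignment)
interp_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  if (n_out == n_in) { diag(M) <- 1; return(M) }
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale - 0.5 + 1  # 1-based source coordinate
  for (i in seq_len(n_out)) {
    s <- src[i]
    lo <- floor(s)
    w <- s - lo
    lo <- max(1, min(n_in, lo))
    hi <- max(1, min(n_in, lo + 1))
    if (src[i] < 1) { lo <- hi <- 1L; w <- 0 }
    M[i, lo] <- M[i, lo] + (1 - w)
    M[i, hi] <- M[i, hi] + w
  }
  M
}

# 1-D block-average matrix for integer-factor area downsampling
area_matrix <- function(n_in, factor) {
  n_out <- n_in %/% factor
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    M[i, ((i - 1L) * factor + 1L):(i * factor)] <- 1 / factor
  }
  M
}

# bilinear resize of an H x W x C array to Ho x Wo (per-channel linear map)
resize_bilinear <- function(x, Ho, Wo, cache = FALSE) {
  d <- dim(x)
  Rh <- interp_matrix(Ho, d[1L])
  Rw <- interp_matrix(Wo, d[2L])
  out <- array(0, c(Ho, Wo, d[3L]))
  for (c in seq_len(d[3L])) out[, , c] <- Rh %*% x[, , c] %*% t(Rw)
  if (cache) list(out = out, Rh = Rh, Rw = Rw, din = d) else out
}

resize_bilinear_bwd <- function(dout, cache) {
  dx <- array(0, cache$din)
  for (c in seq_len(cache$din[3L])) {
    dx[, , c] <- t(cache$Rh) %*% dout[, , c] %*% cache$Rw
  }
  dx
}

# nearest-neighbour resize; used for label masks, which must never blend
resize_nearest <- function(x, Ho, Wo) {
  H <- nrow(x); W <- ncol(x)
  ih <- pmin(H, pmax(1L, floor((seq_len(Ho) - 0.5) * H / Ho) + 1L))
  iw <- pmin(W, pmax(1L, floor((seq_len(Wo) - 0.5) * W / Wo) + 1L))
  x[ih, iw, drop = FALSE]
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
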