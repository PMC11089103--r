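# Hierarchical Mix-Transformer encoder: overlapped patch merging, efficient
# self-attention with spatial reduction (SRA), and Mix-FFN blocks, producing
# the four-level feature pyramid at 1/4, 1/8, 1/16 and 1/32 of the input
# resolution. All backward passes are derived by hand; no positional
# encoding is used anywhere (the Mix-FFN's depthwise 3x3 convolution leaks
# position through zero padding), so any admissible input size works.

## ---- attention --------------------------------------------------------------

# x: N x C token matrix living on an H x W grid. p: named sublist of block
# parameters (Wq/bq, Wk/bk, Wv/bv, Wo/bo, optionally Wsr/bsr + srnorm.g/b).
attn_fwd <- function(x, H, W, p, heads, R, eps, pdrop = 0, train = FALSE) {
  C <- ncol(x)
  N <- nrow(x)
  q <- linear_fwd(x, p$Wq, p$bq)
  if (R > 1L) {
    if (H %% R != 0L || W %% R != 0L) {
      stop("reduction ratio ", R, " does not tile the ", H, "x", W, " token grid")
    }
    sr_ic <- im2col(tokens_to_grid(x, H, W), R, R, 0L)
    sr_lin <- linear_fwd(sr_ic$cols, p$Wsr, p$bsr)
    sr_ln <- layernorm_fwd(sr_lin$out, p$srnorm.g, p$srnorm.b, eps)
    kv_in <- sr_ln$out
  } else {
    sr_ic <- NULL; sr_lin <- NULL; sr_ln <- NULL
    kv_in <- x
  }
  kf <- linear_fwd(kv_in, p$Wk, p$bk)
  vf <- linear_fwd(kv_in, p$Wv, p$bv)
  d <- C %/% heads
  O <- matrix(0, N, C)
  A <- vector("list", heads)
  for (j in seq_len(heads)) {
    idx <- ((j - 1L) * d + 1L):(j * d)
    S <- tcrossprod(q$out[, idx, drop = FALSE], kf$out[, idx, drop = FALSE]) /
      sqrt(d)
    A[[j]] <- softmax_rows(S)
    O[, idx] <- A[[j]] %*% vf$out[, idx, drop = FALSE]
  }
  o <- linear_fwd(O, p$Wo, p$bo)
  dr <- dropout_fwd(o$out, pdrop, train)
  list(out = dr$out,
       cache = list(q = q, kf = kf, vf = vf, o = o, dr = dr, A = A, O = O,
                    sr_ic = sr_ic, sr_lin = sr_lin, sr_ln = sr_ln,
                    heads = heads, d = d, R = R, H = H, W = W, C = C))
}

attn_bwd <- function(dout, cache) {
  g <- list()
  dout <- dropout_bwd(dout, cache$dr$cache)$dx
  ob <- linear_bwd(dout, cache$o$cache)
  g$Wo <- ob$dW; g$bo <- ob$db
  dO <- ob$dx
  d <- cache$d
  dQ <- matrix(0, nrow(dO), cache$C)
  dK <- matrix(0, nrow(cache$kf$out), cache$C)
  dV <- matrix(0, nrow(cache$vf$out), cache$C)
  for (j in seq_len(cache$heads)) {
    idx <- ((j - 1L) * d + 1L):(j * d)
    A <- cache$A[[j]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$vf$out[, idx, drop = FALSE]
    dV[, idx] <- crossprod(A, dOh)
    dA <- tcrossprod(dOh, Vh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- (dS %*% cache$kf$out[, idx, drop = FALSE]) / sqrt(d)
    dK[, idx] <- (crossprod(dS, cache$q$out[, idx, drop = FALSE])) / sqrt(d)
  }
  kb <- linear_bwd(dK, cache$kf$cache)
  vb <- linear_bwd(dV, cache$vf$cache)
  g$Wk <- kb$dW; g$bk <- kb$db
  g$Wv <- vb$dW; g$bv <- vb$db
  dkv <- kb$dx + vb$dx
  qb <- linear_bwd(dQ, cache$q$cache)
  g$Wq <- qb$dW; g$bq <- qb$db
  dx <- qb$dx
  if (cache$R > 1L) {
    lnb <- layernorm_bwd(dkv, cache$sr_ln$cache)
    g$srnorm.g <- lnb$dgamma; g$srnorm.b <- lnb$dbeta
    srb <- linear_bwd(lnb$dx, cache$sr_lin$cache)
    g$Wsr <- srb$dW; g$bsr <- srb$db
    dgrid <- col2im(srb$dx, cache$sr_ic)
    dx <- dx + matrix(dgrid, cache$H * cache$W, cache$C)
  } else {
    dx <- dx + dkv
  }
  list(dx = dx, grads = g)
}

## ---- Mix-FFN ---------------------------------------------------------------

ffn_fwd <- function(x, H, W, p, pdrop = 0, train = FALSE) {
  f1 <- linear_fwd(x, p$W1, p$b1)
  dw <- dwconv3_fwd(tokens_to_grid(f1$out, H, W), p$Wdw, p$bdw)
  ge <- gelu_fwd(matrix(dw$out, H * W, dim(dw$out)[3L]))
  f2 <- linear_fwd(ge$out, p$W2, p$b2)
  dr <- dropout_fwd(f2$out, pdrop, train)
  list(out = dr$out,
       cache = list(f1 = f1, dw = dw, ge = ge, f2 = f2, dr = dr, H = H, W = W))
}

ffn_bwd <- function(dout, cache) {
  g <- list()
  dout <- dropout_bwd(dout, cache$dr$cache)$dx
  f2b <- linear_bwd(dout, cache$f2$cache)
  g$W2 <- f2b$dW; g$b2 <- f2b$db
  geb <- gelu_bwd(f2b$dx, cache$ge$cache)
  H <- cache$H; W <- cache$W
  dwb <- dwconv3_bwd(array(geb$dx, c(H, W, ncol(geb$dx))), cache$dw$cache)
  g$Wdw <- dwb$dW; g$bdw <- dwb$db
  f1b <- linear_bwd(matrix(dwb$dx, H * W, dim(dwb$dx)[3L]), cache$f1$cache)
  g$W1 <- f1b$dW; g$b1 <- f1b$db
  list(dx = f1b$dx, grads = g)
}

## ---- transformer block (pre-norm, residual) --------------------------------

block_fwd <- function(x, H, W, bp, heads, R, mlp_ratio, eps,
                      pdrop = 0, train = FALSE) {
  n1 <- layernorm_fwd(x, bp$norm1.g, bp$norm1.b, eps)
  at <- attn_fwd(n1$out, H, W,
                 bp[grep("^(W|b|srnorm)", names(bp), value = TRUE)],
                 heads, R, eps, pdrop, train)
  x2 <- x + at$out
  n2 <- layernorm_fwd(x2, bp$norm2.g, bp$norm2.b, eps)
  ff <- ffn_fwd(n2$out, H, W, bp, pdrop, train)
  list(out = x2 + ff$out,
       cache = list(n1 = n1, at = at, n2 = n2, ff = ff))
}

block_bwd <- function(dout, cache) {
  fb <- ffn_bwd(dout, cache$ff$cache)
  n2b <- layernorm_bwd(fb$dx, cache$n2$cache)
  dx2 <- dout + n2b$dx
  ab <- attn_bwd(dx2, cache$at$cache)
  n1b <- layernorm_bwd(ab$dx, cache$n1$cache)
  dx <- dx2 + n1b$dx
  g <- c(fb$grads, ab$grads)
  g$norm1.g <- n1b$dgamma; g$norm1.b <- n1b$dbeta
  g$norm2.g <- n2b$dgamma; g$norm2.b <- n2b$dbeta
  list(dx = dx, grads = g)
}

# pull the parameters of one block out of the flat container
block_params <- function(params, stage, block) {
  pre <- sprintf("enc.s%d.b%d.", stage, block)
  keys <- grep(pre, names(params), fixed = TRUE, value = TRUE)
  p <- params[keys]
  names(p) <- sub(pre, "", names(p), fixed = TRUE)
  names(p) <- sub("^attn\\.", "", names(p))
  names(p) <- sub("^ffn\\.", "", names(p))
  p
}

## ---- encoder ---------------------------------------------------------------

encoder_fwd <- function(image, params, spec, train = FALSE, keep_cache = FALSE) {
  x <- image
  levels <- vector("list", 4L)
  caches <- if (keep_cache) vector("list", 4L) else NULL
  for (i in 1:4) {
    pre <- sprintf("enc.s%d.", i)
    cv <- conv2d_fwd(x, params[[paste0(pre, "embed.W")]],
                     params[[paste0(pre, "embed.b")]],
                     spec$merge_kernels[i], spec$merge_strides[i],
                     spec$merge_paddings[i])
    H <- dim(cv$out)[1L]; W <- dim(cv$out)[2L]
    tok <- matrix(cv$out, H * W, dim(cv$out)[3L])
    ln <- layernorm_fwd(tok, params[[paste0(pre, "embed.g")]],
                        params[[paste0(pre, "embed.be")]], spec$layer_norm_eps)
    tok <- ln$out
    bl <- vector("list", spec$depths[i])
    for (j in seq_len(spec$depths[i])) {
      b <- block_fwd(tok, H, W, block_params(params, i, j),
                     spec$attention_heads[i], spec$sr_ratios[i],
                     spec$mlp_ratio, spec$layer_norm_eps,
                     spec$dropout, train)
      tok <- b$out
      if (keep_cache) bl[[j]] <- b$cache
    }
    sn <- layernorm_fwd(tok, params[[paste0(pre, "norm.g")]],
                        params[[paste0(pre, "norm.b")]], spec$layer_norm_eps)
    levels[[i]] <- structure(tokens_to_grid(sn$out, H, W), stage_index = i)
    if (keep_cache) {
      caches[[i]] <- list(cv = cv, ln = ln, blocks = bl, sn = sn, H = H, W = W)
    }
    x <- tokens_to_grid(sn$out, H, W)
  }
  list(pyramid = new_feature_pyramid(levels), caches = caches)
}

# dlevels: list of 4 gradient arrays matching the pyramid levels
encoder_bwd <- function(dlevels, caches, params, spec) {
  grads <- list()
  dnext <- NULL  # gradient flowing into the *input grid* of stage i+1
  for (i in 4:1) {
    cc <- caches[[i]]
    H <- cc$H; W <- cc$W
    C <- spec$hidden_dims[i]
    dtok <- matrix(dlevels[[i]], H * W, C)
    if (!is.null(dnext)) dtok <- dtok + matrix(dnext, H * W, C)
    pre <- sprintf("enc.s%d.", i)
    snb <- layernorm_bwd(dtok, cc$sn$cache)
    grads[[paste0(pre, "norm.g")]] <- snb$dgamma
    grads[[paste0(pre, "norm.b")]] <- snb$dbeta
    dtok <- snb$dx
    for (j in rev(seq_len(spec$depths[i]))) {
      bb <- block_bwd(dtok, cc$blocks[[j]])
      dtok <- bb$dx
      bp <- sprintf("%sb%d.", pre, j)
      for (k in names(bb$grads)) {
        key <- if (grepl("^norm[12]", k)) paste0(bp, k)
               else if (grepl("^(W[12]|b[12]|Wdw|bdw)$", k)) paste0(bp, "ffn.", k)
               else paste0(bp, "attn.", k)
        grads[[key]] <- bb$grads[[k]]
      }
    }
    lnb <- layernorm_bwd(dtok, cc$ln$cache)
    grads[[paste0(pre, "embed.g")]] <- lnb$dgamma
    grads[[paste0(pre, "embed.be")]] <- lnb$dbeta
    cvb <- conv2d_bwd(array(lnb$dx, c(H, W, C)), cc$cv$cache)
    grads[[paste0(pre, "embed.W")]] <- cvb$dW
    grads[[paste0(pre, "embed.b")]] <- cvb$db
    dnext <- cvb$dx
  }
  list(dimage = dnext, grads = grads)
}

## ---- public operations -----------------------------------------------------

new_feature_pyramid <- function(levels) {
  stopifnot(length(levels) == 4L)
  structure(list(levels = levels), class = "feature_pyramid")
}

#' @export
print.feature_pyramid <- function(x, ...) {
  cat("Feature pyramid (4 levels):\n")
  for (i in 1:4) {
    d <- dim(x$levels[[i]])
    cat(sprintf("  F%d: %d x %d x %d\n", i, d[1L], d[2L], d[3L]))
  }
  invisible(x)
}

#' Overlapped patch merging
#'
#' Projects overlapping K x K patches (stride S, zero padding P) of an image
#' or feature grid to `c_out` channels and layer-normalises the result. With
#' K > S adjacent patches overlap, preserving local continuity around patch
#' borders; spatial dims shrink to `floor((dim + 2P - K)/S) + 1`.
#'
#' @param x numeric array H x W x C.
#' @param K,S,P patch size, stride and padding (K >= S required).
#' @param c_out output channel width.
#' @param params optional list with entries `W` ((K*K*C) x c_out), `b`, `g`,
#'   `be`; freshly initialised under `seed` when omitted.
#' @param eps layer-norm epsilon.
#' @param seed RNG seed for fresh weights.
#' @return merged feature grid, array Ho x Wo x c_out.
#' @export
overlapped_patch_merge <- function(x, K, S, P, c_out, params = NULL,
                                   eps = 1e-6, seed = 1L) {
  if (K < S) stop("merge kernel must be >= stride (overlap)")
  if (P < 0) stop("padding must be non-negative")
  C <- dim(x)[3L]
  if (is.null(params)) {
    set.seed(seed)
    sd <- sqrt(2 / (K * K * C + c_out))
    params <- list(W = matrix(rnorm(K * K * C * c_out, sd = sd), K * K * C),
                   b = rep(0, c_out), g = rep(1, c_out), be = rep(0, c_out))
  }
  cv <- conv2d_fwd(x, params$W, params$b, K, S, P)
  d <- dim(cv$out)
  ln <- layernorm_fwd(matrix(cv$out, d[1L] * d[2L], d[3L]),
                      params$g, params$be, eps)
  structure(array(ln$out, d), merged = TRUE)
}

#' Efficient self-attention with spatial reduction (SRA)
#'
#' Multi-head self-attention whose key/value sequence is first shortened by
#' a factor R^2: the token grid is reshaped into non-overlapping R x R
#' groups of R^2*C features, projected back to C and layer-normalised. Cost
#' drops from O(N^2) to O(N^2 / R^2); R = 1 is exact full attention.
#'
#' @param x token matrix N x C with N = H*W.
#' @param H,W token grid dimensions.
#' @param heads number of attention heads (must divide C).
#' @param R per-dimension reduction ratio (must tile the grid).
#' @param params optional attention parameter list; fresh weights under
#'   `seed` when omitted.
#' @param eps layer-norm epsilon.
#' @param seed RNG seed for fresh weights.
#' @return token matrix N x C.
#' @export
efficient_self_attention <- function(x, H, W, heads, R, params = NULL,
                                     eps = 1e-6, seed = 1L) {
  C <- ncol(x)
  if (C %% heads != 0L) stop("channels must be divisible by heads")
  if (nrow(x) != H * W) stop("token count must equal H*W")
  if (is.null(params)) {
    set.seed(seed)
    sd <- sqrt(1 / C)
    mk <- function(nr, nc) matrix(rnorm(nr * nc, sd = sd), nr, nc)
    params <- list(Wq = mk(C, C), bq = rep(0, C), Wk = mk(C, C), bk = rep(0, C),
                   Wv = mk(C, C), bv = rep(0, C), Wo = mk(C, C), bo = rep(0, C))
    if (R > 1L) {
      params$Wsr <- mk(R * R * C, C); params$bsr <- rep(0, C)
      params$srnorm.g <- rep(1, C); params$srnorm.b <- rep(0, C)
    }
  }
  attn_fwd(x, H, W, params, heads, R, eps)$out
}

#' Mix-FFN feed-forward block
#'
#' `MLP -> depthwise 3x3 convolution on the token grid -> GELU -> MLP`, with
#' hidden width `mlp_ratio * C`. The zero-padded convolution injects
#' positional information, so no explicit positional encoding is needed.
#' (The caller adds the residual connection.)
#'
#' @param x token matrix N x C with N = H*W.
#' @param H,W token grid dimensions.
#' @param mlp_ratio hidden expansion factor.
#' @param params optional parameter list (`W1`, `b1`, `Wdw`, `bdw`, `W2`,
#'   `b2`); fresh weights under `seed` when omitted.
#' @param seed RNG seed for fresh weights.
#' @return token matrix N x C.
#' @export
mix_ffn <- function(x, H, W, mlp_ratio = 4L, params = NULL, seed = 1L) {
  C <- ncol(x)
  if (nrow(x) != H * W) stop("token sequence not reshapeable to ", H, "x", W,
                             " grid")
  hid <- mlp_ratio * C
  if (is.null(params)) {
    set.seed(seed)
    params <- list(W1 = matrix(rnorm(C * hid, sd = sqrt(2 / (C + hid))), C),
                   b1 = rep(0, hid),
                   Wdw = array(rnorm(9 * hid, sd = sqrt(2 / (9 + 1))), c(3, 3, hid)),
                   bdw = rep(0, hid),
                   W2 = matrix(rnorm(hid * C, sd = sqrt(2 / (C + hid))), hid),
                   b2 = rep(0, C))
  }
  ffn_fwd(x, H, W, params)$out
}

#' Encode an image into the four-level feature pyramid
#'
#' Runs the full hierarchical encoder: four stages of overlapped patch
#' merging followed by `depths[i]` transformer blocks (SRA attention +
#' Mix-FFN) and a closing layer normalisation, yielding features at 1/4,
#' 1/8, 1/16 and 1/32 of the input resolution with channel widths
#' `hidden_dims`.
#'
#' @param image numeric array H x W x 3, H and W at least 32.
#' @param spec a validated `mit_spec`.
#' @param params flat parameter container from [init_params()]; freshly
#'   initialised under `seed` when omitted.
#' @param seed RNG seed for fresh weights.
#' @return a `feature_pyramid` object (list of 4 arrays `levels`).
#' @examples
#' spec <- resolve_spec("mit-b0")
#' img <- array(runif(64 * 64 * 3), c(64, 64, 3))
#' pyr <- encode(img, spec)
#' sapply(pyr$levels, function(f) dim(f)[1])  # 16 8 4 2
#' @export
encode <- function(image, spec, params = NULL, seed = 1L) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) stop("image must be H x W x 3")
  if (d[1L] < 32L || d[2L] < 32L) stop("image smaller than minimum 32 x 32")
  spec <- validate_spec(spec)
  if (is.null(params)) params <- init_params(spec, "encoder", seed)
  encoder_fwd(image, params, spec)$pyramid
}

## ---- checkpoint container --------------------------------------------------

#' Save / load a flat weight checkpoint
#'
#' Weights live in a flat `key -> array` named list (keys like
#' `enc.s1.b2.attn.Wq`, `dec.cls.W`), so externally trained MiT weights can
#' be mapped in by renaming keys. Stored via R serialisation.
#'
#' @param params named list of numeric arrays.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the parameter list.
#' @export
save_checkpoint <- function(params, path) {
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
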