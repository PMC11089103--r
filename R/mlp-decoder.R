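# Lightweight all-MLP decoder: each pyramid level is linearly mapped to a
# unified width C, bilinearly upsampled to the 1/4-resolution grid of F1,
# concatenated (4C channels), fused back to C, passed through GELU (the
# decoder's hidden activation) and projected to one logit per class,
# yielding an H/4 x W/4 x N_Cats logit map.

decoder_fwd <- function(pyramid, params, spec, train = FALSE,
                        keep_cache = FALSE) {
  lv <- pyramid$levels
  H1 <- dim(lv[[1L]])[1L]; W1 <- dim(lv[[1L]])[2L]
  Cd <- spec$decoder_dim
  lins <- vector("list", 4L)
  ups <- vector("list", 4L)
  cat_mat <- matrix(0, H1 * W1, 4L * Cd)
  for (i in 1:4) {
    d <- dim(lv[[i]])
    tok <- matrix(lv[[i]], d[1L] * d[2L], d[3L])
    lf <- linear_fwd(tok, params[[sprintf("dec.lin%d.W", i)]],
                     params[[sprintf("dec.lin%d.b", i)]])
    grid <- array(lf$out, c(d[1L], d[2L], Cd))
    if (i == 1L) {
      up <- list(out = grid)
    } else {
      up <- resize_bilinear(grid, H1, W1, cache = TRUE)
    }
    cat_mat[, ((i - 1L) * Cd + 1L):(i * Cd)] <- matrix(up$out, H1 * W1, Cd)
    lins[[i]] <- lf; ups[[i]] <- up
  }
  fu <- linear_fwd(cat_mat, params[["dec.fuse.W"]], params[["dec.fuse.b"]])
  ge <- gelu_fwd(fu$out)
  dr <- dropout_fwd(ge$out, spec$dropout, train)
  cl <- linear_fwd(dr$out, params[["dec.cls.W"]], params[["dec.cls.b"]])
  out <- array(cl$out, c(H1, W1, spec$num_classes))
  cache <- if (keep_cache) {
    list(lins = lins, ups = ups, fu = fu, ge = ge, dr = dr, cl = cl,
         H1 = H1, W1 = W1, ldims = lapply(lv, dim), Cd = Cd)
  }
  list(out = out, cache = cache)
}

decoder_bwd <- function(dout, cache, spec) {
  g <- list()
  H1 <- cache$H1; W1 <- cache$W1; Cd <- cache$Cd
  dcl <- matrix(dout, H1 * W1, dim(dout)[3L])
  clb <- linear_bwd(dcl, cache$cl$cache)
  g[["dec.cls.W"]] <- clb$dW; g[["dec.cls.b"]] <- clb$db
  ddr <- dropout_bwd(clb$dx, cache$dr$cache)$dx
  dge <- gelu_bwd(ddr, cache$ge$cache)$dx
  fub <- linear_bwd(dge, cache$fu$cache)
  g[["dec.fuse.W"]] <- fub$dW; g[["dec.fuse.b"]] <- fub$db
  dlevels <- vector("list", 4L)
  for (i in 1:4) {
    dcat <- fub$dx[, ((i - 1L) * Cd + 1L):(i * Cd), drop = FALSE]
    dgrid_up <- array(dcat, c(H1, W1, Cd))
    dgrid <- if (i == 1L) dgrid_up else resize_bilinear_bwd(dgrid_up, cache$ups[[i]])
    d <- cache$ldims[[i]]
    lb <- linear_bwd(matrix(dgrid, d[1L] * d[2L], Cd), cache$lins[[i]]$cache)
    g[[sprintf("dec.lin%d.W", i)]] <- lb$dW
    g[[sprintf("dec.lin%d.b", i)]] <- lb$db
    dlevels[[i]] <- array(lb$dx, d)
  }
  list(dlevels = dlevels, grads = g)
}

#' Decode a feature pyramid into a class-logit map
#'
#' Fuses the four multi-scale encoder features into per-class logits on the
#' 1/4-resolution grid: per-level linear projection to `decoder_dim`
#' channels, bilinear upsampling to the F1 grid, channel concatenation, a
#' fusing linear layer with GELU, and a final linear classifier.
#'
#' @param pyramid a `feature_pyramid` from [encode()].
#' @param spec a validated `mit_spec` (supplies `decoder_dim` and
#'   `num_classes`).
#' @param params flat parameter container holding the `dec.*` keys; freshly
#'   initialised under `seed` when omitted.
#' @param seed RNG seed for fresh weights.
#' @return logit map, numeric array H/4 x W/4 x num_classes.
#' @export
decode <- function(pyramid, spec, params = NULL, seed = 1L) {
  if (!inherits(pyramid, "feature_pyramid")) stop("need a feature_pyramid")
  spec <- validate_spec(spec)
  dims <- vapply(pyramid$levels, function(f) dim(f)[3L], integer(1))
  if (!identical(dims, spec$hidden_dims)) {
    stop("pyramid channel widths ", paste(dims, collapse = ","),
         " do not match spec hidden_dims")
  }
  if (is.null(params)) params <- init_params(spec, "decoder", seed)
  decoder_fwd(pyramid, params, spec)$out
}

#' Upsample a logit map to full resolution
#'
#' Bilinearly interpolates the 1/4-resolution logit map to the target size;
#' the per-pixel argmax of the result defines the predicted mask.
#'
#' @param logits numeric array h x w x K.
#' @param H,W target spatial size (each at least the logit dims).
#' @return numeric array H x W x K.
#' @export
upsample_logits <- function(logits, H, W) {
  d <- dim(logits)
  if (H < d[1L] || W < d[2L]) stop("target must be at least the logit dims")
  resize_bilinear(logits, H, W)
}

#' Convert a logit map to a predicted class mask
#'
#' @param logits numeric array H x W x K.
#' @return integer matrix H x W with 0-based class indices (argmax).
#' @export
logits_to_mask <- function(logits) {
  d <- dim(logits)
  m <- max.col(matrix(logits, d[1L] * d[2L], d[3L]), ties.method = "first") - 1L
  matrix(m, d[1L], d[2L])
}
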