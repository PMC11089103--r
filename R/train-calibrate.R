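# Seeded training loop (pixelwise cross-entropy on logits bilinearly
# upsampled to mask resolution, Adam), temperature-scaling calibration and
# per-pixel uncertainty maps.

#' Training configuration
#'
#' Defaults follow the study's setting: batches of 8 for 50 epochs with
#' Adam at learning rate 6e-4, dropout 0.1 and layer-norm epsilon 1e-6.
#' There is no learning-rate schedule and no weight decay. Pixels flagged
#' invalid (tile padding) are ignored by the loss.
#'
#' @param batch_size images per gradient step.
#' @param epochs passes over the training set.
#' @param learning_rate Adam step size.
#' @param dropout dropout rate applied in attention/Mix-FFN outputs and the
#'   decoder hidden layer during training.
#' @param layer_norm_eps layer normalisation epsilon.
#' @param seed RNG seed covering initialisation, shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 8L, epochs = 50L,
                         learning_rate = 6e-4, dropout = 0.1,
                         layer_norm_eps = 1e-6, seed = 1L) {
  stopifnot(batch_size >= 1L, epochs >= 1L, learning_rate > 0,
            learning_rate < 1, dropout >= 0, dropout <= 1, layer_norm_eps > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 optimizer = "adam", learning_rate = learning_rate,
                 dropout = dropout, layer_norm_eps = layer_norm_eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Construct an untrained segmentation model
#'
#' @param spec a validated `mit_spec`.
#' @param seed RNG seed for weight initialisation.
#' @return a `seg_model`: list with `spec` and flat `params`.
#' @export
seg_model <- function(spec, seed = 1L) {
  spec <- validate_spec(spec)
  structure(list(spec = spec, params = init_params(spec, "full", seed)),
            class = "seg_model")
}

# cross-entropy over valid pixels; labels 0-based; returns loss + dlogits
ce_loss <- function(logits_full, labels, valid) {
  d <- dim(logits_full)
  K <- d[3L]
  L <- matrix(logits_full, d[1L] * d[2L], K)
  lab <- as.vector(labels) + 1L
  v <- as.vector(valid)
  m <- apply(L, 1L, max)
  e <- exp(L - m)
  se <- rowSums(e)
  p <- e / se
  nv <- sum(v)
  if (nv == 0L) stop("no valid pixels")
  picked <- (L - m - log(se))[cbind(seq_along(lab), lab)]
  loss <- -sum(picked[v]) / nv
  dL <- p
  dL[cbind(seq_along(lab), lab)] <- dL[cbind(seq_along(lab), lab)] - 1
  dL[!v, ] <- 0
  list(loss = loss, dlogits = array(dL / nv, d))
}

# full forward + backward for one image; returns loss and parameter grads
model_grad_step <- function(params, spec, image, labels, valid, train = TRUE) {
  ef <- encoder_fwd(image, params, spec, train = train, keep_cache = TRUE)
  df <- decoder_fwd(ef$pyramid, params, spec, train = train, keep_cache = TRUE)
  up <- resize_bilinear(df$out, nrow(labels), ncol(labels), cache = TRUE)
  cl <- ce_loss(up$out, labels, valid)
  dlog <- resize_bilinear_bwd(cl$dlogits, up)
  db <- decoder_bwd(dlog, df$cache, spec)
  eb <- encoder_bwd(db$dlevels, ef$caches, params, spec)
  list(loss = cl$loss, grads = c(db$grads, eb$grads))
}

#' Train a segmentation model
#'
#' Minimises pixelwise cross-entropy between the mask and the decoder
#' logits bilinearly upsampled to mask resolution; padded pixels (a tile's
#' `valid` mask) are excluded. Optimisation is Adam at the configured rate,
#' gradients averaged over each batch. Deterministic given the config seed
#' (single-threaded BLAS assumed for bitwise identity).
#'
#' @param model a `seg_model`.
#' @param train_set,val_set lists of `labeled_specimen` or tiles (lists with
#'   `image`, `mask` and optionally `valid`).
#' @param config a `train_config`.
#' @return the trained `seg_model`, with a `history` data frame (per-epoch
#'   mean train loss and validation mIoU) attached as `model$history`.
#' @export
train <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "seg_model"), length(train_set) >= 1L)
  spec <- model$spec
  spec$dropout <- config$dropout
  spec$layer_norm_eps <- config$layer_norm_eps
  K <- spec$num_classes
  for (s in c(train_set, val_set)) {
    if (any(s$mask >= K)) stop("class index >= num_classes found in data")
  }
  params <- model$params
  state <- adam_init(params)
  set.seed(config$seed)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_miou = numeric())
  n <- length(train_set)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    b0 <- 1L
    while (b0 <= n) {
      ix <- ord[b0:min(n, b0 + config$batch_size - 1L)]
      acc <- NULL
      bl <- 0
      for (i in ix) {
        s <- train_set[[i]]
        valid <- s$valid %||% matrix(TRUE, nrow(s$mask), ncol(s$mask))
        g <- model_grad_step(params, spec, s$image, s$mask, valid)
        bl <- bl + g$loss
        acc <- if (is.null(acc)) g$grads else {
          for (k in names(acc)) acc[[k]] <- acc[[k]] + g$grads[[k]]
          acc
        }
      }
      for (k in names(acc)) acc[[k]] <- acc[[k]] / length(ix)
      upd <- adam_step(params, acc, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, bl / length(ix))
      b0 <- b0 + config$batch_size
    }
    val_miou <- if (length(val_set)) {
      m2 <- model; m2$params <- params
      evaluate_set(m2, val_set)$mean_iou
    } else NA_real_
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(losses),
                                         val_miou = val_miou))
  }
  model$params <- params
  model$history <- history
  model
}

#' Predict segmentation for one image
#'
#' @param model a `seg_model`.
#' @param image numeric array H x W x 3.
#' @param temperature positive scalar dividing the logits before softmax
#'   (1 = uncalibrated).
#' @return list with `logits` (H/4-resolution), `logits_full`, `probs`
#'   (H x W x K softmax), and `mask` (H x W argmax, 0-based).
#' @export
predict_seg <- function(model, image, temperature = 1) {
  stopifnot(temperature > 0, is.finite(temperature))
  ef <- encoder_fwd(image, model$params, model$spec)
  lg <- decoder_fwd(ef$pyramid, model$params, model$spec)$out
  lf <- upsample_logits(lg, dim(image)[1L], dim(image)[2L])
  d <- dim(lf)
  P <- softmax_rows(matrix(lf / temperature, d[1L] * d[2L], d[3L]))
  list(logits = lg, logits_full = lf,
       probs = array(P, d), mask = logits_to_mask(lf))
}

# confusion-matrix based mIoU of a model over a set (used for history)
evaluate_set <- function(model, set, temperature = 1) {
  K <- model$spec$num_classes
  cm <- matrix(0, K, K)
  for (s in set) {
    pr <- predict_seg(model, s$image, temperature)
    valid <- s$valid %||% matrix(TRUE, nrow(s$mask), ncol(s$mask))
    cm <- cm + confusion(pr$mask, s$mask, K, valid)
  }
  cm <- as_confusion(cm)
  list(confusion = cm, mean_iou = mean_iou(cm),
       average_accuracy = average_accuracy(cm), f1 = f1_scores(cm))
}

## ---- temperature scaling ---------------------------------------------------

#' Fit a calibration temperature on validation logits
#'
#' One-dimensional search for the temperature T minimising the negative
#' log-likelihood of `softmax(logits / T)` against the validation labels
#' (the standard post-hoc calibration; the NLL is convex in 1/T). Dividing
#' by a positive scalar never reorders logits, so argmax predictions — and
#' hence accuracy and mIoU — are unchanged by calibration.
#'
#' @param val_logits numeric matrix N x K of uncalibrated logits (or an
#'   H x W x K array).
#' @param val_labels integer vector/matrix of 0-based labels, length N.
#' @return a `calibrated_predictor` stub: list with `temperature` and the
#'   achieved `nll`; attach to a model via [predict_seg()]'s `temperature`.
#' @export
fit_temperature <- function(val_logits, val_labels) {
  if (length(dim(val_logits)) == 3L) {
    d <- dim(val_logits)
    val_logits <- matrix(val_logits, d[1L] * d[2L], d[3L])
  }
  lab <- as.vector(val_labels) + 1L
  stopifnot(nrow(val_logits) == length(lab))
  if (length(unique(lab)) < 2L) {
    warning("single-class validation labels; temperature fixed at 1")
    return(structure(list(temperature = 1, nll = nll_at(val_logits, lab, 1)),
                     class = "calibrated_predictor"))
  }
  opt <- stats::optimize(function(logT) nll_at(val_logits, lab, exp(logT)),
                         interval = c(log(0.05), log(50)), tol = 1e-6)
  t_star <- exp(opt$minimum)
  if (opt$objective > nll_at(val_logits, lab, 1)) t_star <- 1
  structure(list(temperature = t_star,
                 nll = nll_at(val_logits, lab, t_star)),
            class = "calibrated_predictor")
}

nll_at <- function(logits, lab1, temp) {
  L <- logits / temp
  m <- apply(L, 1L, max)
  lse <- m + log(rowSums(exp(L - m)))
  -mean(L[cbind(seq_along(lab1), lab1)] - lse)
}

#' Per-pixel uncertainty map
#'
#' One minus the maximum calibrated class probability per pixel: 0 where
#' the model is certain, up to `1 - 1/K` where the posterior is uniform.
#' High values concentrate on tissue boundaries and complex regions.
#'
#' @param probs numeric array H x W x K of class probabilities (rows must
#'   sum to 1 within 1e-4).
#' @return numeric matrix H x W in `[0, 1 - 1/K]`.
#' @export
uncertainty_map <- function(probs) {
  d <- dim(probs)
  P <- if (length(d) == 3L) matrix(probs, d[1L] * d[2L], d[3L]) else probs
  if (any(abs(rowSums(P) - 1) > 1e-4)) {
    stop("probability rows do not sum to 1")
  }
  u <- 1 - apply(P, 1L, max)
  if (length(d) == 3L) matrix(u, d[1L], d[2L]) else u
}

#' Write an uncertainty map as PNG
#'
#' Grey-scale map (u scaled to 0..255) plus an optional colour-mapped
#' overlay on the source image.
#'
#' @param u numeric matrix from [uncertainty_map()].
#' @param path output PNG path.
#' @param image optional H x W x 3 image for a red-tinted overlay written
#'   next to `path` (suffix `_overlay.png`).
#' @return `path` invisibly.
#' @export
write_uncertainty_png <- function(u, path, image = NULL) {
  png::writePNG(u / max(1e-12, 1), path)
  if (!is.null(image)) {
    ov <- image
    ov[, , 1L] <- pmin(1, image[, , 1L] + u)
    ov[, , 2L] <- image[, , 2L] * (1 - 0.6 * u)
    ov[, , 3L] <- image[, , 3L] * (1 - 0.6 * u)
    png::writePNG(ov, sub("\\.png$", "_overlay.png", path))
  }
  invisible(path)
}
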