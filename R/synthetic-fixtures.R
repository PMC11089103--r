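# Synthetic pseudo-histology specimens: background-dominant canvases with a
# wobbly tissue blob whose anatomically ordered bands (keratin/epidermis at
# the rim, papillary then reticular dermis inside, hypodermis deepest) carry
# the dataset's class-frequency profile, plus lesion blobs (one of the three
# carcinomas) and small gland/follicle/inflammation islands. Textures are
# flat per-class colours with correlated Gaussian noise: enough signal for a
# segmentation model to learn from, with no pretence of stain physics.

#' Published class-frequency profile
#'
#' Pixel-share of each class in the 290-slide dataset, used as the default
#' generator target (background dominates at 58.6%).
#'
#' @return named numeric vector over the 12 classes, summing to 1.
#' @export
dataset_class_frequencies <- function() {
  f <- c(BCC = 0.011, SCC = 0.024, IEC = 0.010, GLD = 0.004, FOL = 0.002,
         INF = 0.028, RET = 0.198, HYP = 0.093, PAP = 0.017, EPI = 0.006,
         KER = 0.021, BKG = 0.586)
  f / sum(f)
}

#' Build a fixture recipe
#'
#' @param seed integer RNG seed; the whole specimen is a deterministic
#'   function of the recipe.
#' @param size canvas edge in pixels (square canvas, at least 64).
#' @param class_freqs target class-frequency vector over the 12 classes
#'   (non-negative, summing to ~1).
#' @param n_lesions number of carcinoma blobs to place.
#' @param noise_sd pixel noise standard deviation before blurring.
#' @param cancer_type which carcinoma the lesions carry.
#' @return a `fixture_recipe` list.
#' @export
fixture_recipe <- function(seed = 1L, size = 128L,
                           class_freqs = dataset_class_frequencies(),
                           n_lesions = 2L, noise_sd = 0.06,
                           cancer_type = c("BCC", "SCC", "IEC")) {
  cancer_type <- match.arg(cancer_type)
  if (size < 64L) stop("canvas must be at least 64 x 64")
  if (length(class_freqs) != 12L || any(class_freqs < 0)) {
    stop("infeasible frequency vector: need 12 non-negative frequencies")
  }
  if (abs(sum(class_freqs) - 1) > 0.02) {
    stop("infeasible frequency vector: frequencies must sum to ~1")
  }
  if (class_freqs[["BKG"]] <= 0) stop("infeasible frequency vector: BKG <= 0")
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 class_freqs = class_freqs, n_lesions = as.integer(n_lesions),
                 noise_sd = noise_sd, cancer_type = cancer_type),
            class = "fixture_recipe")
}

# muted H&E-flavoured base colours per class (rows: class order, cols RGB)
fixture_base_colors <- function() {
  rbind(BCC = c(0.45, 0.25, 0.55), SCC = c(0.75, 0.45, 0.60),
        IEC = c(0.55, 0.30, 0.45), GLD = c(0.80, 0.65, 0.80),
        FOL = c(0.55, 0.45, 0.30), INF = c(0.35, 0.30, 0.60),
        RET = c(0.90, 0.70, 0.75), HYP = c(0.95, 0.85, 0.70),
        PAP = c(0.85, 0.60, 0.70), EPI = c(0.60, 0.40, 0.70),
        KER = c(0.90, 0.55, 0.40), BKG = c(0.97, 0.96, 0.97))
}

# separable Gaussian blur of a matrix (reflecting edges)
gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(r)]), v, rev(v[(n - r + 1L):n]))
    stats::filter(vp, k, sides = 2L)[(r + 1L):(r + n)]
  }
  m <- apply(m, 2L, pad_conv)
  t(apply(t(m), 2L, pad_conv))
}

#' Generate one synthetic labeled specimen
#'
#' Deterministic in the recipe seed. The mask is the exact set of generating
#' labels; the image is the per-class base colour plus correlated noise.
#' The realised background fraction tracks the recipe's BKG target (the
#' generator contract is within 10 percentage points).
#'
#' @param recipe a `fixture_recipe`.
#' @param id,cancer_type,biopsy_type,resolution_factor metadata passed to
#'   [labeled_specimen()]; `cancer_type` defaults to the recipe's.
#' @return a `labeled_specimen`.
#' @export
generate_specimen <- function(recipe, id = sprintf("fix%04d", recipe$seed),
                              cancer_type = recipe$cancer_type,
                              biopsy_type = "excision",
                              resolution_factor = 10L) {
  set.seed(recipe$seed)
  n <- recipe$size
  f <- recipe$class_freqs
  cls <- function(name) match(name, mitseg_classes) - 1L

  # wobbly elliptical tissue blob occupying ~ (1 - BKG) of the canvas
  tissue_frac <- 1 - f[["BKG"]]
  cy <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  cx <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  aspect <- stats::runif(1, 0.75, 1.3)
  area <- tissue_frac * n * n
  a <- sqrt(area / pi * aspect)
  b <- sqrt(area / pi / aspect)
  theta <- stats::runif(1, 0, pi)
  nw <- 3L + sample.int(3L, 1L)          # boundary wobble harmonics
  amp <- stats::runif(nw, 0.02, 0.06)
  phs <- stats::runif(nw, 0, 2 * pi)
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  dy <- yy - cy; dx <- xx - cx
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  rho <- sqrt((u / a)^2 + (v / b)^2)     # 1 at the nominal boundary
  ang <- atan2(v / b, u / a)
  wob <- Reduce(`+`, lapply(seq_len(nw), function(k) {
    amp[k] * cos((k + 1L) * ang + phs[k])
  }))
  rho <- rho / (1 + wob)

  # nested bands from the rim inwards: KER, EPI, PAP, RET, HYP. For the
  # wobbled ellipse the area inside rho <= t scales ~ t^2, so thresholds are
  # square roots of cumulative inner shares.
  band_order <- c("KER", "EPI", "PAP", "RET", "HYP")
  band_f <- f[band_order]
  # lesions and islands are stamped into RET/HYP later; reserve their area
  stamp <- sum(f[c("BCC", "SCC", "IEC", "GLD", "FOL", "INF")])
  band_f[["RET"]] <- band_f[["RET"]] + 0.6 * stamp
  band_f[["HYP"]] <- band_f[["HYP"]] + 0.4 * stamp
  shares <- band_f / sum(band_f)
  inner_cum <- rev(cumsum(rev(shares)))  # share inside each band's outer edge
  thr <- sqrt(inner_cum)                 # outer rho threshold per band
  # thin rims (epidermis, keratin) must survive pixelisation: enforce a
  # minimum band width of ~2 px in rho units
  r_char <- sqrt(area / pi)
  wmin <- 2 / r_char
  for (i in 2:length(thr)) thr[i] <- min(thr[i], thr[i - 1L] - wmin)
  mask <- matrix(cls("BKG"), n, n)
  for (i in seq_along(band_order)) {
    sel <- rho <= thr[i]
    mask[sel] <- cls(band_order[i])
  }

  # carcinoma lesions: discs seeded in the dermis (RET band); every
  # carcinoma class with a positive target frequency gets at least one blob,
  # the recipe's cancer_type first
  carc <- c("BCC", "SCC", "IEC")
  carc <- unique(c(cancer_type, carc[f[carc] > 0]))
  if (recipe$n_lesions > 0L && length(carc)) {
    per_type <- pmax(1L, largest_remainder(max(recipe$n_lesions, length(carc)),
                                           f[carc] / sum(f[carc])))
    for (t in seq_along(carc)) {
      r_les <- max(2, sqrt(f[[carc[t]]] * n * n / per_type[t] / pi))
      for (l in seq_len(per_type[t])) {
        host <- which(mask == cls("RET"), arr.ind = TRUE)
        if (nrow(host) == 0L) break
        ctr <- host[sample.int(nrow(host), 1L), ]
        d2 <- (yy - ctr[1L])^2 + (xx - ctr[2L])^2
        mask[d2 <= r_les^2 & mask != cls("BKG")] <- cls(carc[t])
      }
    }
  }

  # small adnexal / inflammatory islands inside the dermis and hypodermis
  for (isl in c("GLD", "FOL", "INF")) {
    r_isl <- max(1.6, sqrt(f[[isl]] * n * n / pi))
    dermal <- mask == cls("RET") | mask == cls("HYP")
    host <- which(dermal, arr.ind = TRUE)
    if (nrow(host) == 0L) next
    ctr <- host[sample.int(nrow(host), 1L), ]
    d2 <- (yy - ctr[1L])^2 + (xx - ctr[2L])^2
    mask[d2 <= r_isl^2 & dermal] <- cls(isl)
  }

  base <- fixture_base_colors()
  img <- array(0, c(n, n, 3L))
  for (ch in 1:3) {
    noise <- gauss_blur(matrix(stats::rnorm(n * n, sd = recipe$noise_sd), n), 1.5)
    img[, , ch] <- pmin(1, pmax(0, matrix(base[mask + 1L, ch], n) + noise))
  }
  labeled_specimen(img, mask, id = id, cancer_type = cancer_type,
                   biopsy_type = biopsy_type,
                   resolution_factor = resolution_factor)
}

#' Generate a synthetic dataset
#'
#' Cancer types follow the study's 140:60:90 BCC:SCC:IEC slide mix and
#' biopsy types the 100:58:132 shave:punch:excision mix (largest-remainder
#' apportionment, seeded shuffle). Fully reproducible from `seed`.
#'
#' @param n number of specimens (>= 1).
#' @param seed integer RNG seed.
#' @param mix cancer-type proportions (normalised internally).
#' @param size canvas edge per specimen.
#' @return list of `labeled_specimen` objects.
#' @export
generate_dataset <- function(n, seed = 1L,
                             mix = c(BCC = 140, SCC = 60, IEC = 90),
                             size = 128L) {
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  cancer <- rep(c("BCC", "SCC", "IEC"), largest_remainder(n, mix / sum(mix)))
  biopsy_mix <- c(shave = 100, punch = 58, excision = 132)
  biopsy <- rep(names(biopsy_mix), largest_remainder(n, biopsy_mix / sum(biopsy_mix)))
  cancer <- sample(cancer)
  biopsy <- sample(biopsy)
  seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) {
    generate_specimen(
      fixture_recipe(seed = seeds[i], size = size, cancer_type = cancer[i]),
      id = sprintf("fix%04d", i),
      cancer_type = cancer[i], biopsy_type = biopsy[i])
  })
}
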