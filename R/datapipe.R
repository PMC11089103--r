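# Dataset handling: the 12-class palette mask codec, resolution variants,
# tiling/stitching for patch-based inference, stratified splitting, and the
# 8-fold dihedral augmentation.

#' The twelve tissue / lesion classes
#'
#' Class order fixes the integer coding 0..11 used in every mask: the three
#' non-melanoma carcinomas (BCC basal cell, SCC squamous cell, IEC
#' intraepidermal), glands (GLD), hair follicles (FOL), inflammation (INF),
#' reticular dermis (RET), hypodermis (HYP), papillary dermis (PAP),
#' epidermis (EPI), keratin (KER) and background (BKG).
#'
#' @export
mitseg_classes <- c("BCC", "SCC", "IEC", "GLD", "FOL", "INF",
                    "RET", "HYP", "PAP", "EPI", "KER", "BKG")

#' Default class palette
#'
#' An ordered set of 12 pairwise-distinct colours, one per class (BKG is
#' white, matching the appearance of slide background). The published
#' palette exists only as a figure, so the colours here are a configurable
#' package default; any palette with 12 distinct colours works.
#'
#' @return named character vector of hex colours in class order.
#' @export
default_palette <- function() {
  c(BCC = "#E6194B", SCC = "#3CB44B", IEC = "#FFE119", GLD = "#4363D8",
    FOL = "#F58231", INF = "#911EB4", RET = "#46F0F0", HYP = "#F032E6",
    PAP = "#BCF60C", EPI = "#A0711C", KER = "#008080", BKG = "#FFFFFF")
}

palette_rgb <- function(palette = default_palette()) {
  stopifnot(length(palette) == 12L, !anyDuplicated(palette))
  t(grDevices::col2rgb(palette))  # 12 x 3, 0..255
}

#' Construct a labeled specimen
#'
#' Pairs an RGB image with its integer class mask and carries the metadata
#' used for stratified splitting.
#'
#' @param image numeric array H x W x 3 with values in `[0, 1]`.
#' @param mask integer matrix H x W with class codes 0..11.
#' @param id specimen identifier.
#' @param cancer_type one of `"BCC"`, `"SCC"`, `"IEC"`.
#' @param biopsy_type one of `"shave"`, `"punch"`, `"excision"`.
#' @param resolution_factor 1 (native 0.67 um/pixel), 2, 5 or 10.
#' @return a `labeled_specimen` object.
#' @export
labeled_specimen <- function(image, mask, id = "specimen",
                             cancer_type = c("BCC", "SCC", "IEC"),
                             biopsy_type = c("shave", "punch", "excision"),
                             resolution_factor = 1L) {
  cancer_type <- match.arg(cancer_type)
  biopsy_type <- match.arg(biopsy_type)
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) stop("image must be H x W x 3")
  if (!identical(dim(mask), d[1:2])) stop("image and mask dims must match")
  if (any(mask < 0L) || any(mask > 11L)) stop("mask values must be in 0..11")
  if (resolution_factor < 1L || resolution_factor != as.integer(resolution_factor)) {
    stop("resolution_factor must be a positive integer (dataset variants use 1, 2, 5, 10)")
  }
  structure(list(image = image, mask = matrix(as.integer(mask), d[1L], d[2L]),
                 id = id, cancer_type = cancer_type, biopsy_type = biopsy_type,
                 resolution_factor = as.integer(resolution_factor)),
            class = "labeled_specimen")
}

#' @export
print.labeled_specimen <- function(x, ...) {
  cat(sprintf("Labeled specimen '%s': %d x %d, %s, %s biopsy, %dx\n",
              x$id, nrow(x$mask), ncol(x$mask), x$cancer_type, x$biopsy_type,
              x$resolution_factor))
  invisible(x)
}

#' Physical pixel pitch of a specimen
#'
#' Native scans have a pitch of 0.67 micrometres per pixel; downsampled
#' variants scale accordingly.
#'
#' @param specimen a `labeled_specimen`.
#' @return pixel pitch in micrometres.
#' @export
pixel_pitch_um <- function(specimen) {
  0.67 * specimen$resolution_factor
}

## ---- palette codec ---------------------------------------------------------

rgb_key <- function(r, g, b) r * 65536 + g * 256 + b

#' Decode a colour-coded mask into integer class codes
#'
#' Every pixel colour must belong to the palette; any off-palette colour is
#' an error listing the offending colours and their pixel counts.
#'
#' @param rgb_mask numeric array H x W x 3 in `[0, 1]` (e.g. from
#'   [png::readPNG()]).
#' @param palette named hex colour vector in class order (12 entries).
#' @return integer matrix of class codes 0..11.
#' @export
decode_mask <- function(rgb_mask, palette = default_palette()) {
  pal <- palette_rgb(palette)
  d <- dim(rgb_mask)
  q <- round(rgb_mask * 255)
  keys <- rgb_key(q[, , 1L], q[, , 2L], q[, , 3L])
  pal_keys <- rgb_key(pal[, 1L], pal[, 2L], pal[, 3L])
  idx <- match(keys, pal_keys)
  if (anyNA(idx)) {
    bad <- table(keys[is.na(idx)])
    bad_hex <- sprintf("#%06X (%d px)", as.numeric(names(bad)), as.integer(bad))
    stop("mask contains ", length(bad), " colour(s) outside the palette: ",
         paste(bad_hex, collapse = ", "))
  }
  matrix(as.integer(idx - 1L), d[1L], d[2L])
}

#' Encode an integer class mask as a colour image
#'
#' Inverse of [decode_mask()]; the round trip is exact.
#'
#' @param mask integer matrix of class codes 0..11.
#' @param palette named hex colour vector in class order.
#' @return numeric array H x W x 3 in `[0, 1]`.
#' @export
encode_mask <- function(mask, palette = default_palette()) {
  pal <- palette_rgb(palette) / 255
  d <- dim(mask)
  out <- array(0, c(d[1L], d[2L], 3L))
  for (ch in 1:3) out[, , ch] <- matrix(pal[mask + 1L, ch], d[1L], d[2L])
  out
}

#' Read / write specimen rasters
#'
#' Images travel as TIFF, masks as colour-coded PNG.
#'
#' @param path file path.
#' @param palette palette for the mask codec.
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' @rdname raster_io
#' @param image numeric array H x W x 3 in `[0, 1]`.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(image, path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_mask_png <- function(path, palette = default_palette()) {
  decode_mask(png::readPNG(path)[, , 1:3, drop = FALSE], palette)
}

#' @rdname raster_io
#' @param mask integer matrix of class codes 0..11.
#' @export
write_mask_png <- function(mask, path, palette = default_palette()) {
  png::writePNG(encode_mask(mask, palette), path)
  invisible(path)
}

## ---- resolution variants ---------------------------------------------------

#' Downsample a specimen to a coarser resolution variant
#'
#' The image is reduced by block averaging (area interpolation); the mask by
#' nearest neighbour, so labels are never blended. The physical pixel pitch
#' becomes `0.67 * factor` micrometres.
#'
#' @param specimen a `labeled_specimen` at native resolution.
#' @param factor 2, 5 or 10.
#' @return the downsampled `labeled_specimen`.
#' @export
downsample <- function(specimen, factor) {
  if (!factor %in% c(2L, 5L, 10L)) stop("factor must be 2, 5 or 10")
  img <- specimen$image
  H <- dim(img)[1L]; W <- dim(img)[2L]
  Ah <- area_matrix(H, factor)
  Aw <- area_matrix(W, factor)
  out <- array(0, c(nrow(Ah), nrow(Aw), 3L))
  for (ch in 1:3) out[, , ch] <- Ah %*% img[, , ch] %*% t(Aw)
  mask <- resize_nearest(specimen$mask, nrow(Ah), nrow(Aw))
  labeled_specimen(out, mask, specimen$id, specimen$cancer_type,
                   specimen$biopsy_type,
                   specimen$resolution_factor * as.integer(factor))
}

## ---- tiling / stitching ----------------------------------------------------

#' Cut a specimen into fixed-size training tiles
#'
#' A non-overlapping grid of `size` x `size` tiles covers the specimen;
#' right/bottom edge tiles are padded (white pixels, BKG label) and the
#' padded pixels are recorded in a validity mask so they can be excluded
#' from loss and metrics. Each tile is then rescaled to
#' `rescale_to` x `rescale_to` (image bilinear, mask and validity nearest
#' neighbour). Tile coordinates are 0-based, row-major, half-open.
#'
#' @param specimen a `labeled_specimen`.
#' @param size tile edge before rescaling (default 256).
#' @param rescale_to tile edge after rescaling (default 512).
#' @return list of tiles; each tile is a list with `image`, `mask`, `valid`,
#'   `row`, `col` (0-based pixel offsets into the source) and `size`.
#' @export
tile <- function(specimen, size = 256L, rescale_to = 512L) {
  H <- nrow(specimen$mask); W <- ncol(specimen$mask)
  if (H < 1L || W < 1L) stop("empty image")
  bkg <- match("BKG", mitseg_classes) - 1L
  nrows <- ceiling(H / size)
  ncols <- ceiling(W / size)
  Hp <- nrows * size; Wp <- ncols * size
  img <- array(1, c(Hp, Wp, 3L))          # white padding (H&E background)
  img[seq_len(H), seq_len(W), ] <- specimen$image
  msk <- matrix(bkg, Hp, Wp)
  msk[seq_len(H), seq_len(W)] <- specimen$mask
  val <- matrix(FALSE, Hp, Wp)
  val[seq_len(H), seq_len(W)] <- TRUE
  tiles <- list()
  for (r in seq_len(nrows)) for (cc in seq_len(ncols)) {
    rows <- ((r - 1L) * size + 1L):(r * size)
    cols <- ((cc - 1L) * size + 1L):(cc * size)
    ti <- img[rows, cols, , drop = FALSE]
    tm <- msk[rows, cols, drop = FALSE]
    tv <- val[rows, cols, drop = FALSE]
    if (rescale_to != size) {
      ti <- resize_bilinear(ti, rescale_to, rescale_to)
      tm <- resize_nearest(tm, rescale_to, rescale_to)
      tv <- resize_nearest(tv, rescale_to, rescale_to)
    }
    tiles[[length(tiles) + 1L]] <-
      list(image = ti, mask = tm, valid = tv,
           row = (r - 1L) * size, col = (cc - 1L) * size, size = size)
  }
  attr(tiles, "full_size") <- c(H, W)
  attr(tiles, "rescale_to") <- as.integer(rescale_to)
  tiles
}

#' Reassemble predicted tile masks into a full-size mask
#'
#' Each predicted tile is rescaled back from the inference size to the tile
#' grid (nearest neighbour), placed at its recorded coordinates, and the
#' padding introduced by [tile()] is cropped away.
#'
#' @param pred_tiles list of tiles as from [tile()], with `mask` replaced by
#'   the predicted mask (any square size).
#' @param full_size integer vector `c(H, W)` of the original specimen.
#' @return integer mask H x W.
#' @export
stitch <- function(pred_tiles, full_size = attr(pred_tiles, "full_size")) {
  if (is.null(full_size)) stop("full_size required")
  H <- full_size[1L]; W <- full_size[2L]
  out <- matrix(NA_integer_, H, W)
  for (t in pred_tiles) {
    m <- t$mask
    if (nrow(m) != t$size) m <- resize_nearest(m, t$size, t$size)
    rows <- (t$row + 1L):min(H, t$row + t$size)
    cols <- (t$col + 1L):min(W, t$col + t$size)
    out[rows, cols] <- m[seq_along(rows), seq_along(cols)]
  }
  if (anyNA(out)) stop("tiles do not cover the full image (coverage gap)")
  out
}

## ---- splitting -------------------------------------------------------------

#' Stratified train/validation/test split
#'
#' Splits specimens 80/10/10 (by default), stratified over the
#' cancer-type x biopsy-type cells so every cancer and biopsy kind is
#' distributed evenly across the three sets; within each cell the split
#' counts follow largest-remainder rounding and the assignment is a seeded
#' random permutation.
#'
#' @param items data frame with columns `id`, `cancer_type`, `biopsy_type`,
#'   or a list of `labeled_specimen` objects.
#' @param ratios length-3 proportions summing to 1.
#' @param seed integer RNG seed.
#' @return a `split_manifest`: data frame `id`, `split`, `cancer_type`,
#'   `biopsy_type` with attributes `seed` and `ratios`.
#' @export
split_dataset <- function(items, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (!is.data.frame(items)) {
    items <- data.frame(
      id = vapply(items, `[[`, character(1), "id"),
      cancer_type = vapply(items, `[[`, character(1), "cancer_type"),
      biopsy_type = vapply(items, `[[`, character(1), "biopsy_type"),
      stringsAsFactors = FALSE)
  }
  if (nrow(items) < 10L) stop("need at least 10 items to split")
  if (abs(sum(ratios) - 1) > 1e-9 || length(ratios) != 3L) {
    stop("ratios must be 3 proportions summing to 1")
  }
  set.seed(seed)
  items$split <- NA_character_
  strata <- interaction(items$cancer_type, items$biopsy_type, drop = TRUE)
  for (s in levels(strata)) {
    ix <- which(strata == s)
    n <- length(ix)
    if (n < 3L) warning("stratum ", s, " has only ", n, " item(s)")
    counts <- largest_remainder(n, ratios)
    lab <- rep(c("train", "val", "test"), counts)
    items$split[ix] <- sample(lab)
  }
  out <- items[, c("id", "split", "cancer_type", "biopsy_type")]
  attr(out, "seed") <- seed
  attr(out, "ratios") <- ratios
  class(out) <- c("split_manifest", "data.frame")
  out
}

# apportion n into integer counts proportional to `ratios`
largest_remainder <- function(n, ratios) {
  q <- n * ratios
  base <- floor(q)
  rem <- round(n - sum(base))
  if (rem > 0L) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' @rdname split_dataset
#' @param manifest a `split_manifest`.
#' @param path CSV file path.
#' @export
write_manifest_csv <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

## ---- dihedral augmentation -------------------------------------------------

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
flip_h <- function(m) m[, ncol(m):1, drop = FALSE]

apply_d4 <- function(m, k) {
  # k in 1..8: identity, r90, r180, r270, flip, flip+r90, flip+r180, flip+r270
  if (k > 4L) m <- flip_h(m)
  for (i in seq_len((k - 1L) %% 4L)) m <- rot90cw(m)
  m
}

apply_d4_image <- function(img, k) {
  planes <- lapply(1:3, function(ch) apply_d4(img[, , ch], k))
  array(unlist(planes), c(dim(planes[[1L]]), 3L))
}

#' Eight-fold dihedral augmentation
#'
#' Replaces one square tile with the 8 elements of the dihedral group D4:
#' the original, its 90/180/270-degree rotations, the horizontal flip, and
#' the flip's three rotations — image and mask transformed identically. The
#' original comes first and the order is deterministic.
#'
#' @param specimen a square `labeled_specimen` (rotation closure requires a
#'   square).
#' @return list of 8 `labeled_specimen` objects.
#' @export
augment <- function(specimen) {
  if (nrow(specimen$mask) != ncol(specimen$mask)) {
    stop("augmentation requires a square tile")
  }
  lapply(1:8, function(k) {
    labeled_specimen(apply_d4_image(specimen$image, k),
                     apply_d4(specimen$mask, k),
                     id = paste0(specimen$id, "_d4_", k),
                     cancer_type = specimen$cancer_type,
                     biopsy_type = specimen$biopsy_type,
                     resolution_factor = specimen$resolution_factor)
  })
}
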