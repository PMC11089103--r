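# Palette codec, resolution variants, tiling/stitching, stratified
# splitting and dihedral augmentation.

test_that("mask codec is a bijection on palette colours", {
  m <- random_mask(40, 30, seed = 2)
  expect_identical(decode_mask(encode_mask(m)), m)
  # uniform background decodes to the BKG index everywhere
  bkg <- matrix(11L, 8, 8)
  expect_identical(decode_mask(encode_mask(bkg)), bkg)
  # file round trip through PNG
  path <- tempfile(fileext = ".png")
  write_mask_png(m, path)
  expect_identical(read_mask_png(path), m)
})

test_that("off-palette colours are reported with counts", {
  rgbm <- encode_mask(matrix(0L, 5, 5))
  rgbm[2, 3, ] <- c(0.5, 0.5, 0.5)
  err <- tryCatch(decode_mask(rgbm), error = conditionMessage)
  expect_match(err, "1 colour")
  expect_match(err, "1 px")
})

test_that("downsampling scales image by area, mask by nearest neighbour", {
  set.seed(3)
  img <- array(runif(1000 * 800 * 3), c(1000, 800, 3))
  msk <- matrix(sample(0:11, 1000 * 800, TRUE), 1000, 800)
  sp <- labeled_specimen(img, msk, id = "a")
  d10 <- downsample(sp, 10)
  expect_identical(dim(d10$mask), c(100L, 80L))
  expect_equal(pixel_pitch_um(d10), 6.7)
  # area interpolation: first output pixel is the mean of its 10x10 block
  expect_equal(d10$image[1, 1, 1], mean(img[1:10, 1:10, 1]))
  # nearest neighbour never invents labels
  expect_true(all(unique(as.vector(d10$mask)) %in% unique(as.vector(msk))))
  # factor-2 twice matches factor-4 dims within floor effects
  d22 <- downsample(downsample(sp, 2), 2)
  expect_identical(dim(d22$mask), c(250L, 200L))
  expect_error(downsample(sp, 3), "factor")
})

test_that("tiling covers the image and stitching inverts it", {
  sp <- checker_specimen(96)
  tiles <- tile(sp, size = 32L, rescale_to = 64L)
  expect_length(tiles, 9L)
  expect_identical(dim(tiles[[1]]$image), c(64L, 64L, 3L))
  expect_identical(stitch(tiles), sp$mask)

  # non-divisible size: 300x300 at 256 -> 2x2 grid with 212 px padding
  set.seed(4)
  big <- labeled_specimen(array(runif(300 * 300 * 3), c(300, 300, 3)),
                          matrix(sample(0:11, 300 * 300, TRUE), 300, 300),
                          id = "b")
  tl <- tile(big, size = 256L, rescale_to = 256L)
  expect_length(tl, 4L)
  expect_equal(sapply(tl, `[[`, "row"), c(0, 0, 256, 256))
  edge <- tl[[4]]
  expect_equal(sum(!edge$valid), 256^2 - 44^2)   # 212 px of padding per axis
  expect_true(all(edge$mask[!edge$valid] == 11L))
  expect_identical(stitch(tl), big$mask)
  expect_error(stitch(tl[-2], dim(big$mask)), "gap")
})

test_that("splitting is stratified, proportional and reproducible", {
  items <- data.frame(id = sprintf("s%03d", 1:290),
                      cancer_type = "BCC", biopsy_type = "shave")
  man <- split_dataset(items, seed = 7)
  expect_identical(as.integer(table(man$split)[c("train", "val", "test")]),
                   c(232L, 29L, 29L))
  expect_identical(split_dataset(items, seed = 7), man)
  expect_false(identical(split_dataset(items, seed = 8)$split, man$split))

  ten <- data.frame(id = letters[1:10], cancer_type = "SCC",
                    biopsy_type = "punch")
  expect_identical(as.integer(table(split_dataset(ten, seed = 1)$split)[
    c("train", "val", "test")]), c(8L, 1L, 1L))

  # multi-stratum: still a partition, near-even per cell
  set.seed(9)
  multi <- data.frame(id = sprintf("m%03d", 1:120),
                      cancer_type = sample(c("BCC", "SCC", "IEC"), 120, TRUE),
                      biopsy_type = sample(c("shave", "punch", "excision"),
                                           120, TRUE))
  mm <- split_dataset(multi, seed = 2)
  expect_setequal(mm$id, multi$id)
  expect_false(any(duplicated(mm$id)))
  expect_true(all(table(mm$split)[c("val", "test")] >= 9))
  expect_error(split_dataset(ten[1:5, ], seed = 1), "at least 10")
})

test_that("augmentation yields the 8 dihedral variants with preserved counts", {
  sp <- checker_specimen(32)
  sp$mask[1, 2] <- 3L   # off-axis markers break every dihedral symmetry
  sp$mask[3, 7] <- 5L
  sp$image <- encode_mask(sp$mask)
  aug <- augment(sp)
  expect_length(aug, 8L)
  expect_identical(aug[[1]]$mask, sp$mask)   # original first
  counts <- class_counts(sp$mask)
  for (a in aug) {
    expect_identical(class_counts(a$mask), counts)
    # image and mask transformed with the same geometry
    expect_identical(decode_mask(a$image), a$mask)
  }
  expect_identical(length(unique(lapply(aug, `[[`, "mask"))), 8L)

  # constant tile is fully symmetric: all 8 outputs identical
  const <- labeled_specimen(array(0.5, c(16, 16, 3)), matrix(11L, 16, 16))
  expect_identical(length(unique(lapply(augment(const), `[[`, "mask"))), 1L)

  rect <- labeled_specimen(array(0.5, c(16, 8, 3)), matrix(11L, 16, 8))
  expect_error(augment(rect), "square")
})

test_that("tiff image io round-trips", {
  img <- random_image(20, 30, seed = 5)
  path <- tempfile(fileext = ".tif")
  write_image_tiff(img, path)
  expect_equal(read_image_tiff(path), img, tolerance = 1 / 255)
})
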