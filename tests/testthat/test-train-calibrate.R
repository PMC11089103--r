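# Loss analytics, temperature scaling and uncertainty maps.

test_that("cross-entropy matches its analytic values", {
  # uniform logits over 12 classes: per-pixel loss = ln 12
  lab <- random_mask(6, 6)
  uniform <- array(0, c(6, 6, 12))
  v <- matrix(TRUE, 6, 6)
  expect_equal(mitseg:::ce_loss(uniform, lab, v)$loss, log(12))
  # near-one-hot logits on the true class: loss ~ 0
  hot <- array(0, c(6, 6, 12))
  for (k in 0:11) hot[, , k + 1][lab == k] <- 50
  expect_lt(mitseg:::ce_loss(hot, lab, v)$loss, 1e-6)
  # invalid pixels carry no gradient
  v2 <- v; v2[1, ] <- FALSE
  g <- mitseg:::ce_loss(uniform, lab, v2)$dlogits
  expect_equal(max(abs(g[1, , ])), 0)
})

test_that("training rejects out-of-range class labels", {
  sp <- tiny_spec(num_classes = 4L)
  bad <- labeled_specimen(random_image(64, 64), random_mask(64, 64, K = 12L))
  expect_error(train(seg_model(sp), list(bad), list(),
                     train_config(epochs = 1L)), "class index")
})

test_that("a short seeded run reduces the training loss and is reproducible", {
  sp <- tiny_spec()
  set.seed(1)
  tiles <- lapply(1:2, function(i) {
    generate_specimen(fixture_recipe(seed = i, size = 64))
  })
  cfg <- train_config(batch_size = 2L, epochs = 4L, seed = 3L)
  m1 <- train(seg_model(sp, seed = 3), tiles, list(), cfg)
  m2 <- train(seg_model(sp, seed = 3), tiles, list(), cfg)
  expect_identical(m1$params, m2$params)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  expect_identical(nrow(m1$history), 4L)
})

test_that("temperature fitting recovers calibrated and overconfident regimes", {
  set.seed(7)
  n <- 4000L; K <- 6L
  freq <- c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05)
  labels <- sample(0:(K - 1L), n, TRUE, prob = freq)
  # logits equal to the log of the empirical label distribution are already
  # calibrated: the fitted temperature sits near 1
  emp <- tabulate(labels + 1L, K) / n
  logits <- matrix(log(emp), n, K, byrow = TRUE) +
    matrix(rnorm(n * K, sd = 1e-3), n, K)
  cal <- fit_temperature(logits, labels)
  expect_lt(abs(cal$temperature - 1), 0.1)
  # scaling the logits by 10 makes them overconfident; the fitted
  # temperature rises ~10-fold to undo it
  cal10 <- fit_temperature(10 * logits, labels)
  expect_gt(cal10$temperature, 1)
  expect_lt(abs(cal10$temperature / cal$temperature - 10), 1)
  # optimisation contract
  nll1 <- mitseg:::nll_at(10 * logits, labels + 1L, 1)
  expect_lte(cal10$nll, nll1)
  expect_warning(fit_temperature(logits, rep(0L, n)), "single-class")
})

test_that("temperature scaling never changes the argmax prediction", {
  sp <- tiny_spec()
  model <- seg_model(sp, seed = 5)
  img <- generate_specimen(fixture_recipe(seed = 4, size = 64))$image
  p1 <- predict_seg(model, img, temperature = 1)
  for (temp in c(0.25, 2, 7.5)) {
    pt <- predict_seg(model, img, temperature = temp)
    expect_identical(pt$mask, p1$mask)
  }
  expect_error(predict_seg(model, img, temperature = 0))
})

test_that("uncertainty maps obey their analytic bounds", {
  onehot <- array(0, c(2, 2, 12)); onehot[, , 4] <- 1
  expect_equal(max(uncertainty_map(onehot)), 0)
  uniform <- array(1 / 12, c(2, 2, 12))
  expect_equal(uncertainty_map(uniform), matrix(11 / 12, 2, 2))
  # invariant to class permutation
  set.seed(8)
  p <- matrix(rexp(10 * 12), 10)
  p <- p / rowSums(p)
  expect_equal(uncertainty_map(p), uncertainty_map(p[, sample(12)]))
  expect_error(uncertainty_map(2 * p), "sum to 1")
  # bounds: [0, 1 - 1/K]
  u <- uncertainty_map(p)
  expect_true(all(u >= 0 & u <= 11 / 12))
})
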