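# Confusion-matrix metrics against hand-computed oracles.

hand_cm <- function() mitseg:::as_confusion(matrix(c(3, 2, 1, 4), 2, 2),
                                            labels = c("A", "B"))

test_that("confusion counts valid pixels by truth and prediction", {
  truth <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  pred <- matrix(c(0L, 1L, 1L, 1L), 2, 2)
  cm <- confusion(pred, truth, K = 2L)
  expect_equal(unclass(cm), matrix(c(1, 0, 1, 2), 2, 2), ignore_attr = TRUE)
  expect_equal(sum(cm), 4)
  # validity mask excludes pixels
  v <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  expect_equal(sum(confusion(pred, truth, 2L, v)), sum(v))
  # identical masks give a diagonal matrix with full trace
  m <- random_mask(10, 10, K = 12L)
  cmd <- confusion(m, m)
  expect_equal(sum(diag(cmd)), 100)
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)
  # disjoint constant masks give one off-diagonal cell
  cm1 <- confusion(matrix(11L, 4, 4), matrix(0L, 4, 4))
  expect_equal(cm1[1, 12], 16)
  expect_equal(sum(cm1), 16)
  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shape")
  expect_error(confusion(matrix(12L, 2, 2), matrix(0L, 2, 2), K = 12L), "< K")
})

test_that("class-wise accuracy, average accuracy and mIoU match hand oracles", {
  cm <- hand_cm()
  expect_equal(unname(classwise_accuracy(cm)), c(3 / 4, 4 / 6))
  expect_equal(average_accuracy(cm), (3 / 4 + 4 / 6) / 2)
  expect_equal(mean_iou(cm), (1 / 2 + 4 / 7) / 2)   # = 15/28
  expect_equal(mean_iou(cm), 15 / 28)
  # per-class IoU never exceeds recall
  expect_true(all(class_iou(cm) <= classwise_accuracy(cm)))
  # perfect prediction
  diagcm <- mitseg:::as_confusion(diag(c(5, 9, 2)), labels = c("A", "B", "C"))
  expect_equal(average_accuracy(diagcm), 1)
  expect_equal(mean_iou(diagcm), 1)
})

test_that("rows absent from ground truth are flagged, not counted as zero", {
  cm <- mitseg:::as_confusion(matrix(c(4, 0, 1, 0), 2, 2), labels = c("A", "B"))
  acc <- classwise_accuracy(cm)
  expect_true(is.na(acc["B"]))
  expect_equal(average_accuracy(cm), 4 / 5)   # macro over present classes only
})

test_that("F1 variants match hand arithmetic and micro equals pixel accuracy", {
  cm <- hand_cm()
  f <- f1_scores(cm)
  f1a <- 2 * (3 / 5) * (3 / 4) / (3 / 5 + 3 / 4)
  f1b <- 2 * (4 / 5) * (4 / 6) / (4 / 5 + 4 / 6)
  expect_equal(f$macro, mean(c(f1a, f1b)), tolerance = 1e-12)
  expect_equal(round(f$macro, 4), 0.6970)
  expect_equal(f$micro, (3 + 4) / 10)
  expect_equal(f$weighted, (4 * f1a + 6 * f1b) / 10)
  perfect <- mitseg:::as_confusion(diag(c(2, 3)), labels = c("A", "B"))
  fp <- f1_scores(perfect)
  expect_equal(c(fp$micro, fp$macro, fp$weighted), c(1, 1, 1))
  # micro F1 == overall pixel accuracy identity on a random case
  m1 <- random_mask(12, 12, seed = 1); m2 <- random_mask(12, 12, seed = 2)
  cmr <- confusion(m2, m1)
  expect_equal(f1_scores(cmr)$micro, sum(m1 == m2) / length(m1))
})

test_that("metrics are invariant under simultaneous label permutation", {
  truth <- random_mask(16, 16, seed = 3)
  pred <- random_mask(16, 16, seed = 4)
  cm <- confusion(pred, truth)
  perm <- sample(0:11)
  relab <- function(m) matrix(perm[m + 1L], nrow(m), ncol(m))
  cmp <- confusion(relab(pred), relab(truth))
  expect_equal(average_accuracy(cmp), average_accuracy(cm))
  expect_equal(mean_iou(cmp), mean_iou(cm))
  expect_equal(f1_scores(cmp)$macro, f1_scores(cm)$macro)
})

test_that("confusion is additive over image partitions", {
  truth <- random_mask(20, 10, seed = 5)
  pred <- random_mask(20, 10, seed = 6)
  whole <- confusion(pred, truth)
  top <- confusion(pred[1:10, ], truth[1:10, ])
  bottom <- confusion(pred[11:20, ], truth[11:20, ])
  expect_equal(unclass(whole), unclass(top) + unclass(bottom))
  # macro metrics unchanged by duplicating every pixel
  dup <- mitseg:::as_confusion(2 * unclass(whole))
  expect_equal(average_accuracy(dup), average_accuracy(whole))
  expect_equal(f1_scores(dup)$micro, f1_scores(whole)$micro)
})

test_that("evaluation artifacts serialise", {
  cm <- confusion(random_mask(8, 8, seed = 7), random_mask(8, 8, seed = 8))
  rep <- metrics_report(cm)
  d <- tempfile(); dir.create(d)
  write_confusion_csv(cm, file.path(d, "cm.csv"))
  write_metrics_csv(rep, file.path(d, "metrics.csv"))
  back <- utils::read.csv(file.path(d, "cm.csv"), row.names = 1)
  expect_equal(unname(as.matrix(back)), unclass(cm), ignore_attr = TRUE)
  expect_true(any(utils::read.csv(file.path(d, "metrics.csv"))$class ==
                  "average_accuracy"))
})
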