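# Confusion matrices and the three reported performance measures: class-wise
# accuracy (recall), its macro mean ("average accuracy"), mean IoU, and F1
# in micro/macro/weighted variants. All metrics derive from one K x K
# pixel-count table (rows = ground truth, columns = prediction), so they
# are additive over image partitions and streamable over tiles.

as_confusion <- function(m, labels = mitseg_classes[seq_len(nrow(m))]) {
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  dimnames(m) <- list(truth = labels, prediction = labels)
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' Pixel confusion matrix
#'
#' Counts valid pixels by (ground-truth class, predicted class).
#'
#' @param pred_mask,true_mask integer matrices of 0-based class codes.
#' @param K number of classes (default 12).
#' @param validity logical matrix; `FALSE` pixels (tile padding) are
#'   excluded from the counts.
#' @return a `confusion_matrix` (K x K counts, rows = truth).
#' @export
confusion <- function(pred_mask, true_mask, K = 12L, validity = NULL) {
  if (!identical(dim(pred_mask), dim(true_mask))) {
    stop("prediction and truth shapes differ")
  }
  if (any(pred_mask >= K) || any(true_mask >= K)) stop("labels must be < K")
  v <- if (is.null(validity)) TRUE else as.vector(validity)
  p <- as.vector(pred_mask)[v]
  t <- as.vector(true_mask)[v]
  cm <- matrix(0, K, K)
  tab <- table(factor(t, levels = 0:(K - 1L)), factor(p, levels = 0:(K - 1L)))
  cm[] <- as.numeric(tab)
  as_confusion(cm, labels = if (K == 12L) mitseg_classes else as.character(0:(K - 1L)))
}

present_classes <- function(cm) which(rowSums(cm) > 0)

#' Class-wise accuracy (recall)
#'
#' `cm[k,k] / rowsum_k` per class; classes absent from the ground truth are
#' returned as `NA` (absent, not zero).
#'
#' @param cm a `confusion_matrix`.
#' @return named numeric vector of per-class recalls.
#' @export
classwise_accuracy <- function(cm) {
  rs <- rowSums(cm)
  acc <- diag(cm) / rs
  acc[rs == 0] <- NA_real_
  acc
}

#' Average accuracy (macro mean of class-wise recalls)
#'
#' The unweighted mean of [classwise_accuracy()] over classes present in
#' the ground truth.
#'
#' @param cm a `confusion_matrix`.
#' @return scalar in `[0, 1]`.
#' @export
average_accuracy <- function(cm) {
  acc <- classwise_accuracy(cm)
  if (all(is.na(acc))) stop("no class present in ground truth")
  mean(acc, na.rm = TRUE)
}

#' Mean intersection-over-union
#'
#' `IoU_k = cm[k,k] / (rowsum_k + colsum_k - cm[k,k])`, averaged over
#' classes present in the ground truth.
#'
#' @param cm a `confusion_matrix`.
#' @return scalar in `[0, 1]`.
#' @export
mean_iou <- function(cm) {
  mean(class_iou(cm), na.rm = TRUE)
}

#' @rdname mean_iou
#' @export
class_iou <- function(cm) {
  rs <- rowSums(cm); cs <- colSums(cm); dg <- diag(cm)
  iou <- dg / (rs + cs - dg)
  iou[rs == 0] <- NA_real_
  iou
}

#' F1 scores
#'
#' Per-class F1 from precision and recall, aggregated three ways: `micro`
#' (global over pixels — equal to overall pixel accuracy for single-label
#' data), `macro` (unweighted mean over present classes) and `weighted`
#' (support-weighted mean).
#'
#' @param cm a `confusion_matrix`.
#' @return list with `per_class`, `micro`, `macro`, `weighted`.
#' @export
f1_scores <- function(cm) {
  rs <- rowSums(cm); cs <- colSums(cm); dg <- diag(cm)
  prec <- ifelse(cs > 0, dg / cs, NA_real_)
  rec <- ifelse(rs > 0, dg / rs, NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec), 0)
  f1[rs == 0] <- NA_real_
  present <- rs > 0
  list(per_class = f1,
       micro = sum(dg) / sum(cm),
       macro = mean(f1[present]),
       weighted = sum((rs[present] / sum(rs)) * f1[present]))
}

#' Full metrics report
#'
#' @param cm a `confusion_matrix`.
#' @return a `metrics_report`: list with `per_class_accuracy`,
#'   `average_accuracy`, `mean_iou`, `per_class_iou` and `f1`.
#' @export
metrics_report <- function(cm) {
  structure(list(per_class_accuracy = classwise_accuracy(cm),
                 average_accuracy = average_accuracy(cm),
                 mean_iou = mean_iou(cm),
                 per_class_iou = class_iou(cm),
                 f1 = f1_scores(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("average accuracy %.3f | mIoU %.3f | F1 micro %.3f macro %.3f weighted %.3f\n",
              x$average_accuracy, x$mean_iou, x$f1$micro, x$f1$macro,
              x$f1$weighted))
  tab <- rbind(accuracy = x$per_class_accuracy, iou = x$per_class_iou)
  print(round(tab, 3))
  invisible(x)
}

#' Serialise evaluation artifacts
#'
#' @param cm a `confusion_matrix`.
#' @param report a `metrics_report`.
#' @param path CSV output path.
#' @name metrics_io
NULL

#' @rdname metrics_io
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname metrics_io
#' @export
write_metrics_csv <- function(report, path) {
  df <- data.frame(class = names(report$per_class_accuracy),
                   accuracy = as.numeric(report$per_class_accuracy),
                   iou = as.numeric(report$per_class_iou),
                   f1 = as.numeric(report$f1$per_class))
  summary <- data.frame(class = c("average_accuracy", "mean_iou",
                                  "f1_micro", "f1_macro", "f1_weighted"),
                        accuracy = c(report$average_accuracy, report$mean_iou,
                                     report$f1$micro, report$f1$macro,
                                     report$f1$weighted),
                        iou = NA_real_, f1 = NA_real_)
  utils::write.csv(rbind(df, summary), path, row.names = FALSE)
  invisible(path)
}

#' @rdname metrics_io
#' @export
confusion_heatmap_png <- function(cm, path) {
  norm <- cm / pmax(1, rowSums(cm))
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  K <- nrow(cm)
  graphics::image(seq_len(K), seq_len(K), t(norm[K:1, ]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "prediction", ylab = "truth")
  graphics::axis(1, seq_len(K), colnames(cm), las = 2)
  graphics::axis(2, seq_len(K), rev(rownames(cm)), las = 2)
  invisible(path)
}
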