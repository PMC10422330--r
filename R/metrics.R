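#' Confusion matrix between predicted and true label rasters
#'
#' `counts[i, j]` = number of pixels of true class `i - 1` predicted as class
#' `j - 1`. Nodata pixels in either raster are excluded.
#'
#' @param pred,truth co-registered label [reef_raster()] objects (or plain
#'   label matrices)
#' @param n_classes number of classes (default 3)
#' @return `n_classes x n_classes` integer matrix with class ids as dimnames
#' @export
confusion <- function(pred, truth, n_classes = 3L) {
  p <- if (inherits(pred, "reef_raster")) pred$data else pred
  t <- if (inherits(truth, "reef_raster")) truth$data else truth
  if (inherits(pred, "reef_raster") && inherits(truth, "reef_raster"))
    assert_coregistered(pred, truth)
  ok <- !is.na(p) & !is.na(t)
  if (!any(ok)) stop("metric error: no valid pixels", call. = FALSE)
  lv <- 0:(n_classes - 1L)
  cm <- table(factor(t[ok], levels = lv), factor(p[ok], levels = lv))
  m <- matrix(as.integer(cm), n_classes, n_classes,
              dimnames = list(true = lv, pred = lv))
  m
}

#' Mean pixel accuracy (mPA)
#'
#' Mean over classes of the per-class pixel accuracy
#' `counts[i, i] / row_total[i]`; classes absent from the truth (zero row
#' total) are excluded from the mean.
#'
#' @param cm confusion matrix from [confusion()]
#' @return fraction in `[0, 1]`
#' @export
mean_pixel_accuracy <- function(cm) {
  rt <- rowSums(cm)
  present <- rt > 0
  if (!any(present)) stop("metric error: empty confusion matrix", call. = FALSE)
  mean(diag(cm)[present] / rt[present])
}

#' Mean intersection over union (mIoU)
#'
#' Mean over classes of `counts[i, i] / (row_total[i] + col_total[i] -
#' counts[i, i])`; classes absent from both truth and prediction are
#' excluded.
#'
#' @param cm confusion matrix from [confusion()]
#' @return fraction in `[0, 1]`
#' @export
mean_iou <- function(cm) {
  rt <- rowSums(cm); ct <- colSums(cm); d <- diag(cm)
  present <- (rt + ct) > 0
  if (!any(present)) stop("metric error: empty confusion matrix", call. = FALSE)
  mean(d[present] / (rt[present] + ct[present] - d[present]))
}

#' Per-class IoU
#' @param cm confusion matrix from [confusion()]
#' @return named vector of IoU per class (NaN for classes absent from both)
#' @export
class_iou <- function(cm) {
  rt <- rowSums(cm); ct <- colSums(cm); d <- diag(cm)
  d / (rt + ct - d)
}

#' Segmentation evaluation summary
#'
#' @param pred,truth co-registered label rasters
#' @param n_classes number of classes (default 3)
#' @return list with `mPA`, `mIoU`, `per_class_iou`, `confusion`
#' @export
seg_eval <- function(pred, truth, n_classes = 3L) {
  cm <- confusion(pred, truth, n_classes)
  list(mPA = mean_pixel_accuracy(cm), mIoU = mean_iou(cm),
       per_class_iou = class_iou(cm), confusion = cm)
}
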