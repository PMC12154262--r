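## Evaluation: per-image Dice and IoU, subject-level fold plans, per-fold
## metrics with and without the rejection filter, fold averaging, and AoD
## error summaries.

check_same_shape <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("mask shape mismatch: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(gt), collapse = "x"))
}

#' Dice coefficient between two binary masks
#'
#' `2|P∩G| / (|P| + |G|)`. When both masks are empty the score is defined as
#' 1.0 (perfect agreement on absence); when exactly one is empty it is 0.
#'
#' @param pred,gt 0/1 matrices of the same shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coef <- function(pred, gt) {
  check_same_shape(pred, gt)
  p <- sum(pred > 0); g <- sum(gt > 0)
  if (p + g == 0) return(1)
  2 * sum(pred > 0 & gt > 0) / (p + g)
}

#' Intersection over union between two binary masks
#'
#' `foreground` mode is the usual `|P∩G| / |P∪G|` (both empty: 1.0).
#' `global` mode averages the per-class IoU over foreground and background;
#' for masks whose foreground is a small fraction of the image this is
#' dominated by the background class and can exceed the Dice coefficient.
#'
#' @param pred,gt 0/1 matrices of the same shape.
#' @param mode `"foreground"` or `"global"`.
#' @return scalar in `[0, 1]`.
#' @export
iou_score <- function(pred, gt, mode = c("foreground", "global")) {
  mode <- match.arg(mode)
  check_same_shape(pred, gt)
  cls_iou <- function(p, g) {
    u <- sum(p | g)
    if (u == 0) 1 else sum(p & g) / u
  }
  fg <- cls_iou(pred > 0, gt > 0)
  if (mode == "foreground") return(fg)
  (fg + cls_iou(pred == 0, gt == 0)) / 2
}

#' Subject-level cross-validation fold plan
#'
#' Subjects are assigned to test sets as contiguous blocks in input order
#' (fold 1 tests the first block, fold 2 the next, ...). When the subject
#' count is not divisible by `n_folds` the first `n %% n_folds` blocks get
#' one extra subject. Within each fold the remaining subjects are split
#' 8:1 train:validation by a deterministic seeded draw (validation size is
#' 1/9 of the remainder, rounded, at least 1 when possible).
#'
#' @param subject_ids character vector (order defines the blocks).
#' @param n_folds number of folds (default 10).
#' @param seed seed for the train/validation draw.
#' @return object of class `fold_plan`: list of folds, each with `test`,
#'   `train`, `val` character vectors.
#' @export
make_fold_plan <- function(subject_ids, n_folds = 10, seed = 1L) {
  n <- length(subject_ids)
  if (n_folds > n)
    stop("n_folds (", n_folds, ") exceeds the number of subjects (", n, ")")
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  base <- n %/% n_folds
  extra <- n %% n_folds
  sizes <- rep(base, n_folds) + c(rep(1, extra), rep(0, n_folds - extra))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  with_local_seed(seed, {
    folds <- lapply(seq_len(n_folds), function(f) {
      test <- subject_ids[starts[f]:ends[f]]
      rest <- setdiff(subject_ids, test)
      n_val <- if (length(rest) == 0) 0 else max(1, round(length(rest) / 9))
      val <- if (n_val > 0) sample(rest, n_val) else character(0)
      list(fold_id = f, test = test, val = val, train = setdiff(rest, val))
    })
    structure(folds, class = "fold_plan", n_folds = n_folds)
  })
}

#' Per-fold metrics with and without rejection
#'
#' Per-image Dice and IoU are computed for every test image (`_all`), and
#' again over only the images whose diameter measurement was accepted
#' (`_retained`). Metrics are averaged per image, not pooled over pixels.
#' An empty retained set yields `NA` retained metrics (undefined, not 0).
#'
#' @param predictions list of predicted 0/1 masks.
#' @param truths list of ground-truth 0/1 masks, aligned with `predictions`.
#' @param measurements list of `aod_measurement`s aligned with
#'   `predictions`; their `accepted` flags define the retained set. When
#'   provenance is present in both measurements and `provenance`, alignment
#'   is checked.
#' @param fold_id identifier stored in the result.
#' @param iou_mode passed to [iou_score].
#' @param provenance optional list of `list(subject_id, slice_index)` for the
#'   prediction/truth pairs.
#' @return one-row data.frame (class `fold_metrics`): `fold_id`, `dice_all`,
#'   `dice_retained`, `iou_all`, `iou_retained`, `n_images`, `n_retained`.
#' @export
evaluate_fold <- function(predictions, truths, measurements, fold_id = 1L,
                          iou_mode = "global", provenance = NULL) {
  n <- length(predictions)
  if (length(truths) != n || length(measurements) != n)
    stop("predictions, truths and measurements must have equal length")
  if (!is.null(provenance)) {
    for (i in seq_len(n)) {
      mp <- measurements[[i]]$provenance
      if (!is.null(mp) && !identical(mp, provenance[[i]]))
        stop("provenance mismatch at position ", i)
    }
  }
  dice <- vapply(seq_len(n), function(i) dice_coef(predictions[[i]], truths[[i]]), 1)
  iou <- vapply(seq_len(n), function(i)
    iou_score(predictions[[i]], truths[[i]], iou_mode), 1)
  acc <- vapply(measurements, function(m) isTRUE(m$accepted), TRUE)
  structure(data.frame(fold_id = fold_id,
                       dice_all = mean(dice),
                       dice_retained = if (any(acc)) mean(dice[acc]) else NA_real_,
                       iou_all = mean(iou),
                       iou_retained = if (any(acc)) mean(iou[acc]) else NA_real_,
                       n_images = n, n_retained = sum(acc)),
            class = c("fold_metrics", "data.frame"))
}

#' Fold-average row
#'
#' Unweighted arithmetic mean of each metric column across folds, rounded to
#' 4 decimals for reporting (counts are summed).
#'
#' @param fold_metrics data.frame with one row per fold (e.g. rbind of
#'   [evaluate_fold] rows, or a loaded per-fold table with columns
#'   `dice_all`, `dice_retained`, `iou_all`, `iou_retained`).
#' @param digits rounding for the metric columns (default 4).
#' @return one-row data.frame with `fold_id = "average"`.
#' @export
aggregate_folds <- function(fold_metrics, digits = 4) {
  if (nrow(fold_metrics) < 1) stop("need at least one fold")
  metric_cols <- intersect(c("dice_all", "dice_retained", "iou_all",
                             "iou_retained"), names(fold_metrics))
  out <- data.frame(fold_id = "average", stringsAsFactors = FALSE)
  for (cn in metric_cols)
    out[[cn]] <- round(mean(fold_metrics[[cn]], na.rm = TRUE), digits)
  for (cn in intersect(c("n_images", "n_retained"), names(fold_metrics)))
    out[[cn]] <- sum(fold_metrics[[cn]])
  out
}

#' AoD error summary
#'
#' Mean absolute error between predicted and truth diameters over accepted
#' measurements, plus median and interquartile range (linear-interpolation,
#' type-7 quantiles) of the predicted diameters.
#'
#' @param measurements list of `aod_measurement`s (rejected entries are
#'   dropped) or a numeric vector of predicted diameters in mm.
#' @param truth_mm numeric vector of ground-truth diameters aligned with
#'   `measurements` (including the rejected entries, which are dropped
#'   together with their predictions).
#' @return list (class `aod_error_summary`): `mean_abs_error_mm`,
#'   `median_mm`, `iqr_mm` (`q1`, `q3`), `n`.
#' @export
aod_error_summary <- function(measurements, truth_mm) {
  if (is.list(measurements)) {
    acc <- vapply(measurements, function(m) isTRUE(m$accepted), TRUE)
    pred <- vapply(measurements, function(m) m$diameter_mm, 1)[acc]
    truth_mm <- truth_mm[acc]
  } else {
    pred <- as.numeric(measurements)
  }
  if (length(pred) == 0) stop("no accepted measurements to summarize")
  if (length(pred) != length(truth_mm))
    stop("predicted and truth diameters must pair one-to-one")
  q <- quantile(pred, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(mean_abs_error_mm = mean(abs(pred - truth_mm)),
                 median_mm = q[2], iqr_mm = c(q1 = q[1], q3 = q[3]),
                 n = length(pred)),
            class = "aod_error_summary")
}

#' @export
print.aod_error_summary <- function(x, ...) {
  cat(sprintf("AoD over %d accepted measurements: MAE %.2f mm, median %.2f mm (IQR %.2f-%.2f mm)\n",
              x$n, x$mean_abs_error_mm, x$median_mm, x$iqr_mm[1], x$iqr_mm[2]))
  invisible(x)
}

#' Load the published per-fold reference metrics shipped with the package
#'
#' Per-fold Dice and IoU (with and without rejection) from the reference
#' ten-fold clinical aortic-segmentation experiments: `"sanet"` for the
#' shallow-attention model, `"unet"` for the plain encoder-decoder baseline.
#' Useful as input to [aggregate_folds].
#'
#' @param model `"sanet"` or `"unet"`.
#' @return data.frame with columns `fold_id`, `dice_all`, `dice_retained`,
#'   `iou_all`, `iou_retained`.
#' @export
reference_fold_metrics <- function(model = c("sanet", "unet")) {
  model <- match.arg(model)
  f <- system.file("extdata", paste0(model, "_fold_metrics.csv"),
                   package = "aodmeter", mustWork = TRUE)
  read.csv(f, stringsAsFactors = FALSE)
}
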