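## Evaluation metrics: confusion tallies and the four segmentation metrics
## (Dice similarity, relative area difference, sensitivity, accuracy), per
## image and aggregated over a dataset.

#' Pixel confusion counts
#'
#' @param predBin numeric H x W matrix in \{0, 1\} (binarized prediction).
#' @param gt numeric H x W matrix in \{0, 1\}.
#' @return named integer vector `(tp, tn, fp, fn)`.
#' @examples
#' gt <- matrix(c(1, 1, 0, 0), 2, 2)
#' confusionCounts(gt, gt)  # fp = fn = 0
#' @export
confusionCounts <- function(predBin, gt) {
  checkBinMask(predBin); checkBinMask(gt); checkSameShape(predBin, gt)
  tp <- sum(predBin == 1 & gt == 1)
  tn <- sum(predBin == 0 & gt == 0)
  fp <- sum(predBin == 1 & gt == 0)
  fn <- sum(predBin == 0 & gt == 1)
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Segmentation metrics from confusion counts
#'
#' DSC = 2TP/(2TP+FP+FN); relative area difference
#' \eqn{\Delta A = |(TP+FP)-(TP+FN)|/(TP+FN)}; sensitivity = TP/(TP+FN);
#' accuracy = (TP+TN)/(TP+TN+FP+FN). Degenerate denominators: with both
#' masks empty, DSC = 1, sensitivity = 1 and deltaA = 0 by convention; with
#' an empty ground truth but a nonempty prediction, DSC = 0 and sensitivity
#' and deltaA are `NA` (excluded from aggregation).
#'
#' @param counts named vector with elements `tp`, `tn`, `fp`, `fn`.
#' @return named numeric vector `(dsc, deltaA, sensitivity, accuracy)` on the
#'   0--1 scale (deltaA may exceed 1).
#' @examples
#' computeMetrics(c(tp = 8, tn = 88, fp = 2, fn = 2))
#' @export
computeMetrics <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  gtPos <- tp + fn
  predPos <- tp + fp
  dsc <- if (gtPos == 0 && predPos == 0) 1
         else 2 * tp / (2 * tp + fp + fn)
  deltaA <- if (gtPos == 0) { if (predPos == 0) 0 else NA_real_ }
            else abs(predPos - gtPos) / gtPos
  sens <- if (gtPos == 0) { if (predPos == 0) 1 else NA_real_ }
          else tp / gtPos
  acc <- (tp + tn) / (tp + tn + fp + fn)
  c(dsc = dsc, deltaA = deltaA, sensitivity = sens, accuracy = acc)
}

#' Evaluate a dataset of predicted masks
#'
#' Binarizes each prediction at `threshold`, computes per-image metrics and
#' aggregates. Macro aggregation is the unweighted mean over images for which
#' a metric is defined; micro aggregation pools the pixel tallies first.
#'
#' @param predMasks list of probability matrices.
#' @param gtMasks list of binary matrices, same length.
#' @param threshold binarization threshold in (0, 1).
#' @param aggregation `"macro"` (default) or `"micro"`.
#' @return a [MetricReport-class].
#' @export
evaluateDataset <- function(predMasks, gtMasks, threshold = 0.5,
                            aggregation = c("macro", "micro")) {
  aggregation <- match.arg(aggregation)
  if (length(predMasks) != length(gtMasks))
    stop("prediction and ground-truth collections differ in length", call. = FALSE)
  if (length(predMasks) == 0L) stop("empty dataset", call. = FALSE)
  if (length(threshold) != 1L || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  rows <- vector("list", length(predMasks))
  pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in seq_along(predMasks)) {
    checkProbMask(predMasks[[i]])
    pb <- (predMasks[[i]] >= threshold) * 1
    cc <- confusionCounts(pb, gtMasks[[i]])
    pooled <- pooled + cc
    m <- computeMetrics(cc)
    rows[[i]] <- data.frame(image = i, tp = cc[["tp"]], tn = cc[["tn"]],
                            fp = cc[["fp"]], fn = cc[["fn"]],
                            dsc = m[["dsc"]], deltaA = m[["deltaA"]],
                            sensitivity = m[["sensitivity"]],
                            accuracy = m[["accuracy"]])
  }
  perImage <- do.call(rbind, rows)
  if (aggregation == "macro") {
    agg <- vapply(c("dsc", "deltaA", "sensitivity", "accuracy"),
                  function(col) mean(perImage[[col]], na.rm = TRUE), 0)
  } else {
    agg <- computeMetrics(pooled)
  }
  new("MetricReport", perImage = perImage, dsc = unname(agg[["dsc"]]),
      deltaA = unname(agg[["deltaA"]]),
      sensitivity = unname(agg[["sensitivity"]]),
      accuracy = unname(agg[["accuracy"]]), aggregation = aggregation,
      threshold = threshold)
}

#' Write a metric report to files
#'
#' Emits the per-image table as CSV and the aggregates (x100, matching the
#' usual presentation of segmentation tables) as JSON.
#'
#' @param report a [MetricReport-class].
#' @param csvPath,jsonPath output paths; `NULL` skips that file.
#' @return invisibly, the list written to JSON.
#' @export
writeMetricReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  stopifnot(is(report, "MetricReport"))
  if (!is.null(csvPath)) write.csv(report@perImage, csvPath, row.names = FALSE)
  summary <- list(aggregation = report@aggregation,
                  threshold = report@threshold,
                  n_images = nrow(report@perImage),
                  dsc = 100 * report@dsc, delta_a = 100 * report@deltaA,
                  sensitivity = 100 * report@sensitivity,
                  accuracy = 100 * report@accuracy)
  if (!is.null(jsonPath))
    jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
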