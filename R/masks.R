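## Mask validation. Masks are plain numeric matrices: a probability mask has
## entries in [0,1], a binary mask entries in {0,1}. Dimension checks are
## shared by every loss.

checkProbMask <- function(pred) {
  if (!is.matrix(pred) || !is.numeric(pred))
    stop("prediction must be a numeric matrix", call. = FALSE)
  if (nrow(pred) < 1L || ncol(pred) < 1L)
    stop("prediction must have at least one row and column", call. = FALSE)
  if (anyNA(pred) || any(pred < 0 | pred > 1))
    stop("prediction values must lie in [0, 1]", call. = FALSE)
  invisible(pred)
}

checkBinMask <- function(gt) {
  if (!is.matrix(gt) || !is.numeric(gt))
    stop("ground truth must be a numeric matrix", call. = FALSE)
  if (anyNA(gt) || any(gt != 0 & gt != 1))
    stop("ground truth values must be 0 or 1", call. = FALSE)
  invisible(gt)
}

checkSameShape <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop(sprintf("mask shapes differ: %dx%d vs %dx%d", nrow(pred), ncol(pred),
                 nrow(gt), ncol(gt)), call. = FALSE)
  invisible(NULL)
}

clampProb <- function(pred, clamp) {
  if (length(clamp) != 1L || !is.finite(clamp) || clamp <= 0 || clamp >= 0.5)
    stop("clamp must lie in (0, 0.5)", call. = FALSE)
  pmin(pmax(pred, clamp), 1 - clamp)
}
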