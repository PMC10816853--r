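## Pixel-level losses: binary cross-entropy, soft dice, focal, and their
## static hybrid. Each function returns the scalar loss, or with
## gradient = TRUE a list(value, grad) where grad is the derivative of the
## loss with respect to every entry of the prediction (same shape as pred).
## BCE and focal are means over pixels so magnitudes are comparable across
## image sizes; dice is a single global quotient over the whole mask.

#' Binary cross-entropy loss
#'
#' Mean over pixels of \eqn{-[y \log \hat y + (1-y) \log(1-\hat y)]}, with the
#' prediction clamped into `[clamp, 1 - clamp]` before the logarithms.
#'
#' @param pred numeric H x W matrix of probabilities in \[0, 1\].
#' @param gt numeric H x W matrix with entries in \{0, 1\}.
#' @param clamp clamp in (0, 0.5) for log stability.
#' @param gradient if `TRUE`, also return the gradient w.r.t. `pred`.
#' @return non-negative scalar, or `list(value, grad)` when `gradient = TRUE`.
#'   The gradient is 0 at clamped pixels.
#' @examples
#' gt <- matrix(c(0, 1, 1, 0), 2, 2)
#' bceLoss(matrix(0.5, 2, 2), gt)  # log(2)
#' @export
bceLoss <- function(pred, gt, clamp = 1e-7, gradient = FALSE) {
  checkProbMask(pred); checkBinMask(gt); checkSameShape(pred, gt)
  p <- clampProb(pred, clamp)
  n <- length(p)
  value <- -sum(gt * log(p) + (1 - gt) * log(1 - p)) / n
  if (!gradient) return(value)
  g <- (-gt / p + (1 - gt) / (1 - p)) / n
  g[pred < clamp | pred > 1 - clamp] <- 0
  list(value = value, grad = g)
}

#' Soft dice loss
#'
#' One minus a smoothed overlap quotient over the whole mask. The `"paper"`
#' dialect is \eqn{1 - (\sum \hat y y + \epsilon)/(\sum \hat y + \sum y +
#' \epsilon)}; the `"standard"` dialect doubles the numerator overlap,
#' \eqn{1 - (2\sum \hat y y + \epsilon)/(\sum \hat y + \sum y + \epsilon)},
#' the conventional soft dice. Both lie in \[0, 1\].
#'
#' @inheritParams bceLoss
#' @param epsilon positive smoothing constant.
#' @param dialect `"paper"` (default) or `"standard"`.
#' @return scalar in \[0, 1\], or `list(value, grad)`.
#' @examples
#' gt <- matrix(0, 4, 4); gt[2:3, 2:3] <- 1
#' diceLoss(gt, gt)                         # 1 - (s+1)/(2s+1)
#' diceLoss(gt, gt, dialect = "standard")   # ~0
#' @export
diceLoss <- function(pred, gt, epsilon = 1, dialect = c("paper", "standard"),
                     gradient = FALSE) {
  dialect <- match.arg(dialect)
  checkProbMask(pred); checkBinMask(gt); checkSameShape(pred, gt)
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0)
    stop("epsilon must be positive", call. = FALSE)
  k <- if (dialect == "standard") 2 else 1
  num <- k * sum(pred * gt) + epsilon
  den <- sum(pred) + sum(gt) + epsilon
  value <- 1 - num / den
  if (!gradient) return(value)
  g <- -(k * gt * den - num) / den^2
  list(value = value, grad = g)
}

#' Focal loss
#'
#' With \eqn{\hat Y_t} the predicted probability of the true class
#' (\eqn{\hat y} where \eqn{y = 1}, \eqn{1-\hat y} where \eqn{y = 0}), the
#' mean over pixels of \eqn{-(1-\hat Y_t)^\upsilon \log \hat Y_t}. The
#' focusing parameter `upsilon` down-weights well-classified pixels; at
#' `upsilon = 0` the loss equals [bceLoss()].
#'
#' @inheritParams bceLoss
#' @param upsilon non-negative focusing parameter.
#' @return non-negative scalar, or `list(value, grad)`.
#' @examples
#' gt <- matrix(1, 1, 1)
#' focalLoss(matrix(0.5, 1, 1), gt, upsilon = 2)  # 0.25 * log(2)
#' @export
focalLoss <- function(pred, gt, upsilon, clamp = 1e-7, gradient = FALSE) {
  if (length(upsilon) != 1L || !is.finite(upsilon) || upsilon < 0)
    stop("upsilon must be a single non-negative number", call. = FALSE)
  checkProbMask(pred); checkBinMask(gt); checkSameShape(pred, gt)
  p <- clampProb(pred, clamp)
  pt <- ifelse(gt == 1, p, 1 - p)
  n <- length(pt)
  omt <- 1 - pt
  value <- -sum(omt^upsilon * log(pt)) / n
  if (!gradient) return(value)
  ## d/dpt of -(1-pt)^u log(pt); the u*(1-pt)^(u-1) factor is 0 when u = 0
  dpt <- if (upsilon > 0) upsilon * omt^(upsilon - 1) * log(pt) - omt^upsilon / pt
         else -1 / pt
  sgn <- ifelse(gt == 1, 1, -1)
  g <- sgn * dpt / n
  g[pred < clamp | pred > 1 - clamp] <- 0
  list(value = value, grad = g)
}

#' Static pixel-level hybrid loss
#'
#' Weighted sum `alpha * dice + beta * BCE` with weights and constants taken
#' from a [PixelLossConfig-class].
#'
#' @inheritParams bceLoss
#' @param cfg a [PixelLossConfig-class].
#' @return non-negative scalar, or `list(value, grad)`.
#' @examples
#' gt <- matrix(0, 4, 4); gt[1:2, 1:2] <- 1
#' pred <- matrix(0.4, 4, 4)
#' hybridPixelLoss(pred, gt, pixelLossConfig())
#' @export
hybridPixelLoss <- function(pred, gt, cfg = pixelLossConfig(), gradient = FALSE) {
  stopifnot(is(cfg, "PixelLossConfig"))
  validObject(cfg)
  d <- diceLoss(pred, gt, epsilon = cfg@diceEpsilon, dialect = cfg@diceDialect,
                gradient = gradient)
  b <- bceLoss(pred, gt, clamp = cfg@probClamp, gradient = gradient)
  if (!gradient) return(cfg@alpha * d + cfg@beta * b)
  list(value = cfg@alpha * d$value + cfg@beta * b$value,
       grad = cfg@alpha * d$grad + cfg@beta * b$grad)
}
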