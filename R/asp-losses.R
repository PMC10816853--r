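## The adaptive sample-level prioritizing losses: the ratio-driven hybrid
## (with binary group indicator or continuous ratio), the learned-weight
## variant and its subnetwork, the density-driven hybrid that adds a
## theta-scaled region-level term, and the adaptive focal variants.

#' Ratio-driven adaptive hybrid loss
#'
#' `(iDice + (1 - p)^gammaDice) * dice + (iBce + p^gammaBce) * BCE`: the dice
#' term is prioritized for small-mass samples (`p = 0`), where pixel class
#' imbalance is severe, and BCE for large-mass samples (`p = 1`). With a
#' binary `p` the exponents are inert (`0^g = 0`, `1^g = 1`); in
#' `pMode = "continuous"` a normalized ratio in \[0, 1\] may be supplied and
#' the exponents shape the transition.
#'
#' @inheritParams bceLoss
#' @param p group indicator in \{0, 1\} (binary mode) or a real in \[0, 1\]
#'   (continuous mode).
#' @param cfg a [RaspConfig-class].
#' @param pixelCfg a [PixelLossConfig-class] supplying the dice epsilon,
#'   dialect and probability clamp of the constituents.
#' @return non-negative scalar, or `list(value, grad)`.
#' @examples
#' gt <- matrix(0, 8, 8); gt[2:3, 2:3] <- 1
#' pred <- matrix(0.3, 8, 8)
#' raspLoss(pred, gt, p = 0)  # dice-prioritized
#' @export
raspLoss <- function(pred, gt, p, cfg = raspConfig(),
                     pixelCfg = pixelLossConfig(), gradient = FALSE) {
  stopifnot(is(cfg, "RaspConfig"), is(pixelCfg, "PixelLossConfig"))
  validObject(cfg); validObject(pixelCfg)
  if (length(p) != 1L || !is.finite(p)) stop("p must be a single number", call. = FALSE)
  if (cfg@pMode == "binary") {
    if (!p %in% c(0, 1)) stop("p must be 0 or 1 in binary mode", call. = FALSE)
  } else if (p < 0 || p > 1) {
    stop("p must lie in [0, 1] in continuous mode", call. = FALSE)
  }
  wDice <- cfg@iDice + (1 - p)^cfg@gammaDice
  wBce <- cfg@iBce + p^cfg@gammaBce
  d <- diceLoss(pred, gt, epsilon = pixelCfg@diceEpsilon,
                dialect = pixelCfg@diceDialect, gradient = gradient)
  b <- bceLoss(pred, gt, clamp = pixelCfg@probClamp, gradient = gradient)
  if (!gradient) return(wDice * d + wBce * b)
  list(value = wDice * d$value + wBce * b$value,
       grad = wDice * d$grad + wBce * b$grad)
}

## ---- learned-weight subnetwork ------------------------------------------

#' Construct a learned loss-weight subnetwork
#'
#' @param imageSize integer length 2, the (H, W) of the masks the net reads.
#' @param hiddenSize hidden layer width.
#' @param poolFactor average-pooling factor applied to the mask first.
#' @param normalization `"sum2"` (softmax scaled to sum to 2, the default,
#'   which prevents joint collapse of both weights to 0) or `"softplus"`
#'   (unnormalized strictly positive outputs).
#' @param seed integer used for weight initialization.
#' @param zeroOutput if `TRUE` the output layer starts at zero, so the net
#'   initially emits weights (1, 1) under `"sum2"`.
#' @return an [LraspWeightNet-class].
#' @examples
#' net <- lraspWeightNet(c(16, 16), zeroOutput = TRUE)
#' lraspWeights(matrix(0, 16, 16), net)  # c(1, 1)
#' @export
lraspWeightNet <- function(imageSize, hiddenSize = 8L, poolFactor = 4L,
                           normalization = c("sum2", "softplus"), seed = 1L,
                           zeroOutput = FALSE) {
  normalization <- match.arg(normalization)
  imageSize <- as.integer(imageSize)
  d <- prod(imageSize %/% as.integer(poolFactor))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  W1 <- matrix(rnorm(hiddenSize * d, sd = sqrt(2 / d)), hiddenSize, d)
  b1 <- numeric(hiddenSize)
  W2 <- if (zeroOutput) matrix(0, 2, hiddenSize) else
    matrix(rnorm(2 * hiddenSize, sd = sqrt(1 / hiddenSize)), 2, hiddenSize)
  b2 <- numeric(2)
  new("LraspWeightNet", imageSize = imageSize,
      poolFactor = as.integer(poolFactor), hiddenSize = as.integer(hiddenSize),
      W1 = W1, b1 = b1, W2 = W2, b2 = b2, normalization = normalization)
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.lraspParamVec <- function(net)
  c(as.vector(net@W1), net@b1, as.vector(net@W2), net@b2)

.lraspSetParams <- function(net, v) {
  i <- 0L
  n1 <- length(net@W1); net@W1 <- matrix(v[i + seq_len(n1)], nrow(net@W1)); i <- i + n1
  nb1 <- length(net@b1); net@b1 <- v[i + seq_len(nb1)]; i <- i + nb1
  n2 <- length(net@W2); net@W2 <- matrix(v[i + seq_len(n2)], nrow(net@W2)); i <- i + n2
  net@b2 <- v[i + seq_len(length(net@b2))]
  net
}

#' Loss weights from the learned subnetwork
#'
#' Deterministic map from a ground-truth mask to the two strictly positive
#' loss weights `(wDice, wBce)`. With `gradient = TRUE` the Jacobian of the
#' weights w.r.t. the flattened network parameters is also returned.
#'
#' @param gt numeric H x W binary matrix matching the net's `imageSize`.
#' @param net an [LraspWeightNet-class].
#' @param gradient if `TRUE`, return `list(weights, jacobian)` where
#'   `jacobian` is 2 x n_params.
#' @return numeric length-2 vector `(wDice, wBce)`, or the list above.
#' @export
lraspWeights <- function(gt, net, gradient = FALSE) {
  stopifnot(is(net, "LraspWeightNet")); validObject(net)
  checkBinMask(gt)
  if (!identical(dim(gt), as.integer(net@imageSize)))
    stop("mask shape does not match the net's imageSize", call. = FALSE)
  v <- as.vector(.poolAvg(gt, net@poolFactor))
  z1 <- as.vector(net@W1 %*% v + net@b1)
  h <- pmax(z1, 0)
  o <- as.vector(net@W2 %*% h + net@b2)
  if (net@normalization == "sum2") {
    e <- exp(o - max(o)); sm <- e / sum(e)
    wts <- 2 * sm
  } else {
    wts <- log1p(exp(pmin(o, 30))) + 1e-12
    wts[o > 30] <- o[o > 30]
  }
  names(wts) <- c("wDice", "wBce")
  if (!gradient) return(wts)
  ## Jacobian rows by backprop, one per output weight
  J <- matrix(0, 2, length(.lraspParamVec(net)))
  for (i in 1:2) {
    if (net@normalization == "sum2") {
      do <- 2 * sm[i] * ((seq_len(2) == i) - sm)
    } else {
      do <- (seq_len(2) == i) * stats::plogis(o)
    }
    dW2 <- do %o% h
    db2 <- do
    dh <- as.vector(t(net@W2) %*% do)
    dh[z1 <= 0] <- 0
    dW1 <- dh %o% v
    db1 <- dh
    J[i, ] <- c(as.vector(dW1), db1, as.vector(dW2), db2)
  }
  list(weights = wts, jacobian = J)
}

#' Learned ratio-adaptive hybrid loss
#'
#' `wDice * dice + wBce * BCE` with weights produced by the learned
#' subnetwork from the ground truth. Gradients flow both to the prediction
#' and (via `paramGrad`) to the subnetwork parameters.
#'
#' @inheritParams bceLoss
#' @param net an [LraspWeightNet-class].
#' @param pixelCfg a [PixelLossConfig-class] for the constituents.
#' @return non-negative scalar, or `list(value, grad, paramGrad)`.
#' @export
lraspLoss <- function(pred, gt, net, pixelCfg = pixelLossConfig(),
                      gradient = FALSE) {
  stopifnot(is(pixelCfg, "PixelLossConfig")); validObject(pixelCfg)
  d <- diceLoss(pred, gt, epsilon = pixelCfg@diceEpsilon,
                dialect = pixelCfg@diceDialect, gradient = gradient)
  b <- bceLoss(pred, gt, clamp = pixelCfg@probClamp, gradient = gradient)
  if (!gradient) {
    wts <- lraspWeights(gt, net)
    return(unname(wts[1] * d + wts[2] * b))
  }
  wg <- lraspWeights(gt, net, gradient = TRUE)
  wts <- wg$weights
  list(value = unname(wts[1] * d$value + wts[2] * b$value),
       grad = wts[1] * d$grad + wts[2] * b$grad,
       paramGrad = as.vector(t(wg$jacobian) %*% c(d$value, b$value)))
}

## ---- density-driven hybrid ----------------------------------------------

#' Region-term coefficient for a density category
#'
#' One-hot encoding of the ACR density category dotted with the prioritizing
#' vector `theta`: category `c` selects `theta[c]`.
#'
#' @param densityCategory integer in 1--4.
#' @param theta numeric length-4 non-negative prioritizing vector.
#' @return `theta[densityCategory]`.
#' @examples
#' daspRegionCoefficient(3, c(0.5, 0.5, 0.85, 0.95))  # 0.85
#' @export
daspRegionCoefficient <- function(densityCategory, theta) {
  if (length(theta) != 4L || any(!is.finite(theta)) || any(theta < 0))
    stop("theta must be 4 non-negative numbers", call. = FALSE)
  if (length(densityCategory) != 1L || is.na(densityCategory) ||
      !densityCategory %in% 1:4)
    stop("densityCategory must be one of 1, 2, 3, 4", call. = FALSE)
  unname(theta[densityCategory])
}

#' Density-driven adaptive hybrid loss
#'
#' Pixel-level hybrid plus the region-level hybrid scaled by the sample's
#' density coefficient: `theta[d] * (eta * RMI + tau * SSIM) + (alpha * dice +
#' beta * BCE)`. Region-level structure gets more weight for denser breasts,
#' where masses are harder to tell from surrounding tissue.
#'
#' @inheritParams bceLoss
#' @param densityCategory integer in 1--4 (ACR category of the sample).
#' @param cfg a [DaspConfig-class].
#' @return scalar, or `list(value, grad)`.
#' @export
daspLoss <- function(pred, gt, densityCategory, cfg = daspConfig(),
                     gradient = FALSE) {
  stopifnot(is(cfg, "DaspConfig")); validObject(cfg)
  coef <- daspRegionCoefficient(densityCategory, cfg@theta)
  hp <- hybridPixelLoss(pred, gt, cfg@pixel, gradient = gradient)
  if (coef == 0) {
    if (!gradient) return(hp)
    return(hp)
  }
  hr <- hybridRegionLoss(pred, gt, cfg@region, gradient = gradient)
  if (!gradient) return(coef * hr + hp)
  list(value = coef * hr$value + hp$value,
       grad = coef * hr$grad + hp$grad)
}

## ---- adaptive focal -----------------------------------------------------

#' Per-sample focusing parameter
#'
#' Looks up the focal focusing parameter for a sample: in `"ratio"` mode from
#' its assigned size group (small/large), in `"density"` mode from its ACR
#' density category.
#'
#' @param meta a [SampleMeta-class].
#' @param cfg an [AdaptiveFocalConfig-class].
#' @return non-negative scalar focusing parameter.
#' @examples
#' adaptiveUpsilon(sampleMeta(0.01, group = 0L), adaptiveFocalConfig())  # 0.25
#' @export
adaptiveUpsilon <- function(meta, cfg = adaptiveFocalConfig()) {
  stopifnot(is(meta, "SampleMeta"), is(cfg, "AdaptiveFocalConfig"))
  validObject(meta); validObject(cfg)
  if (cfg@mode == "ratio") {
    if (is.na(meta@group))
      stop("sample has no assigned size group; apply a grouping model first",
           call. = FALSE)
    unname(cfg@upsilonByGroup[meta@group + 1L])
  } else {
    unname(cfg@upsilonByDensity[meta@densityCategory])
  }
}

#' Adaptive focal loss
#'
#' [focalLoss()] evaluated at the per-sample focusing parameter from
#' [adaptiveUpsilon()]: easy pixels in easy samples (large masses, or low
#' density) are down-weighted more.
#'
#' @inheritParams bceLoss
#' @param meta a [SampleMeta-class].
#' @param cfg an [AdaptiveFocalConfig-class].
#' @return non-negative scalar, or `list(value, grad)`.
#' @export
adaptiveFocalLoss <- function(pred, gt, meta, cfg = adaptiveFocalConfig(),
                              gradient = FALSE) {
  u <- adaptiveUpsilon(meta, cfg)
  focalLoss(pred, gt, upsilon = u, clamp = cfg@probClamp, gradient = gradient)
}
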