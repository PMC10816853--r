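## S4 classes for loss configuration, sample metadata, grouping models and
## reports. Masks themselves are plain numeric matrices (see checkProbMask /
## checkBinMask): every loss operates on an H x W matrix, as image packages do
## with arrays.

.scalarNonneg <- function(x) length(x) == 1L && is.finite(x) && x >= 0
.scalarPos <- function(x) length(x) == 1L && is.finite(x) && x > 0

#' Pixel-level loss configuration
#'
#' Holds the weights and numerical constants of the static pixel-level hybrid
#' loss: `alpha` scales the soft-dice term and `beta` the binary cross-entropy
#' term, `diceEpsilon` is the smoothing constant of the dice quotient and
#' `probClamp` bounds predicted probabilities away from 0 and 1 before any
#' logarithm. `diceDialect` selects between the dice quotient written without
#' the factor 2 in the numerator (`"paper"`, the default) and the conventional
#' soft dice with the 2x numerator (`"standard"`).
#'
#' @slot alpha numeric, non-negative dice weight.
#' @slot beta numeric, non-negative BCE weight.
#' @slot diceEpsilon numeric, positive smoothing constant.
#' @slot probClamp numeric in (0, 0.5), clamp for log stability.
#' @slot diceDialect character, `"paper"` or `"standard"`.
#' @export
setClass("PixelLossConfig",
  representation(alpha = "numeric", beta = "numeric", diceEpsilon = "numeric",
                 probClamp = "numeric", diceDialect = "character"),
  prototype(alpha = 1, beta = 1, diceEpsilon = 1, probClamp = 1e-7,
            diceDialect = "paper"))

setValidity("PixelLossConfig", function(object) {
  msg <- character()
  if (!.scalarNonneg(object@alpha)) msg <- c(msg, "alpha must be a single non-negative number")
  if (!.scalarNonneg(object@beta)) msg <- c(msg, "beta must be a single non-negative number")
  if (!.scalarPos(object@diceEpsilon)) msg <- c(msg, "diceEpsilon must be positive")
  if (!(length(object@probClamp) == 1L && object@probClamp > 0 && object@probClamp < 0.5))
    msg <- c(msg, "probClamp must lie in (0, 0.5)")
  if (!object@diceDialect %in% c("paper", "standard"))
    msg <- c(msg, "diceDialect must be 'paper' or 'standard'")
  if (length(msg)) msg else TRUE
})

#' @rdname PixelLossConfig-class
#' @param alpha,beta,diceEpsilon,probClamp,diceDialect see slots.
#' @return a `PixelLossConfig` object.
#' @examples
#' pixelLossConfig(alpha = 2, beta = 1)
#' @export
pixelLossConfig <- function(alpha = 1, beta = 1, diceEpsilon = 1,
                            probClamp = 1e-7, diceDialect = c("paper", "standard")) {
  new("PixelLossConfig", alpha = alpha, beta = beta, diceEpsilon = diceEpsilon,
      probClamp = probClamp, diceDialect = match.arg(diceDialect))
}

#' Structural-similarity loss configuration
#'
#' Window and stabilization constants of the SSIM loss. Defaults follow the
#' original SSIM convention: an 11x11 Gaussian window with sigma 1.5 and
#' constants C1 = (0.01 L)^2, C2 = (0.03 L)^2 with dynamic range L = 1 for
#' probability masks. A uniform window is available (useful for oracle
#' testing).
#'
#' @slot windowSize integer, odd window side in pixels.
#' @slot windowKind character, `"gaussian"` or `"uniform"`.
#' @slot gaussianSigma numeric, Gaussian window sigma in pixels.
#' @slot c1,c2 numeric, positive stabilization constants.
#' @slot dynamicRange numeric, value range L of the inputs.
#' @export
setClass("SsimConfig",
  representation(windowSize = "integer", windowKind = "character",
                 gaussianSigma = "numeric", c1 = "numeric", c2 = "numeric",
                 dynamicRange = "numeric"),
  prototype(windowSize = 11L, windowKind = "gaussian", gaussianSigma = 1.5,
            c1 = 1e-4, c2 = 9e-4, dynamicRange = 1))

setValidity("SsimConfig", function(object) {
  msg <- character()
  if (object@windowSize < 1L || object@windowSize %% 2L == 0L)
    msg <- c(msg, "windowSize must be odd and positive")
  if (!object@windowKind %in% c("gaussian", "uniform"))
    msg <- c(msg, "windowKind must be 'gaussian' or 'uniform'")
  if (!.scalarPos(object@gaussianSigma)) msg <- c(msg, "gaussianSigma must be positive")
  if (!.scalarPos(object@c1) || !.scalarPos(object@c2)) msg <- c(msg, "c1 and c2 must be positive")
  if (!.scalarPos(object@dynamicRange)) msg <- c(msg, "dynamicRange must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SsimConfig-class
#' @param windowSize,windowKind,gaussianSigma,dynamicRange,c1,c2 see slots;
#'   `c1`/`c2` default to `(0.01 L)^2` and `(0.03 L)^2`.
#' @return an `SsimConfig` object.
#' @export
ssimConfig <- function(windowSize = 11L, windowKind = c("gaussian", "uniform"),
                       gaussianSigma = 1.5, dynamicRange = 1,
                       c1 = (0.01 * dynamicRange)^2, c2 = (0.03 * dynamicRange)^2) {
  new("SsimConfig", windowSize = as.integer(windowSize),
      windowKind = match.arg(windowKind), gaussianSigma = gaussianSigma,
      c1 = c1, c2 = c2, dynamicRange = dynamicRange)
}

#' Regional mutual-information loss configuration
#'
#' Settings of the covariance-based lower-bound surrogate of regional mutual
#' information: neighborhoods of side `regionSize` around each pixel become
#' `regionSize^2`-dimensional points; both masks may first be pooled by
#' `downsampleFactor`; `regularizationEpsilon` scales the ridge added to the
#' covariance diagonals (relative to the mean ground-truth variance, with a
#' tiny absolute floor so constant masks stay well-posed).
#'
#' @slot regionSize integer >= 2, neighborhood side in pixels.
#' @slot downsampleFactor integer >= 1, pooling factor before extraction.
#' @slot pooling character, `"avg"`, `"max"` or `"none"`.
#' @slot regularizationEpsilon numeric, positive relative ridge.
#' @export
setClass("RmiConfig",
  representation(regionSize = "integer", downsampleFactor = "integer",
                 pooling = "character", regularizationEpsilon = "numeric"),
  prototype(regionSize = 3L, downsampleFactor = 2L, pooling = "avg",
            regularizationEpsilon = 5e-4))

setValidity("RmiConfig", function(object) {
  msg <- character()
  if (object@regionSize < 2L) msg <- c(msg, "regionSize must be >= 2")
  if (object@downsampleFactor < 1L) msg <- c(msg, "downsampleFactor must be >= 1")
  if (!object@pooling %in% c("avg", "max", "none"))
    msg <- c(msg, "pooling must be 'avg', 'max' or 'none'")
  if (!.scalarPos(object@regularizationEpsilon))
    msg <- c(msg, "regularizationEpsilon must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname RmiConfig-class
#' @param regionSize,downsampleFactor,pooling,regularizationEpsilon see slots.
#' @return an `RmiConfig` object.
#' @export
rmiConfig <- function(regionSize = 3L, downsampleFactor = 2L,
                      pooling = c("avg", "max", "none"),
                      regularizationEpsilon = 5e-4) {
  new("RmiConfig", regionSize = as.integer(regionSize),
      downsampleFactor = as.integer(downsampleFactor),
      pooling = match.arg(pooling), regularizationEpsilon = regularizationEpsilon)
}

#' Region-level hybrid loss configuration
#'
#' `eta` weights the regional mutual-information term and `tau` the SSIM term
#' of the static region-level hybrid.
#'
#' @slot eta numeric, non-negative RMI weight.
#' @slot tau numeric, non-negative SSIM weight.
#' @slot ssim an [SsimConfig-class].
#' @slot rmi an [RmiConfig-class].
#' @export
setClass("RegionLossConfig",
  representation(eta = "numeric", tau = "numeric", ssim = "SsimConfig",
                 rmi = "RmiConfig"),
  prototype(eta = 1, tau = 1))

setValidity("RegionLossConfig", function(object) {
  msg <- character()
  if (!.scalarNonneg(object@eta)) msg <- c(msg, "eta must be a single non-negative number")
  if (!.scalarNonneg(object@tau)) msg <- c(msg, "tau must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' @rdname RegionLossConfig-class
#' @param eta,tau,ssim,rmi see slots.
#' @return a `RegionLossConfig` object.
#' @export
regionLossConfig <- function(eta = 1, tau = 1, ssim = ssimConfig(), rmi = rmiConfig()) {
  new("RegionLossConfig", eta = eta, tau = tau, ssim = ssim, rmi = rmi)
}

#' Ratio-driven adaptive loss configuration
#'
#' Initial weights and exponents of the ratio-driven adaptive hybrid: the
#' dice coefficient is `iDice + (1 - p)^gammaDice` and the BCE coefficient is
#' `iBce + p^gammaBce`, where `p` is the sample's size-group indicator (0 =
#' small, 1 = large). With `pMode = "continuous"` the normalized mass ratio is
#' used for `p` instead, making the exponents active.
#'
#' @slot iDice,iBce numeric, non-negative initial weights.
#' @slot gammaDice,gammaBce numeric, positive exponents.
#' @slot pMode character, `"binary"` or `"continuous"`.
#' @export
setClass("RaspConfig",
  representation(iDice = "numeric", iBce = "numeric", gammaDice = "numeric",
                 gammaBce = "numeric", pMode = "character"),
  prototype(iDice = 1, iBce = 1, gammaDice = 0.25, gammaBce = 0.35,
            pMode = "binary"))

setValidity("RaspConfig", function(object) {
  msg <- character()
  if (!.scalarNonneg(object@iDice) || !.scalarNonneg(object@iBce))
    msg <- c(msg, "iDice and iBce must be single non-negative numbers")
  if (!.scalarPos(object@gammaDice) || !.scalarPos(object@gammaBce))
    msg <- c(msg, "gammaDice and gammaBce must be positive")
  if (!object@pMode %in% c("binary", "continuous"))
    msg <- c(msg, "pMode must be 'binary' or 'continuous'")
  if (length(msg)) msg else TRUE
})

#' @rdname RaspConfig-class
#' @param iDice,iBce,gammaDice,gammaBce,pMode see slots.
#' @return a `RaspConfig` object.
#' @export
raspConfig <- function(iDice = 1, iBce = 1, gammaDice = 0.25, gammaBce = 0.35,
                       pMode = c("binary", "continuous")) {
  new("RaspConfig", iDice = iDice, iBce = iBce, gammaDice = gammaDice,
      gammaBce = gammaBce, pMode = match.arg(pMode))
}

#' Density-driven adaptive loss configuration
#'
#' `theta` is the prioritizing vector: one non-negative weight per ACR density
#' category (1--4) that scales the region-level hybrid term added on top of
#' the pixel-level hybrid.
#'
#' @slot theta numeric length 4, non-negative per-category weights.
#' @slot pixel a [PixelLossConfig-class].
#' @slot region a [RegionLossConfig-class].
#' @export
setClass("DaspConfig",
  representation(theta = "numeric", pixel = "PixelLossConfig",
                 region = "RegionLossConfig"),
  prototype(theta = c(0.5, 0.5, 0.85, 0.95)))

setValidity("DaspConfig", function(object) {
  if (length(object@theta) != 4L || any(!is.finite(object@theta)) || any(object@theta < 0))
    "theta must be 4 non-negative numbers" else TRUE
})

#' @rdname DaspConfig-class
#' @param theta,pixel,region see slots.
#' @return a `DaspConfig` object.
#' @export
daspConfig <- function(theta = c(0.5, 0.5, 0.85, 0.95),
                       pixel = pixelLossConfig(alpha = 2, beta = 1),
                       region = regionLossConfig()) {
  new("DaspConfig", theta = theta, pixel = pixel, region = region)
}

#' Adaptive focal loss configuration
#'
#' Per-sample focusing parameter tables for the single-loss adaptive focal
#' variants: in `"ratio"` mode the focusing parameter is `upsilonByGroup[1]`
#' for the small size group and `upsilonByGroup[2]` for the large group; in
#' `"density"` mode it is `upsilonByDensity[c]` for density category `c`.
#'
#' @slot mode character, `"ratio"` or `"density"`.
#' @slot upsilonByGroup numeric length 2 `(small, large)`.
#' @slot upsilonByDensity numeric length 4.
#' @slot probClamp numeric in (0, 0.5).
#' @export
setClass("AdaptiveFocalConfig",
  representation(mode = "character", upsilonByGroup = "numeric",
                 upsilonByDensity = "numeric", probClamp = "numeric"),
  prototype(mode = "ratio", upsilonByGroup = c(0.25, 0.5),
            upsilonByDensity = c(0.2, 0.25, 0.3, 0.35), probClamp = 1e-7))

setValidity("AdaptiveFocalConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("ratio", "density"))
    msg <- c(msg, "mode must be 'ratio' or 'density'")
  if (object@mode == "ratio" &&
      (length(object@upsilonByGroup) != 2L || any(object@upsilonByGroup < 0) ||
       any(!is.finite(object@upsilonByGroup))))
    msg <- c(msg, "upsilonByGroup must be 2 non-negative numbers")
  if (object@mode == "density" &&
      (length(object@upsilonByDensity) != 4L || any(object@upsilonByDensity < 0) ||
       any(!is.finite(object@upsilonByDensity))))
    msg <- c(msg, "upsilonByDensity must be 4 non-negative numbers")
  if (length(msg)) msg else TRUE
})

#' @rdname AdaptiveFocalConfig-class
#' @param mode,upsilonByGroup,upsilonByDensity,probClamp see slots.
#' @return an `AdaptiveFocalConfig` object.
#' @export
adaptiveFocalConfig <- function(mode = c("ratio", "density"),
                                upsilonByGroup = c(0.25, 0.5),
                                upsilonByDensity = c(0.2, 0.25, 0.3, 0.35),
                                probClamp = 1e-7) {
  new("AdaptiveFocalConfig", mode = match.arg(mode),
      upsilonByGroup = upsilonByGroup, upsilonByDensity = upsilonByDensity,
      probClamp = probClamp)
}

#' Per-sample metadata
#'
#' The mass-to-image ratio, the ACR density category and (once a grouping
#' model has been applied) the size-group indicator of one sample.
#'
#' @slot ratio numeric in \[0, 1\].
#' @slot densityCategory integer in 1--4.
#' @slot group integer 0 (small), 1 (large) or `NA` (unassigned).
#' @export
setClass("SampleMeta",
  representation(ratio = "numeric", densityCategory = "integer",
                 group = "integer"),
  prototype(ratio = 0, densityCategory = 1L, group = NA_integer_))

setValidity("SampleMeta", function(object) {
  msg <- character()
  if (!(length(object@ratio) == 1L && is.finite(object@ratio) &&
        object@ratio >= 0 && object@ratio <= 1))
    msg <- c(msg, "ratio must lie in [0, 1]")
  if (!(length(object@densityCategory) == 1L &&
        object@densityCategory %in% 1:4))
    msg <- c(msg, "densityCategory must be one of 1, 2, 3, 4")
  if (!(length(object@group) == 1L && (is.na(object@group) || object@group %in% 0:1)))
    msg <- c(msg, "group must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' @rdname SampleMeta-class
#' @param ratio,densityCategory,group see slots.
#' @return a `SampleMeta` object.
#' @export
sampleMeta <- function(ratio, densityCategory = 1L, group = NA_integer_) {
  new("SampleMeta", ratio = as.numeric(ratio),
      densityCategory = as.integer(densityCategory), group = as.integer(group))
}

#' Fitted size-grouping model
#'
#' Maps a mass ratio to the small (0) or large (1) size group. Strategies:
#' `"quantile"` thresholds at the median of the training ratios, `"value"` at
#' their mean, `"cluster"` assigns to the nearer of two 1-D k-means centers
#' (fitted exactly by split-point enumeration).
#'
#' @slot strategy character, `"quantile"`, `"value"` or `"cluster"`.
#' @slot threshold numeric, length 1 for quantile/value, else length 0.
#' @slot centers numeric, length 2 strictly increasing for cluster, else 0.
#' @slot fittedOn integer, number of training ratios.
#' @export
setClass("GroupingModel",
  representation(strategy = "character", threshold = "numeric",
                 centers = "numeric", fittedOn = "integer"),
  prototype(strategy = "quantile", threshold = numeric(0),
            centers = numeric(0), fittedOn = 0L))

setValidity("GroupingModel", function(object) {
  msg <- character()
  if (!object@strategy %in% c("quantile", "value", "cluster"))
    msg <- c(msg, "strategy must be 'quantile', 'value' or 'cluster'")
  if (object@strategy %in% c("quantile", "value")) {
    if (length(object@threshold) != 1L) msg <- c(msg, "threshold must have length 1")
    if (length(object@centers) != 0L) msg <- c(msg, "centers must be empty for this strategy")
  } else if (object@strategy == "cluster") {
    if (length(object@centers) != 2L || !(object@centers[1] < object@centers[2]))
      msg <- c(msg, "centers must be 2 strictly increasing values")
    if (length(object@threshold) != 0L) msg <- c(msg, "threshold must be empty for cluster")
  }
  if (length(msg)) msg else TRUE
})

#' Learned loss-weight subnetwork
#'
#' A small trainable map from a ground-truth mask to the two positive weights
#' of the learned ratio-adaptive hybrid: the mask is average-pooled by
#' `poolFactor`, flattened, passed through one ReLU hidden layer and a linear
#' output layer. Under `normalization = "sum2"` the two outputs are softmaxed
#' and scaled to sum to 2 (so a zeroed output layer yields weights (1, 1));
#' `"softplus"` gives unnormalized strictly positive outputs.
#'
#' @slot imageSize integer length 2, (H, W) the net expects.
#' @slot poolFactor integer, average-pooling factor applied to the mask.
#' @slot hiddenSize integer, hidden layer width.
#' @slot W1,b1,W2,b2 numeric parameter arrays.
#' @slot normalization character, `"sum2"` or `"softplus"`.
#' @export
setClass("LraspWeightNet",
  representation(imageSize = "integer", poolFactor = "integer",
                 hiddenSize = "integer", W1 = "matrix", b1 = "numeric",
                 W2 = "matrix", b2 = "numeric", normalization = "character"))

setValidity("LraspWeightNet", function(object) {
  msg <- character()
  if (length(object@imageSize) != 2L || any(object@imageSize < 4L))
    msg <- c(msg, "imageSize must be 2 integers >= 4")
  if (any(object@imageSize %% object@poolFactor != 0L))
    msg <- c(msg, "imageSize must be divisible by poolFactor")
  if (!object@normalization %in% c("sum2", "softplus"))
    msg <- c(msg, "normalization must be 'sum2' or 'softplus'")
  d <- prod(object@imageSize %/% object@poolFactor)
  if (ncol(object@W1) != d || nrow(object@W1) != object@hiddenSize)
    msg <- c(msg, "W1 dimensions inconsistent with imageSize/hiddenSize")
  if (nrow(object@W2) != 2L || ncol(object@W2) != object@hiddenSize)
    msg <- c(msg, "W2 must be 2 x hiddenSize")
  if (length(msg)) msg else TRUE
})

#' Phantom generation settings
#'
#' Describes the synthetic mammogram-like phantoms: image size, the
#' right-skewed target mass-ratio distribution (log-normal by default, or a
#' two-mode mixture for grouping-recovery experiments), the density-category
#' mix, and how the density category is realized as background texture and
#' mass/background contrast (higher category = more texture, less contrast =
#' harder segmentation).
#'
#' @slot imageSize integer length 2 (H, W).
#' @slot ratioFamily character, `"lognormal"` or `"mixture"`.
#' @slot ratioParams numeric; for lognormal `(meanlog, sdlog)`, for mixture
#'   `(mean1, sd1, mean2, sd2, weight1)`.
#' @slot ratioRange numeric length 2, truncation interval.
#' @slot densityMix numeric length 4, category probabilities summing to 1.
#' @slot textureAmplitude numeric length 4, background noise sd per category.
#' @slot textureBlurSigma numeric length 4, noise correlation scale (pixels).
#' @slot contrastByDensity numeric length 4, mass/background intensity gap,
#'   strictly decreasing in the category.
#' @slot backgroundLevel numeric, base background intensity.
#' @slot massShape character, `"ellipse"` or `"perturbed-ellipse"`.
#' @slot perturbAmplitude numeric, radial boundary perturbation amplitude.
#' @slot seed integer.
#' @export
setClass("PhantomSpec",
  representation(imageSize = "integer", ratioFamily = "character",
                 ratioParams = "numeric", ratioRange = "numeric",
                 densityMix = "numeric", textureAmplitude = "numeric",
                 textureBlurSigma = "numeric", contrastByDensity = "numeric",
                 backgroundLevel = "numeric", massShape = "character",
                 perturbAmplitude = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@imageSize) != 2L || any(object@imageSize < 16L))
    msg <- c(msg, "imageSize must be 2 integers >= 16")
  if (!object@ratioFamily %in% c("lognormal", "mixture"))
    msg <- c(msg, "ratioFamily must be 'lognormal' or 'mixture'")
  rr <- object@ratioRange
  if (length(rr) != 2L || !(rr[1] > 0 && rr[1] < rr[2] && rr[2] <= 0.5))
    msg <- c(msg, "ratioRange must satisfy 0 < min < max <= 0.5")
  if (length(object@densityMix) != 4L ||
      abs(sum(object@densityMix) - 1) > 1e-9 || any(object@densityMix < 0))
    msg <- c(msg, "densityMix must be 4 probabilities summing to 1")
  if (length(object@contrastByDensity) != 4L ||
      any(diff(object@contrastByDensity) >= 0))
    msg <- c(msg, "contrastByDensity must be strictly decreasing over categories")
  if (length(object@textureAmplitude) != 4L || any(object@textureAmplitude < 0))
    msg <- c(msg, "textureAmplitude must be 4 non-negative values")
  if (length(object@textureBlurSigma) != 4L || any(object@textureBlurSigma <= 0))
    msg <- c(msg, "textureBlurSigma must be 4 positive values")
  if (!object@massShape %in% c("ellipse", "perturbed-ellipse"))
    msg <- c(msg, "massShape must be 'ellipse' or 'perturbed-ellipse'")
  if (length(msg)) msg else TRUE
})

#' @rdname PhantomSpec-class
#' @param imageSize,ratioFamily,ratioParams,ratioRange,densityMix see slots.
#' @param textureAmplitude,textureBlurSigma,contrastByDensity see slots.
#' @param backgroundLevel,massShape,perturbAmplitude,seed see slots.
#' @return a `PhantomSpec` object.
#' @examples
#' spec <- phantomSpec(imageSize = c(64, 64), seed = 1)
#' @export
phantomSpec <- function(imageSize = c(64L, 64L),
                        ratioFamily = c("lognormal", "mixture"),
                        ratioParams = c(-3.5, 0.8),
                        ratioRange = c(0.002, 0.35),
                        densityMix = c(0.35, 0.35, 0.2, 0.1),
                        textureAmplitude = c(0.03, 0.06, 0.09, 0.12),
                        textureBlurSigma = c(1.5, 2, 2.5, 3),
                        contrastByDensity = c(0.45, 0.38, 0.30, 0.22),
                        backgroundLevel = 0.35,
                        massShape = c("perturbed-ellipse", "ellipse"),
                        perturbAmplitude = 0.06, seed = 1L) {
  new("PhantomSpec", imageSize = as.integer(imageSize),
      ratioFamily = match.arg(ratioFamily), ratioParams = ratioParams,
      ratioRange = ratioRange, densityMix = densityMix,
      textureAmplitude = textureAmplitude, textureBlurSigma = textureBlurSigma,
      contrastByDensity = contrastByDensity, backgroundLevel = backgroundLevel,
      massShape = match.arg(massShape), perturbAmplitude = perturbAmplitude,
      seed = as.integer(seed))
}

#' One synthetic phantom
#'
#' @slot image numeric H x W matrix in \[0, 1\].
#' @slot mask numeric H x W matrix in \{0, 1\}.
#' @slot meta a [SampleMeta-class] whose ratio is recomputed from the mask.
#' @export
setClass("SyntheticSample",
  representation(image = "matrix", mask = "matrix", meta = "SampleMeta"))

#' Segmentation metric report
#'
#' Per-image and aggregated Dice similarity, relative area difference,
#' sensitivity and accuracy. Aggregates are unweighted means over images for
#' which the metric is defined (`"macro"`), or computed from pooled pixel
#' tallies (`"micro"`).
#'
#' @slot perImage data.frame, one row per image.
#' @slot dsc,deltaA,sensitivity,accuracy numeric aggregates.
#' @slot aggregation character, `"macro"` or `"micro"`.
#' @slot threshold numeric, binarization threshold used.
#' @export
setClass("MetricReport",
  representation(perImage = "data.frame", dsc = "numeric", deltaA = "numeric",
                 sensitivity = "numeric", accuracy = "numeric",
                 aggregation = "character", threshold = "numeric"))

#' Training run record
#'
#' @slot history data.frame with one row per epoch (training loss, validation
#'   metrics when a validation set was supplied).
#' @slot config list, snapshot of the training configuration.
#' @slot seed integer.
#' @export
setClass("TrainRecord",
  representation(history = "data.frame", config = "list", seed = "integer"))

#' Tiny encoder--decoder segmentation model
#'
#' A 3-level U-Net-style network with 16 base channels: two max-pooled
#' encoder convolutions, a bottleneck, nearest-neighbor upsampling with skip
#' concatenation, and a sigmoid 1x1 output head. Input images are z-score
#' standardized inside the forward pass.
#'
#' @slot descriptor character, architecture name.
#' @slot params list of convolution weight matrices and biases.
#' @slot channels integer vector of per-stage channel counts.
#' @export
setClass("UNetModel",
  representation(descriptor = "character", params = "list",
                 channels = "integer"))

## ---- show methods -------------------------------------------------------

setMethod("show", "GroupingModel", function(object) {
  cat("GroupingModel (strategy:", object@strategy, ")\n")
  if (length(object@threshold))
    cat("  threshold:", format(object@threshold, digits = 6), "\n")
  if (length(object@centers))
    cat("  centers:", paste(format(object@centers, digits = 6), collapse = ", "), "\n")
  cat("  fitted on:", object@fittedOn, "ratios\n")
})

setMethod("show", "SampleMeta", function(object) {
  cat(sprintf("SampleMeta: ratio %.5f, density %d, group %s\n", object@ratio,
              object@densityCategory,
              if (is.na(object@group)) "unassigned" else object@group))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport (%d images, %s aggregation, threshold %.2f)\n",
              nrow(object@perImage), object@aggregation, object@threshold))
  cat(sprintf("  DSC %.2f | DeltaA %.2f | Sensitivity %.2f | Accuracy %.2f (x100)\n",
              100 * object@dsc, 100 * object@deltaA, 100 * object@sensitivity,
              100 * object@accuracy))
})

setMethod("show", "UNetModel", function(object) {
  np <- sum(vapply(object@params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf("UNetModel '%s' (%d parameters)\n", object@descriptor, np))
})

setMethod("show", "TrainRecord", function(object) {
  cat(sprintf("TrainRecord: %d epochs, loss '%s', seed %d\n",
              nrow(object@history), object@config$lossName, object@seed))
  print(object@history, row.names = FALSE)
})

setMethod("show", "SyntheticSample", function(object) {
  cat(sprintf("SyntheticSample %dx%d, ratio %.5f, density %d\n",
              nrow(object@image), ncol(object@image), object@meta@ratio,
              object@meta@densityCategory))
})

## ---- accessors ----------------------------------------------------------

#' @describeIn GroupingModel-class grouping strategy name.
#' @param object,x a `GroupingModel`.
#' @export
setGeneric("groupingStrategy", function(object) standardGeneric("groupingStrategy"))
#' @rdname GroupingModel-class
#' @export
setMethod("groupingStrategy", "GroupingModel", function(object) object@strategy)

#' @describeIn GroupingModel-class dividing threshold (quantile/value strategies).
#' @export
setGeneric("groupingThreshold", function(object) standardGeneric("groupingThreshold"))
#' @rdname GroupingModel-class
#' @export
setMethod("groupingThreshold", "GroupingModel", function(object) object@threshold)

#' @describeIn GroupingModel-class cluster centers (cluster strategy).
#' @export
setGeneric("groupingCenters", function(object) standardGeneric("groupingCenters"))
#' @rdname GroupingModel-class
#' @export
setMethod("groupingCenters", "GroupingModel", function(object) object@centers)

#' Per-image metric table of a report
#' @param object a [MetricReport-class].
#' @return data.frame with one row per image.
#' @export
setGeneric("perImageMetrics", function(object) standardGeneric("perImageMetrics"))
#' @rdname perImageMetrics
#' @export
setMethod("perImageMetrics", "MetricReport", function(object) object@perImage)

#' Aggregate metrics of a report
#' @param object a [MetricReport-class].
#' @return named numeric vector (dsc, deltaA, sensitivity, accuracy), on the
#'   0--1 scale.
#' @export
setGeneric("aggregateMetrics", function(object) standardGeneric("aggregateMetrics"))
#' @rdname aggregateMetrics
#' @export
setMethod("aggregateMetrics", "MetricReport", function(object)
  c(dsc = object@dsc, deltaA = object@deltaA,
    sensitivity = object@sensitivity, accuracy = object@accuracy))

#' Training history of a run
#' @param object a [TrainRecord-class].
#' @return data.frame with one row per epoch.
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))
#' @rdname trainingHistory
#' @export
setMethod("trainingHistory", "TrainRecord", function(object) object@history)
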