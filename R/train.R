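## Training harness: the loss registry (every loss as a per-sample closure
## receiving that sample's metadata), the mini-batch training loop with Adam,
## and evaluation. Grouping models are fitted on the training split only and
## frozen; the loop averages per-sample losses over each batch, so metadata
## always travels with its sample.

#' Registered loss names
#'
#' @return character vector of the names accepted by [makeLoss()] and
#'   [trainConfig()].
#' @export
registeredLosses <- function() {
  c("bce", "dice", "hybrid", "focal", "qr_asp", "vr_asp", "cr_asp", "lr_asp",
    "d_asp", "sr_asp", "sd_asp")
}

## continuous relaxation of the group indicator for pMode = "continuous"
.continuousP <- function(model, ratio) {
  if (model@strategy %in% c("quantile", "value")) {
    min(1, ratio / (2 * model@threshold))
  } else {
    min(1, max(0, (ratio - model@centers[1]) /
                  (model@centers[2] - model@centers[1])))
  }
}

#' Construct a per-sample loss function
#'
#' Resolves a registered loss name to a closure
#' `function(pred, gt, meta, gradient = FALSE)`. Ratio-driven losses
#' (`qr_asp`, `vr_asp`, `cr_asp`, `sr_asp`) require a fitted
#' [GroupingModel-class] whose strategy matches the name; `lr_asp` uses the
#' supplied [LraspWeightNet-class] (its closure also returns `paramGrad`).
#' The plain `focal` loss uses the fixed focusing parameter
#' `focalUpsilon = 0.5`.
#'
#' @param name one of [registeredLosses()].
#' @param pixelCfg a [PixelLossConfig-class].
#' @param regionCfg a [RegionLossConfig-class].
#' @param raspCfg a [RaspConfig-class].
#' @param daspCfg a [DaspConfig-class]; defaults to one built from `pixelCfg`
#'   and `regionCfg`.
#' @param focalCfg an [AdaptiveFocalConfig-class] (its mode is set by the
#'   `sr_asp` / `sd_asp` choice).
#' @param focalUpsilon fixed focusing parameter of the plain focal loss.
#' @param groupingModel fitted [GroupingModel-class] or `NULL`.
#' @param weightNet an [LraspWeightNet-class] or `NULL`.
#' @return a closure `function(pred, gt, meta, gradient = FALSE)`.
#' @examples
#' lossFn <- makeLoss("hybrid")
#' gt <- matrix(0, 8, 8); gt[2:4, 2:4] <- 1
#' lossFn(matrix(0.5, 8, 8), gt, sampleMeta(massRatio(gt)))
#' @export
makeLoss <- function(name, pixelCfg = pixelLossConfig(),
                     regionCfg = regionLossConfig(), raspCfg = raspConfig(),
                     daspCfg = NULL, focalCfg = adaptiveFocalConfig(),
                     focalUpsilon = 0.5, groupingModel = NULL,
                     weightNet = NULL) {
  if (!name %in% registeredLosses())
    stop("unknown loss name: ", name, call. = FALSE)
  needsGrouping <- name %in% c("qr_asp", "vr_asp", "cr_asp", "sr_asp")
  if (needsGrouping && is.null(groupingModel))
    stop("loss '", name, "' requires a fitted grouping model", call. = FALSE)
  if (needsGrouping && name != "sr_asp") {
    wanted <- c(qr_asp = "quantile", vr_asp = "value", cr_asp = "cluster")[[name]]
    if (groupingModel@strategy != wanted)
      stop("loss '", name, "' expects a grouping model with strategy '",
           wanted, "', got '", groupingModel@strategy, "'", call. = FALSE)
  }
  if (name == "lr_asp" && is.null(weightNet))
    stop("loss 'lr_asp' requires a weight net", call. = FALSE)
  if (is.null(daspCfg))
    daspCfg <- daspConfig(pixel = pixelCfg, region = regionCfg)
  sampleP <- function(meta) {
    if (raspCfg@pMode == "continuous") return(.continuousP(groupingModel, meta@ratio))
    if (!is.na(meta@group)) meta@group else assignGroup(groupingModel, meta@ratio)
  }
  sampleGroupMeta <- function(meta) {
    if (!is.na(meta@group)) return(meta)
    sampleMeta(meta@ratio, meta@densityCategory,
               assignGroup(groupingModel, meta@ratio))
  }
  switch(name,
    bce = function(pred, gt, meta, gradient = FALSE)
      bceLoss(pred, gt, clamp = pixelCfg@probClamp, gradient = gradient),
    dice = function(pred, gt, meta, gradient = FALSE)
      diceLoss(pred, gt, epsilon = pixelCfg@diceEpsilon,
               dialect = pixelCfg@diceDialect, gradient = gradient),
    hybrid = function(pred, gt, meta, gradient = FALSE)
      hybridPixelLoss(pred, gt, pixelCfg, gradient = gradient),
    focal = function(pred, gt, meta, gradient = FALSE)
      focalLoss(pred, gt, upsilon = focalUpsilon, clamp = pixelCfg@probClamp,
                gradient = gradient),
    qr_asp = ,
    vr_asp = ,
    cr_asp = function(pred, gt, meta, gradient = FALSE)
      raspLoss(pred, gt, p = sampleP(meta), cfg = raspCfg, pixelCfg = pixelCfg,
               gradient = gradient),
    lr_asp = function(pred, gt, meta, gradient = FALSE)
      lraspLoss(pred, gt, weightNet, pixelCfg = pixelCfg, gradient = gradient),
    d_asp = function(pred, gt, meta, gradient = FALSE)
      daspLoss(pred, gt, meta@densityCategory, cfg = daspCfg,
               gradient = gradient),
    sr_asp = function(pred, gt, meta, gradient = FALSE)
      adaptiveFocalLoss(pred, gt, sampleGroupMeta(meta),
                        cfg = methods::initialize(focalCfg, mode = "ratio"),
                        gradient = gradient),
    sd_asp = function(pred, gt, meta, gradient = FALSE)
      adaptiveFocalLoss(pred, gt, meta,
                        cfg = methods::initialize(focalCfg, mode = "density"),
                        gradient = gradient))
}

#' Training configuration
#'
#' @slot lossName one of [registeredLosses()].
#' @slot epochs,batchSize integers; batch size defaults to 4.
#' @slot learningRate numeric; defaults to 1e-4 (Adam).
#' @slot modelDescriptor architecture name for [buildModel()].
#' @slot seed integer.
#' @export
setClass("TrainConfig",
  representation(lossName = "character", epochs = "integer",
                 batchSize = "integer", learningRate = "numeric",
                 modelDescriptor = "character", seed = "integer"),
  prototype(lossName = "hybrid", epochs = 5L, batchSize = 4L,
            learningRate = 1e-4, modelDescriptor = "unet3-16", seed = 1L))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!object@lossName %in% registeredLosses())
    msg <- c(msg, paste0("lossName must be one of: ",
                         paste(registeredLosses(), collapse = ", ")))
  if (object@epochs < 1L || object@batchSize < 1L)
    msg <- c(msg, "epochs and batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainConfig-class
#' @param lossName,epochs,batchSize,learningRate,modelDescriptor,seed see slots.
#' @return a `TrainConfig` object.
#' @export
trainConfig <- function(lossName = "hybrid", epochs = 5L, batchSize = 4L,
                        learningRate = 1e-4, modelDescriptor = "unet3-16",
                        seed = 1L) {
  new("TrainConfig", lossName = lossName, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      modelDescriptor = modelDescriptor, seed = as.integer(seed))
}

.sampleParts <- function(s) {
  if (is(s, "SyntheticSample"))
    list(image = s@image, mask = s@mask, meta = s@meta)
  else if (is.list(s) && all(c("image", "mask", "meta") %in% names(s))) s
  else stop("dataset elements must be SyntheticSample or list(image, mask, meta)",
            call. = FALSE)
}

#' Mean per-sample loss of a model over a set of samples
#'
#' @param model a [UNetModel-class].
#' @param samples list of samples (as in [trainModel()]).
#' @param lossFn closure from [makeLoss()].
#' @return mean loss over the samples.
#' @export
modelBatchLoss <- function(model, samples, lossFn) {
  vals <- vapply(samples, function(s) {
    sp <- .sampleParts(s)
    lossFn(predictMask(model, sp$image), sp$mask, sp$meta)
  }, 0)
  mean(vals)
}

#' Train the segmentation model
#'
#' Mini-batch training with Adam. The loss is evaluated per sample with that
#' sample's metadata (size group or density category) and averaged over the
#' batch; for `lr_asp` the weight-net parameters are trained jointly with
#' the segmentation model. Metadata requirements are checked before the
#' first epoch. When a validation set is supplied, the model with the best
#' validation DSC is returned.
#'
#' @param dataset list of [SyntheticSample-class] (or `list(image, mask,
#'   meta)`) training samples.
#' @param cfg a [TrainConfig-class].
#' @param valDataset optional validation samples.
#' @param groupingModel fitted [GroupingModel-class] (fit it on the training
#'   split only), required by the ratio-driven losses.
#' @param weightNet [LraspWeightNet-class] for `lr_asp`; built automatically
#'   when `NULL`.
#' @param ... further arguments to [makeLoss()] (configs, `focalUpsilon`).
#' @return list with elements `model` ([UNetModel-class]), `record`
#'   ([TrainRecord-class]) and, for `lr_asp`, `weightNet`.
#' @export
trainModel <- function(dataset, cfg, valDataset = NULL, groupingModel = NULL,
                       weightNet = NULL, ...) {
  stopifnot(is(cfg, "TrainConfig")); validObject(cfg)
  if (length(dataset) == 0L) stop("empty training dataset", call. = FALSE)
  parts <- lapply(dataset, .sampleParts)
  imgDim <- dim(parts[[1]]$image)
  if (cfg@lossName == "lr_asp" && is.null(weightNet))
    weightNet <- lraspWeightNet(imgDim, seed = cfg@seed)
  lossFn <- makeLoss(cfg@lossName, groupingModel = groupingModel,
                     weightNet = weightNet, ...)
  ## fail fast on metadata problems before any training step
  for (sp in parts) {
    if (!is(sp$meta, "SampleMeta")) stop("sample metadata missing", call. = FALSE)
    if (cfg@lossName %in% c("qr_asp", "vr_asp", "cr_asp", "sr_asp") &&
        is.na(sp$meta@group)) assignGroup(groupingModel, sp$meta@ratio)
  }
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(cfg@seed)
  model <- buildModel(cfg@modelDescriptor, seed = cfg@seed)
  params <- model@params
  adam <- .adamInit(params)
  netVec <- if (!is.null(weightNet)) .lraspParamVec(weightNet)
  netM <- if (!is.null(netVec)) numeric(length(netVec))
  netV <- netM
  useNet <- cfg@lossName == "lr_asp"
  n <- length(parts)
  t <- 0L
  history <- vector("list", cfg@epochs)
  bestDsc <- -Inf; bestParams <- params
  for (epoch in seq_len(cfg@epochs)) {
    idx <- sample.int(n)
    epochLoss <- 0
    nb <- 0L
    for (start in seq(1, n, by = cfg@batchSize)) {
      bidx <- idx[start:min(start + cfg@batchSize - 1L, n)]
      m <- length(bidx)
      acc <- NULL
      netAcc <- if (useNet) numeric(length(netVec))
      batchLoss <- 0
      model@params <- params
      for (i in bidx) {
        sp <- parts[[i]]
        fw <- .unetForward(model, sp$image, cache = TRUE)
        ls <- lossFn(fw$pred, sp$mask, sp$meta, gradient = TRUE)
        batchLoss <- batchLoss + ls$value / m
        g <- .unetBackward(model, fw$cache, ls$grad / m)
        if (is.null(acc)) acc <- g else
          for (nm in names(acc)) {
            acc[[nm]]$dW <- acc[[nm]]$dW + g[[nm]]$dW
            acc[[nm]]$db <- acc[[nm]]$db + g[[nm]]$db
          }
        if (useNet && !is.null(ls$paramGrad))
          netAcc <- netAcc + ls$paramGrad / m
      }
      t <- t + 1L
      upd <- .adamStep(params, acc, adam, cfg@learningRate, t)
      params <- upd$params; adam <- upd$state
      if (useNet) {
        netM <- 0.9 * netM + 0.1 * netAcc
        netV <- 0.999 * netV + 0.001 * netAcc^2
        netVec <- netVec - cfg@learningRate * (netM / (1 - 0.9^t)) /
          (sqrt(netV / (1 - 0.999^t)) + 1e-8)
        weightNet <- .lraspSetParams(weightNet, netVec)
        lossFn <- makeLoss(cfg@lossName, groupingModel = groupingModel,
                           weightNet = weightNet, ...)
      }
      epochLoss <- epochLoss + batchLoss
      nb <- nb + 1L
    }
    model@params <- params
    row <- data.frame(epoch = epoch, trainLoss = epochLoss / nb,
                      valDsc = NA_real_)
    if (!is.null(valDataset)) {
      valRep <- evaluateModel(model, valDataset)
      row$valDsc <- valRep@dsc
      if (valRep@dsc > bestDsc) { bestDsc <- valRep@dsc; bestParams <- params }
    }
    history[[epoch]] <- row
  }
  if (!is.null(valDataset)) model@params <- bestParams
  record <- new("TrainRecord", history = do.call(rbind, history),
                config = list(lossName = cfg@lossName, epochs = cfg@epochs,
                              batchSize = cfg@batchSize,
                              learningRate = cfg@learningRate,
                              modelDescriptor = cfg@modelDescriptor),
                seed = cfg@seed)
  out <- list(model = model, record = record)
  if (useNet) out$weightNet <- weightNet
  out
}

#' Evaluate a model on a dataset
#'
#' Runs inference on every sample and delegates to [evaluateDataset()].
#'
#' @param model a [UNetModel-class].
#' @param dataset list of samples with ground-truth masks.
#' @param threshold binarization threshold.
#' @param aggregation `"macro"` or `"micro"`.
#' @return a [MetricReport-class].
#' @export
evaluateModel <- function(model, dataset, threshold = 0.5,
                          aggregation = "macro") {
  if (length(dataset) == 0L) stop("empty dataset", call. = FALSE)
  parts <- lapply(dataset, .sampleParts)
  preds <- lapply(parts, function(sp) predictMask(model, sp$image))
  gts <- lapply(parts, function(sp) sp$mask)
  evaluateDataset(preds, gts, threshold = threshold, aggregation = aggregation)
}

#' k-fold cross-validation splits
#'
#' @param n number of samples.
#' @param k number of folds (default 5).
#' @param seed integer.
#' @return list of `k` lists with integer vectors `train` and `test`.
#' @export
cvFolds <- function(n, k = 5L, seed = 1L) {
  if (k < 2L || k > n) stop("k must lie in [2, n]", call. = FALSE)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}
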