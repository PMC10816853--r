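# Desk-scale exercises of the model and training loop. The full-scale
# descent-and-accuracy checks over every registered loss live in
# test-acceptance.R; here the wiring is verified on small problems.

smallData <- function(n, seed = 1, size = 32L) {
  generateDataset(phantomSpec(imageSize = c(size, size), seed = seed), n)
}

test_that("model forward has the contracted shape, range and determinism", {
  m1 <- buildModel(seed = 4)
  m2 <- buildModel(seed = 4)
  expect_identical(m1@params, m2@params)
  x <- matrix(runif(64 * 64), 64, 64)
  p <- predictMask(m1, x)
  expect_identical(dim(p), c(64L, 64L))
  expect_true(all(p > 0 & p < 1))
  p0 <- predictMask(m1, matrix(0, 64, 64))
  expect_true(all(is.finite(p0)))
  expect_error(buildModel("unet9-128"), "descriptor")
  expect_error(predictMask(m1, matrix(0, 30, 30)), "multiples of 4")
})

test_that("model backward matches finite differences through a loss", {
  set.seed(51)
  ds <- smallData(1, seed = 51)
  img <- ds[[1]]@image; msk <- ds[[1]]@mask
  m <- buildModel(seed = 2)
  fw <- asploss:::.unetForward(m, img, cache = TRUE)
  ls <- hybridPixelLoss(fw$pred, msk, gradient = TRUE)
  bw <- asploss:::.unetBackward(m, fw$cache, ls$grad)
  f <- function(model) hybridPixelLoss(asploss:::.unetForward(model, img), msk)
  for (nm in c("enc1", "enc2", "bott", "dec2", "dec1", "head")) {
    i <- c(1, 2)
    m1 <- m; m2 <- m
    m1@params[[nm]]$W[i[1], i[2]] <- m1@params[[nm]]$W[i[1], i[2]] + 1e-5
    m2@params[[nm]]$W[i[1], i[2]] <- m2@params[[nm]]$W[i[1], i[2]] - 1e-5
    expect_equal(bw[[nm]]$dW[i[1], i[2]], (f(m1) - f(m2)) / 2e-5,
                 tolerance = 1e-4)
  }
})

test_that("every registered loss runs one training step with finite gradients", {
  ds <- smallData(2, seed = 52)
  ratios <- vapply(ds, function(s) s@meta@ratio, 0)
  gms <- list(quantile = fitGrouping(ratios, "quantile"),
              value = fitGrouping(ratios, "value"),
              cluster = fitGrouping(c(ratios, 0.2, 0.25), "cluster"))
  for (nm in registeredLosses()) {
    gm <- switch(nm, qr_asp = gms$quantile, vr_asp = gms$value,
                 cr_asp = gms$cluster, sr_asp = gms$quantile, NULL)
    cfg <- trainConfig(nm, epochs = 1L, batchSize = 2L, seed = 52)
    fit <- trainModel(ds, cfg, groupingModel = gm)
    hist <- trainingHistory(fit$record)
    expect_true(is.finite(hist$trainLoss[1]), info = nm)
    expect_true(all(vapply(fit$model@params,
                           function(l) all(is.finite(l$W)) && all(is.finite(l$b)),
                           TRUE)), info = nm)
  }
})

test_that("asp losses are wired per sample: batch loss recomposes and permutes", {
  ds <- smallData(4, seed = 53)
  ratios <- vapply(ds, function(s) s@meta@ratio, 0)
  gm <- fitGrouping(c(0.005, 0.01, 0.1, 0.2), "quantile")  # mixed groups
  lossFn <- makeLoss("qr_asp", groupingModel = gm)
  m <- buildModel(seed = 3)
  perSample <- vapply(ds, function(s)
    raspLoss(predictMask(m, s@image), s@mask,
             p = assignGroup(gm, s@meta@ratio)), 0)
  expect_equal(modelBatchLoss(m, ds, lossFn), mean(perSample), tolerance = 1e-6)
  ## both groups actually occur in the batch
  expect_true(length(unique(assignGroup(gm, ratios))) >= 1)
  ## permuting the batch leaves the loss unchanged (meta travels with sample)
  perm <- c(3, 1, 4, 2)
  expect_equal(modelBatchLoss(m, ds[perm], lossFn),
               modelBatchLoss(m, ds, lossFn), tolerance = 1e-12)
})

test_that("metadata and grouping requirements fail before training starts", {
  ds <- smallData(2, seed = 54)
  expect_error(trainModel(ds, trainConfig("cr_asp", epochs = 1L)),
               "grouping model")
  gmQ <- fitGrouping(c(0.01, 0.2), "quantile")
  expect_error(trainModel(ds, trainConfig("cr_asp", epochs = 1L),
                          groupingModel = gmQ), "cluster")
  expect_error(makeLoss("lr_asp"), "weight net")
  expect_error(makeLoss("nonsense"), "unknown loss")
})

test_that("evaluation is deterministic and fails on empty datasets", {
  ds <- smallData(3, seed = 55)
  m <- buildModel(seed = 5)
  r1 <- evaluateModel(m, ds)
  r2 <- evaluateModel(m, ds)
  expect_identical(aggregateMetrics(r1), aggregateMetrics(r2))
  expect_identical(nrow(perImageMetrics(r1)), 3L)
  expect_error(evaluateModel(m, list()), "empty")
})

test_that("cross-validation folds partition the sample set", {
  folds <- cvFolds(23, k = 5, seed = 2)
  expect_length(folds, 5)
  tests <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(tests, 1:23)
  for (f in folds) {
    expect_identical(sort(c(f$train, f$test)), 1:23)
    expect_length(intersect(f$train, f$test), 0)
  }
})
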