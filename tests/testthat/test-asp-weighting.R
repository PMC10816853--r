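test_that("mass ratio is the positive-pixel fraction", {
  expect_equal(massRatio(matrix(0, 8, 8)), 0)
  expect_equal(massRatio(matrix(1, 8, 8)), 1)
  m <- matrix(0, 256, 256); m[seq_len(655)] <- 1
  expect_equal(massRatio(m), 655 / 65536)
})

test_that("grouping fits reproduce median, mean and planted cluster centers", {
  expect_equal(groupingThreshold(fitGrouping(c(0.01, 0.02, 0.03, 0.04), "quantile")),
               0.025)
  expect_equal(groupingThreshold(fitGrouping(c(0.01, 0.02, 0.03, 0.06), "value")),
               0.03)
  set.seed(31)
  ratios <- pmin(pmax(c(rnorm(50, 0.01, 0.002), rnorm(50, 0.20, 0.02)), 0), 1)
  model <- fitGrouping(ratios, "cluster", k = 2, seed = 7)
  expect_lt(max(abs(groupingCenters(model) - c(0.01, 0.20))), 0.01)
  ## exact enumeration oracle agrees
  expect_equal(groupingCenters(model), oracleKmeans2(ratios), tolerance = 1e-12)
  ## every sample lands in its planted mode
  expect_identical(assignGroup(model, ratios), rep(c(0L, 1L), each = 50))
  expect_error(fitGrouping(numeric(0), "quantile"), "nonempty")
  expect_error(fitGrouping(c(0.1, 0.2), "cluster", k = 1), "k = 2")
})

test_that("group assignment uses the documented tie-breaks", {
  qm <- fitGrouping(c(0.01, 0.02, 0.03, 0.04), "quantile")
  expect_identical(assignGroup(qm, c(0.01, 0.04)), c(0L, 1L))
  expect_identical(assignGroup(qm, 0.025), 0L)  # exactly at the threshold
  cm <- new("GroupingModel", strategy = "cluster", centers = c(0.01, 0.20),
            fittedOn = 10L)
  expect_identical(assignGroup(cm, 0.105), 0L)  # equidistant -> small
  expect_identical(assignGroup(cm, c(0.02, 0.18)), c(0L, 1L))
})

test_that("quantile grouping splits non-constant training sets into two groups", {
  set.seed(32)
  for (rep in 1:5) {
    ratios <- runif(20, 0, 0.3)
    m <- fitGrouping(ratios, "quantile")
    g <- assignGroup(m, ratios)
    expect_true(all(c(0L, 1L) %in% g))
  }
})

test_that("ratio-adaptive loss applies the stated group weighting", {
  set.seed(33)
  pred <- randProbMask(8); gt <- randBinMask(8)
  d <- diceLoss(pred, gt); b <- bceLoss(pred, gt)
  cfg1 <- raspConfig(iDice = 1, iBce = 1)
  expect_equal(raspLoss(pred, gt, p = 1, cfg1), d + 2 * b, tolerance = 1e-12)
  expect_equal(raspLoss(pred, gt, p = 0, cfg1), 2 * d + b, tolerance = 1e-12)
  ## binary p makes the exponents inert (regression guard for the formula)
  for (g in c(0.25, 0.35, 1, 3)) {
    cfgG <- raspConfig(gammaDice = g, gammaBce = g)
    expect_equal(raspLoss(pred, gt, p = 0, cfgG), raspLoss(pred, gt, p = 0, cfg1),
                 tolerance = 1e-12)
    expect_equal(raspLoss(pred, gt, p = 1, cfgG), raspLoss(pred, gt, p = 1, cfg1),
                 tolerance = 1e-12)
  }
  ## dice coefficient exceeds the bce coefficient exactly for the small group
  for (iw in c(0.125, 0.25, 1)) {
    cfgI <- raspConfig(iDice = iw, iBce = iw)
    wD0 <- iw + 1; wB0 <- iw  # p = 0
    expect_gt(wD0, wB0)
    expect_equal(raspLoss(pred, gt, 0, cfgI), wD0 * d + wB0 * b, tolerance = 1e-12)
    expect_equal(raspLoss(pred, gt, 1, cfgI), iw * d + (iw + 1) * b, tolerance = 1e-12)
  }
  expect_error(raspLoss(pred, gt, p = 0.5, cfg1), "binary")
})

test_that("continuous-mode ratio weighting activates the exponents", {
  set.seed(34)
  pred <- randProbMask(8); gt <- randBinMask(8)
  cfg <- raspConfig(gammaDice = 0.25, gammaBce = 0.25, pMode = "continuous")
  d <- diceLoss(pred, gt); b <- bceLoss(pred, gt)
  w <- 1 + 0.5^0.25  # both weights at p = 0.5
  expect_equal(w, 1.8409, tolerance = 1e-4)
  expect_equal(raspLoss(pred, gt, 0.5, cfg), w * (d + b), tolerance = 1e-10)
})

test_that("learned weight net is deterministic, normalized and differentiable", {
  set.seed(35)
  gt <- randBinMask(16)
  net0 <- lraspWeightNet(c(16, 16), zeroOutput = TRUE)
  expect_equal(unname(lraspWeights(gt, net0)), c(1, 1), tolerance = 1e-12)
  net <- lraspWeightNet(c(16, 16), seed = 5)
  w1 <- lraspWeights(gt, net); w2 <- lraspWeights(gt, net)
  expect_identical(w1, w2)
  expect_true(all(w1 > 0))
  expect_equal(sum(w1), 2, tolerance = 1e-12)
  ## Jacobian w.r.t. parameters vs central differences
  wj <- lraspWeights(gt, net, gradient = TRUE)
  v <- asploss:::.lraspParamVec(net)
  idx <- sample(length(v), 6)
  for (out in 1:2) {
    fd <- vapply(idx, function(i) {
      v1 <- v; v2 <- v
      v1[i] <- v1[i] + 1e-6; v2[i] <- v2[i] - 1e-6
      (lraspWeights(gt, asploss:::.lraspSetParams(net, v1))[out] -
         lraspWeights(gt, asploss:::.lraspSetParams(net, v2))[out]) / 2e-6
    }, 0)
    expect_equal(wj$jacobian[out, idx], fd, tolerance = 1e-4)
  }
  ## softplus mode emits strictly positive unnormalized weights
  netS <- lraspWeightNet(c(16, 16), normalization = "softplus", seed = 5)
  expect_true(all(lraspWeights(gt, netS) > 0))
})

test_that("learned-weight loss recomposes from weights and constituents", {
  set.seed(36)
  pred <- randProbMask(16); gt <- randBinMask(16)
  net0 <- lraspWeightNet(c(16, 16), zeroOutput = TRUE)
  expect_equal(lraspLoss(pred, gt, net0),
               hybridPixelLoss(pred, gt, pixelLossConfig(1, 1)),
               tolerance = 1e-12)  # weights (1, 1) reduce to the static hybrid
  net <- lraspWeightNet(c(16, 16), seed = 9)
  w <- lraspWeights(gt, net)
  expect_equal(lraspLoss(pred, gt, net),
               w[["wDice"]] * diceLoss(pred, gt) + w[["wBce"]] * bceLoss(pred, gt),
               tolerance = 1e-12)
  ## parameter gradient agrees with central differences through the loss
  ls <- lraspLoss(pred, gt, net, gradient = TRUE)
  v <- asploss:::.lraspParamVec(net)
  idx <- sample(length(v), 5)
  fd <- vapply(idx, function(i) {
    v1 <- v; v2 <- v
    v1[i] <- v1[i] + 1e-6; v2[i] <- v2[i] - 1e-6
    (lraspLoss(pred, gt, asploss:::.lraspSetParams(net, v1)) -
       lraspLoss(pred, gt, asploss:::.lraspSetParams(net, v2))) / 2e-6
  }, 0)
  expect_equal(ls$paramGrad[idx], fd, tolerance = 1e-4)
})

test_that("density coefficient is the one-hot dot product with theta", {
  expect_equal(daspRegionCoefficient(3, c(0.5, 0.5, 0.85, 0.95)), 0.85)
  expect_equal(daspRegionCoefficient(1, c(0.25, 0.25, 0.85, 0.95)), 0.25)
  expect_equal(daspRegionCoefficient(2, c(0, 0, 0, 0)), 0)
  expect_error(daspRegionCoefficient(5, c(0.5, 0.5, 0.85, 0.95)), "1, 2, 3, 4")
})

test_that("density-adaptive loss recomposes and is monotone in theta", {
  set.seed(37)
  pred <- randProbMask(32); gt <- randBinMask(32)
  cfg <- daspConfig(theta = c(0.5, 0.5, 0.85, 0.95))
  ## theta = 0 reduces to the pixel hybrid
  cfg0 <- daspConfig(theta = c(0, 0, 0, 0), pixel = cfg@pixel, region = cfg@region)
  expect_equal(daspLoss(pred, gt, 2, cfg0),
               hybridPixelLoss(pred, gt, cfg@pixel), tolerance = 1e-12)
  hr <- hybridRegionLoss(pred, gt, cfg@region)
  hp <- hybridPixelLoss(pred, gt, cfg@pixel)
  expect_equal(daspLoss(pred, gt, 4, cfg), 0.95 * hr + hp, tolerance = 1e-10)
  ## with increasing theta entries and non-negative region loss, denser
  ## categories cannot decrease the loss
  if (hr >= 0) expect_gte(daspLoss(pred, gt, 4, cfg), daspLoss(pred, gt, 1, cfg))
  ## raising one theta entry raises the loss whenever the region term is >= 0
  cfgLo <- daspConfig(theta = c(0.1, 0.2, 0.3, 0.4))
  cfgHi <- daspConfig(theta = c(0.1, 0.2, 0.9, 0.4))
  if (hybridRegionLoss(pred, gt, cfgLo@region) >= 0)
    expect_gte(daspLoss(pred, gt, 3, cfgHi), daspLoss(pred, gt, 3, cfgLo))
})

test_that("adaptive focal lookups follow the reference tables", {
  presets <- lossPresets("inbreast")
  expect_equal(adaptiveUpsilon(sampleMeta(0.01, group = 0L), presets$focalRatio), 0.25)
  expect_equal(adaptiveUpsilon(sampleMeta(0.3, group = 1L), presets$focalRatio), 0.5)
  expect_equal(adaptiveUpsilon(sampleMeta(0.1, 4L), presets$focalDensity), 0.35)
  expect_equal(adaptiveUpsilon(sampleMeta(0.1, 1L), presets$focalDensity), 0.2)
  ## degenerate table: same upsilon either way
  flat <- adaptiveFocalConfig(upsilonByGroup = c(0.5, 0.5))
  expect_equal(adaptiveUpsilon(sampleMeta(0.1, group = 0L), flat),
               adaptiveUpsilon(sampleMeta(0.1, group = 1L), flat))
  expect_error(adaptiveUpsilon(sampleMeta(0.1), adaptiveFocalConfig()), "group")
})

test_that("adaptive focal loss recomposes and orders groups as expected", {
  set.seed(38)
  pred <- randProbMask(8, lo = 0.05, hi = 0.95); gt <- randBinMask(8)
  cfg <- adaptiveFocalConfig(upsilonByGroup = c(0.25, 0.5))
  small <- adaptiveFocalLoss(pred, gt, sampleMeta(0.01, group = 0L), cfg)
  large <- adaptiveFocalLoss(pred, gt, sampleMeta(0.2, group = 1L), cfg)
  expect_equal(small, focalLoss(pred, gt, 0.25, clamp = cfg@probClamp),
               tolerance = 1e-12)
  ## larger focusing parameter can only lower the loss on interior predictions
  expect_lte(large, small)
  dens <- adaptiveFocalConfig(mode = "density")
  expect_equal(adaptiveFocalLoss(pred, gt, sampleMeta(0.1, 3L), dens),
               focalLoss(pred, gt, 0.3), tolerance = 1e-12)
})

test_that("every adaptive loss gradient matches finite differences", {
  set.seed(39)
  pred <- randProbMask(16, lo = 0.05, hi = 0.95); gt <- randBinMask(16)
  idx <- sample(length(pred), 5)
  net <- lraspWeightNet(c(16, 16), seed = 3)
  cases <- list(
    rasp = list(f = function(x) raspLoss(x, gt, 1),
                g = raspLoss(pred, gt, 1, gradient = TRUE)$grad),
    lrasp = list(f = function(x) lraspLoss(x, gt, net),
                 g = lraspLoss(pred, gt, net, gradient = TRUE)$grad),
    dasp = list(f = function(x) daspLoss(x, gt, 3),
                g = daspLoss(pred, gt, 3, gradient = TRUE)$grad),
    afocal = list(
      f = function(x) adaptiveFocalLoss(x, gt, sampleMeta(0.1, group = 1L)),
      g = adaptiveFocalLoss(pred, gt, sampleMeta(0.1, group = 1L),
                            gradient = TRUE)$grad))
  for (cs in cases)
    expect_equal(cs$g[idx], fdGrad(cs$f, pred, idx), tolerance = 1e-3)
})
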