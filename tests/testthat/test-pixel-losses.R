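test_that("bce loss matches its closed forms and the scalar-loop oracle", {
  gt <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_lte(bceLoss(gt, gt, clamp = 1e-7), 2e-7)  # perfect prediction
  expect_equal(bceLoss(matrix(0.5, 2, 2), gt), log(2), tolerance = 1e-12)
  set.seed(11)
  pred <- randProbMask(4); g4 <- randBinMask(4)
  expect_equal(bceLoss(pred, g4), oracleBce(pred, g4), tolerance = 1e-10)
})

test_that("pixel losses reject malformed inputs", {
  expect_error(bceLoss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "differ")
  expect_error(bceLoss(matrix(1.5, 2, 2), matrix(0, 2, 2)), "\\[0, 1\\]")
  expect_error(diceLoss(matrix(0.5, 2, 2), matrix(0.5, 2, 2)), "0 or 1")
  expect_error(focalLoss(matrix(0.5, 2, 2), matrix(0, 2, 2), upsilon = -1),
               "non-negative")
  expect_error(diceLoss(matrix(0.5, 2, 2), matrix(0, 2, 2), epsilon = 0),
               "positive")
})

test_that("dice loss follows the printed quotient in both dialects", {
  z <- matrix(0, 5, 5)
  expect_equal(diceLoss(z, z, epsilon = 1), 0)  # empty-empty
  gt <- matrix(0, 5, 5); gt[1:2, 1:5] <- 1  # s = 10 positives
  expect_equal(diceLoss(gt, gt, epsilon = 1), 1 - 11 / 21, tolerance = 1e-12)
  expect_equal(diceLoss(gt, gt, epsilon = 1, dialect = "standard"),
               1 - 21 / 21, tolerance = 1e-12)
  ## disjoint supports, 10 positives each
  pr <- matrix(0, 5, 5); pr[4:5, 1:5] <- 1
  expect_equal(diceLoss(pr, gt, epsilon = 1), 1 - 1 / 21, tolerance = 1e-12)
  set.seed(12)
  pred <- randProbMask(8); g8 <- randBinMask(8)
  expect_equal(diceLoss(pred, g8), oracleDice(pred, g8), tolerance = 1e-10)
  expect_equal(diceLoss(pred, g8, dialect = "standard"),
               oracleDice(pred, g8, twice = TRUE), tolerance = 1e-10)
})

test_that("focal loss reduces to bce at upsilon 0 and matches hand values", {
  set.seed(13)
  pred <- randProbMask(6); gt <- randBinMask(6)
  expect_equal(focalLoss(pred, gt, upsilon = 0), bceLoss(pred, gt),
               tolerance = 1e-10)
  expect_lte(focalLoss(gt, gt, upsilon = 2), 1e-6)  # all pixels certain
  one <- matrix(1, 1, 1)
  expect_equal(focalLoss(matrix(0.5, 1, 1), one, upsilon = 2),
               0.25 * log(2), tolerance = 1e-12)
  expect_equal(focalLoss(pred, gt, upsilon = 2), oracleFocal(pred, gt, 2),
               tolerance = 1e-10)
})

test_that("focal loss is non-increasing in the focusing parameter", {
  set.seed(14)
  pred <- randProbMask(8); gt <- randBinMask(8)
  us <- c(0, 0.25, 0.5, 1, 2, 5)
  vals <- vapply(us, function(u) focalLoss(pred, gt, u), 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("hybrid pixel loss is the stated linear combination", {
  set.seed(15)
  pred <- randProbMask(8); gt <- randBinMask(8)
  d <- diceLoss(pred, gt); b <- bceLoss(pred, gt)
  expect_equal(hybridPixelLoss(pred, gt, pixelLossConfig(1, 1)), d + b,
               tolerance = 1e-12)
  expect_equal(hybridPixelLoss(pred, gt, pixelLossConfig(alpha = 0, beta = 3)),
               3 * b, tolerance = 1e-12)
  expect_equal(hybridPixelLoss(pred, gt, pixelLossConfig(alpha = 2, beta = 1)),
               2 * d + b, tolerance = 1e-12)
  ## linearity in (alpha, beta)
  for (ab in list(c(0.3, 1.7), c(5, 0.1))) {
    expect_equal(hybridPixelLoss(pred, gt, pixelLossConfig(ab[1], ab[2])),
                 ab[1] * d + ab[2] * b, tolerance = 1e-12)
  }
})

test_that("pixel losses are non-negative and dice stays in [0, 1]", {
  set.seed(16)
  for (rep in 1:10) {
    pred <- randProbMask(8, lo = 0, hi = 1)
    gt <- randBinMask(8, p = runif(1, 0.05, 0.9))
    expect_gte(bceLoss(pred, gt), 0)
    expect_gte(focalLoss(pred, gt, upsilon = runif(1, 0, 3)), 0)
    d <- diceLoss(pred, gt)
    expect_gte(d, 0); expect_lte(d, 1)
    ds <- diceLoss(pred, gt, dialect = "standard")
    expect_gte(ds, 0); expect_lte(ds, 1)
  }
})

test_that("analytic pixel-loss gradients match central finite differences", {
  set.seed(17)
  pred <- randProbMask(8, lo = 0.05, hi = 0.95); gt <- randBinMask(8)
  idx <- sample(length(pred), 5)
  cases <- list(
    bce = list(f = function(x) bceLoss(x, gt),
               g = bceLoss(pred, gt, gradient = TRUE)$grad),
    dice = list(f = function(x) diceLoss(x, gt),
                g = diceLoss(pred, gt, gradient = TRUE)$grad),
    focal = list(f = function(x) focalLoss(x, gt, 1.7),
                 g = focalLoss(pred, gt, 1.7, gradient = TRUE)$grad),
    hybrid = list(f = function(x) hybridPixelLoss(x, gt),
                  g = hybridPixelLoss(pred, gt, gradient = TRUE)$grad))
  for (cs in cases)
    expect_equal(cs$g[idx], fdGrad(cs$f, pred, idx), tolerance = 1e-6)
})
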