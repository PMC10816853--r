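test_that("generation is deterministic given the spec seed", {
  spec <- phantomSpec(imageSize = c(32, 32), seed = 5)
  d1 <- generateDataset(spec, 5)
  d2 <- generateDataset(spec, 5)
  expect_identical(lapply(d1, function(s) s@image),
                   lapply(d2, function(s) s@image))
  expect_identical(lapply(d1, function(s) s@mask),
                   lapply(d2, function(s) s@mask))
})

test_that("realized ratios are right-skewed and within tolerance of the draw", {
  spec <- phantomSpec(seed = 6)
  ds <- generateDataset(spec, 500)
  r <- vapply(ds, function(s) s@meta@ratio, 0)
  skew <- mean((r - mean(r))^3) / sd(r)^3
  expect_gt(skew, 0)
  expect_true(all(r > 0 & r <= 0.5))
  ## metadata ratio is recomputed from the mask, not the draw
  expect_equal(r, vapply(ds, function(s) massRatio(s@mask), 0))
  ## direct renders land within 15% of the requested ratio
  set.seed(7)
  for (target in c(0.002, 0.01, 0.05, 0.15, 0.3)) {
    s <- renderSample(target, 2, spec)
    expect_lte(abs(s@meta@ratio - target) / target, 0.15)
  }
})

test_that("density categories follow the configured mix", {
  spec <- phantomSpec(imageSize = c(32, 32),
                      densityMix = c(0.4, 0.3, 0.2, 0.1), seed = 8)
  ds <- generateDataset(spec, 400)
  counts <- tabulate(vapply(ds, function(s) s@meta@densityCategory, 0L), 4)
  expected <- 400 * c(0.4, 0.3, 0.2, 0.1)
  sigma <- sqrt(400 * c(0.4, 0.3, 0.2, 0.1) * (1 - c(0.4, 0.3, 0.2, 0.1)))
  expect_true(all(abs(counts - expected) <= 3 * sigma))
})

test_that("rendered masks are single connected components within [0,1] images", {
  spec <- phantomSpec(seed = 9)
  ds <- generateDataset(spec, 40)
  comps <- vapply(ds, function(s) max(EBImage::bwlabel(s@mask)), 0)
  expect_true(all(comps == 1))
  clipped <- vapply(ds, function(s) mean(s@image %in% c(0, 1)), 0)
  expect_true(all(clipped < 0.05))
  rng <- range(vapply(ds, function(s) range(s@image), numeric(2)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
})

test_that("a circle render hits the rasterized-disk area", {
  spec <- phantomSpec(imageSize = c(100, 100), massShape = "ellipse", seed = 10)
  set.seed(10)
  s <- renderSample(0.1, 1, spec, eccentricity = 1)
  expect_gte(sum(s@mask), 0.85 * 1000)
  expect_lte(sum(s@mask), 1.15 * 1000)
  ## feasibility floor: the smallest configured ratio still renders a mass
  spec64 <- phantomSpec(imageSize = c(64, 64), seed = 11)
  set.seed(11)
  tiny <- renderSample(0.002, 1, spec64)
  expect_gte(sum(tiny@mask), 1)
  expect_lte(abs(tiny@meta@ratio - 0.002) / 0.002, 0.15)
})

test_that("higher density means lower mass contrast against the background", {
  spec <- phantomSpec(seed = 12)
  contrast <- vapply(1:4, function(d) {
    set.seed(99)  # same geometry for every category
    s <- renderSample(0.05, d, spec)
    mean(s@image[s@mask == 1]) - mean(s@image[s@mask == 0])
  }, 0)
  expect_true(all(diff(contrast) < 0))
})

test_that("cluster grouping recovers the modes of a bimodal ratio spec", {
  spec <- phantomSpec(imageSize = c(64, 64), ratioFamily = "mixture",
                      ratioParams = c(0.01, 0.002, 0.20, 0.02, 0.5),
                      ratioRange = c(0.002, 0.35), seed = 13)
  ds <- generateDataset(spec, 60)
  r <- vapply(ds, function(s) s@meta@ratio, 0)
  model <- fitGrouping(r, "cluster")
  expect_equal(groupingCenters(model), c(0.01, 0.20), tolerance = 0.015)
  planted <- as.integer(r > 0.1)
  expect_identical(assignGroup(model, r), planted)
})

test_that("dataset round-trips through the on-disk format", {
  spec <- phantomSpec(imageSize = c(32, 32), seed = 14)
  ds <- generateDataset(spec, 3)
  dir <- tempfile()
  writeDataset(ds, dir, spec)
  expect_true(file.exists(file.path(dir, "spec.json")))
  back <- readDatasetDir(dir)
  expect_length(back, 3)
  expect_identical(back[[1]]$mask, ds[[1]]@mask)
  expect_equal(back[[2]]$meta@ratio, ds[[2]]@meta@ratio)
  ## 8-bit image quantization error stays below one gray level
  expect_lte(max(abs(back[[1]]$image - ds[[1]]@image)), 1 / 255)
})

test_that("infeasible specs are rejected", {
  spec <- phantomSpec(imageSize = c(16, 16), seed = 15)
  expect_error(renderSample(0.45, 1, spec), "too large")
  expect_error(generateDataset(spec, 0), ">= 1")
  tinySpec <- phantomSpec(imageSize = c(16, 16), ratioRange = c(0.001, 0.1),
                          seed = 16)
  expect_error(generateDataset(tinySpec, 1), "less than one pixel")
})
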