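## Synthetic mammogram-like phantoms: one elliptical (optionally
## boundary-perturbed) mass per image on a textured background. The target
## mass ratio is drawn from a right-skewed distribution and the ACR density
## category is realized operationally: higher categories get more background
## texture and less mass/background contrast, making segmentation harder.
## This is a test phantom, not a radiological model.

.blur2 <- function(x, sigma) {
  k <- max(3L, 2L * ceiling(3 * sigma) + 1L)
  t <- seq_len(k) - (k + 1) / 2
  w <- exp(-t^2 / (2 * sigma^2)); w <- w / sum(w)
  p <- (k - 1L) %/% 2L
  ri <- c(rev(seq_len(p) + 1L), seq_len(nrow(x)), nrow(x) - seq_len(p))
  ci <- c(rev(seq_len(p) + 1L), seq_len(ncol(x)), ncol(x) - seq_len(p))
  .corrCols(.corrRows(x[ri, ci, drop = FALSE], w), w)
}

.drawRatio <- function(spec) {
  rr <- spec@ratioRange
  for (i in 1:2000) {
    r <- if (spec@ratioFamily == "lognormal") {
      rlnorm(1, meanlog = spec@ratioParams[1], sdlog = spec@ratioParams[2])
    } else {
      p <- spec@ratioParams
      if (runif(1) < p[5]) rnorm(1, p[1], p[2]) else rnorm(1, p[3], p[4])
    }
    if (r >= rr[1] && r <= rr[2]) return(r)
  }
  stop("could not draw a target ratio inside ratioRange", call. = FALSE)
}

#' Render one phantom
#'
#' Solves ellipse semi-axes from `area = targetRatio * H * W` with random
#' eccentricity (axis ratio) in \[1, 3\] and rotation, perturbs the boundary
#' with smooth radial harmonics when `massShape = "perturbed-ellipse"`,
#' places the mass fully inside the image, and iteratively rescales the axes
#' so the rasterized pixel count matches the target area. Uses the current
#' RNG state; seed upstream for reproducibility.
#'
#' @param targetRatio target mass ratio inside `spec`'s `ratioRange`.
#' @param densityCategory integer 1--4.
#' @param spec a [PhantomSpec-class].
#' @param eccentricity optional fixed axis ratio (e.g. 1 for a circle);
#'   `NULL` draws it at random.
#' @return a [SyntheticSample-class]; its metadata ratio is recomputed from
#'   the rendered mask, not the draw.
#' @export
renderSample <- function(targetRatio, densityCategory, spec,
                         eccentricity = NULL) {
  stopifnot(is(spec, "PhantomSpec")); validObject(spec)
  H <- spec@imageSize[1]; W <- spec@imageSize[2]
  area <- targetRatio * H * W
  if (area < 1) stop("target ratio yields a mass of less than one pixel", call. = FALSE)
  perturbed <- spec@massShape == "perturbed-ellipse"
  ## limit the axis ratio so the minor semi-axis stays above ~1.2 px and the
  ## mass fits inside the image with a margin
  eccMax <- max(1, min(3, area / (pi * 1.44)))
  ecc <- if (is.null(eccentricity)) runif(1, 1, eccMax) else
    max(1, min(eccentricity, eccMax))
  rot <- runif(1, 0, pi)
  if (perturbed) {
    cm <- spec@perturbAmplitude * runif(3, 0.3, 1)
    ph <- runif(3, 0, 2 * pi)
  } else {
    cm <- numeric(3); ph <- numeric(3)
  }
  bulge <- 1 + sum(cm)
  maxA <- (min(H, W) / 2 - 1.5) / bulge
  if (sqrt(area / pi) > maxA)
    stop("target ratio too large for the image size", call. = FALSE)
  ecc <- min(ecc, maxA^2 * pi / area)
  a <- sqrt(area * ecc / pi); b <- sqrt(area / (pi * ecc))
  rmax <- a * bulge
  cy <- runif(1, 1 + rmax, H - rmax)
  cx <- runif(1, 1 + rmax, W - rmax)
  rowg <- matrix(seq_len(H), H, W)
  colg <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- rowg - cy; dx <- colg - cx
  u0 <- cos(rot) * dx + sin(rot) * dy
  v0 <- -sin(rot) * dx + cos(rot) * dy
  raster <- function(a, b) {
    u <- u0 / a; v <- v0 / b
    re <- sqrt(u^2 + v^2)
    th <- atan2(v, u)
    rho <- 1 + cm[1] * cos(2 * th + ph[1]) + cm[2] * cos(3 * th + ph[2]) +
      cm[3] * cos(4 * th + ph[3])
    (re <= rho) * 1
  }
  mask <- raster(a, b)
  best <- mask; bestErr <- abs(sum(mask) - area) / area
  for (it in 1:10) {
    cnt <- max(sum(mask), 1)
    if (abs(cnt - area) / area <= 0.02) break
    sc <- sqrt(area / cnt)
    sc <- min(sc, maxA / a)  # never grow past the fit limit
    a <- a * sc; b <- b * sc
    mask <- raster(a, b)
    err <- abs(sum(mask) - area) / area
    if (err < bestErr) { best <- mask; bestErr <- err }
  }
  mask <- best
  noise <- matrix(rnorm(H * W), H, W)
  noise <- .blur2(noise, spec@textureBlurSigma[densityCategory])
  noise <- noise / max(sd(noise), 1e-12) * spec@textureAmplitude[densityCategory]
  bump <- spec@contrastByDensity[densityCategory] * .blur2(mask, 0.7)
  img <- pmin(pmax(spec@backgroundLevel + noise + bump, 0), 1)
  new("SyntheticSample", image = img, mask = mask,
      meta = sampleMeta(massRatio(mask), densityCategory))
}

#' Generate a phantom dataset
#'
#' Deterministic given `spec@seed`: for each sample a density category is
#' drawn from `densityMix`, a target ratio from the ratio distribution
#' (truncated to `ratioRange`), and the phantom is rendered with
#' [renderSample()].
#'
#' @param spec a [PhantomSpec-class].
#' @param n number of samples, >= 1.
#' @return list of [SyntheticSample-class] objects.
#' @examples
#' ds <- generateDataset(phantomSpec(imageSize = c(32, 32), seed = 3), 4)
#' syntheticMetadata(ds)
#' @export
generateDataset <- function(spec, n) {
  stopifnot(is(spec, "PhantomSpec")); validObject(spec)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (spec@ratioRange[1] * prod(spec@imageSize) < 1)
    stop("ratioRange minimum yields a mass of less than one pixel for this image size",
         call. = FALSE)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(spec@seed)
  lapply(seq_len(n), function(i) {
    d <- sample.int(4L, 1L, prob = spec@densityMix)
    r <- .drawRatio(spec)
    renderSample(r, d, spec)
  })
}

#' Metadata table of a phantom dataset
#'
#' @param samples list of [SyntheticSample-class] objects.
#' @return data.frame with columns `sample_id`, `ratio`, `density_category`,
#'   `group` (NA until a grouping model is applied).
#' @export
syntheticMetadata <- function(samples) {
  data.frame(
    sample_id = seq_along(samples),
    ratio = vapply(samples, function(s) s@meta@ratio, 0),
    density_category = vapply(samples, function(s) s@meta@densityCategory, 0L),
    group = vapply(samples, function(s) s@meta@group, NA_integer_))
}

#' Write a phantom dataset to disk
#'
#' Images as 8-bit grayscale PNG, masks as 0/255 PNG, `metadata.csv`, and a
#' `spec.json` snapshot of the generation settings.
#'
#' @param samples list of [SyntheticSample-class] objects.
#' @param dir output directory (created if missing).
#' @param spec the [PhantomSpec-class] used, for the provenance snapshot.
#' @return invisibly, `dir`.
#' @export
writeDataset <- function(samples, dir, spec = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(samples)) {
    png::writePNG(samples[[i]]@image, file.path(dir, sprintf("image_%04d.png", i)))
    png::writePNG(samples[[i]]@mask, file.path(dir, sprintf("mask_%04d.png", i)))
  }
  write.csv(syntheticMetadata(samples), file.path(dir, "metadata.csv"),
            row.names = FALSE)
  if (!is.null(spec)) {
    sn <- list(image_size = spec@imageSize, ratio_family = spec@ratioFamily,
               ratio_params = spec@ratioParams, ratio_range = spec@ratioRange,
               density_mix = spec@densityMix,
               texture_amplitude = spec@textureAmplitude,
               texture_blur_sigma = spec@textureBlurSigma,
               contrast_by_density = spec@contrastByDensity,
               background_level = spec@backgroundLevel,
               mass_shape = spec@massShape,
               perturb_amplitude = spec@perturbAmplitude, seed = spec@seed)
    jsonlite::write_json(sn, file.path(dir, "spec.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}
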