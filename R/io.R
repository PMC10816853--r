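## File interfaces: binary masks as 8-bit grayscale PNG, probability masks
## as 32-bit float TIFF, sample metadata as CSV, loss settings as YAML/JSON.

#' Read and write binary masks as PNG
#'
#' Masks are stored as 8-bit grayscale PNG; on read, gray levels at or above
#' 128/255 become foreground.
#'
#' @param path file path.
#' @param mask numeric H x W matrix in \{0, 1\}.
#' @return `readBinMask` returns a 0/1 matrix; `writeBinMask` invisibly
#'   returns `path`.
#' @export
readBinMask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  (img >= 128 / 255) * 1
}

#' @rdname readBinMask
#' @export
writeBinMask <- function(mask, path) {
  checkBinMask(mask)
  storage.mode(mask) <- "double"
  png::writePNG(mask, path)
  invisible(path)
}

#' Read and write probability masks as 32-bit float TIFF
#'
#' @param path file path.
#' @param pred numeric H x W matrix in \[0, 1\].
#' @return `readProbMask` returns the probability matrix; `writeProbMask`
#'   invisibly returns `path`.
#' @export
readProbMask <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' @rdname readProbMask
#' @export
writeProbMask <- function(pred, path) {
  checkProbMask(pred)
  tiff::writeTIFF(pred, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects columns `sample_id`, `ratio`, `density_category` and optionally
#' `group`.
#'
#' @param path CSV file path.
#' @return data.frame; a missing `group` column is added as `NA`.
#' @export
readSampleMetadata <- function(path) {
  df <- read.csv(path)
  need <- c("sample_id", "ratio", "density_category")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$group)) df$group <- NA_integer_
  df
}

.pickArgs <- function(lst, map) {
  args <- list()
  for (key in names(map)) {
    if (!is.null(lst[[key]])) args[[map[[key]]]] <- lst[[key]]
  }
  args
}

#' Build loss configurations from a settings list or file
#'
#' The file (YAML or JSON, by extension) may contain sections `pixel`,
#' `region` (with subsections `ssim` and `rmi`), `rasp`, `dasp` and `focal`,
#' using snake_case keys (e.g. `dice_epsilon`, `i_dice`, `window_size`,
#' `upsilon_by_group`). Missing sections and keys fall back to the package
#' defaults.
#'
#' @param path YAML or JSON file path.
#' @param lst a list as produced by parsing such a file.
#' @return named list with elements `pixel`, `region`, `rasp`, `dasp`,
#'   `focal` (configuration objects).
#' @export
readLossConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  lossConfigFromList(lst)
}

#' @rdname readLossConfig
#' @export
lossConfigFromList <- function(lst) {
  pixel <- do.call(pixelLossConfig, .pickArgs(lst$pixel, list(
    alpha = "alpha", beta = "beta", dice_epsilon = "diceEpsilon",
    prob_clamp = "probClamp", dice_dialect = "diceDialect")))
  ssim <- do.call(ssimConfig, .pickArgs(lst$region$ssim, list(
    window_size = "windowSize", window_kind = "windowKind",
    gaussian_sigma = "gaussianSigma", dynamic_range = "dynamicRange",
    c1 = "c1", c2 = "c2")))
  rmi <- do.call(rmiConfig, .pickArgs(lst$region$rmi, list(
    region_size = "regionSize", downsample_factor = "downsampleFactor",
    pooling = "pooling", regularization_epsilon = "regularizationEpsilon")))
  regionArgs <- .pickArgs(lst$region, list(eta = "eta", tau = "tau"))
  region <- do.call(regionLossConfig,
                    c(regionArgs, list(ssim = ssim, rmi = rmi)))
  rasp <- do.call(raspConfig, .pickArgs(lst$rasp, list(
    i_dice = "iDice", i_bce = "iBce", gamma_dice = "gammaDice",
    gamma_bce = "gammaBce", p_mode = "pMode")))
  daspArgs <- .pickArgs(lst$dasp, list(theta = "theta"))
  if (!is.null(daspArgs$theta)) daspArgs$theta <- as.numeric(daspArgs$theta)
  dasp <- do.call(daspConfig, c(daspArgs, list(pixel = pixel, region = region)))
  focalArgs <- .pickArgs(lst$focal, list(
    mode = "mode", upsilon_by_group = "upsilonByGroup",
    upsilon_by_density = "upsilonByDensity", prob_clamp = "probClamp"))
  for (nm in c("upsilonByGroup", "upsilonByDensity"))
    if (!is.null(focalArgs[[nm]])) focalArgs[[nm]] <- as.numeric(focalArgs[[nm]])
  focal <- do.call(adaptiveFocalConfig, focalArgs)
  list(pixel = pixel, region = region, rasp = rasp, dasp = dasp, focal = focal)
}
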