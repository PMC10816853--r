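## Size grouping: mass ratios, the fitted small/large divider and its
## serialization. The cluster strategy is an exact 1-D 2-means (all split
## points of the sorted ratios are enumerated), so it has no seed
## sensitivity; the seed argument is kept for API symmetry.

#' Mass-to-image ratio of a binary mask
#'
#' @param gt numeric H x W matrix with entries in \{0, 1\}.
#' @return fraction of positive pixels, in \[0, 1\].
#' @examples
#' m <- matrix(0, 16, 16); m[1:4, 1:4] <- 1
#' massRatio(m)  # 16/256
#' @export
massRatio <- function(gt) {
  checkBinMask(gt)
  sum(gt) / length(gt)
}

## exact 1-D 2-means: minimize within-cluster sum of squares over all split
## points of the sorted sample
.exactKmeans2 <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n < 2L) stop("need at least 2 ratios for clustering", call. = FALSE)
  csum <- cumsum(xs); csq <- cumsum(xs^2)
  best <- Inf; bestm <- c(xs[1], mean(xs[-1]))
  for (m in 1:(n - 1)) {
    s1 <- csum[m]; q1 <- csq[m]
    s2 <- csum[n] - s1; q2 <- csq[n] - q1
    wss <- (q1 - s1^2 / m) + (q2 - s2^2 / (n - m))
    if (wss < best - 1e-15) {
      best <- wss
      bestm <- c(s1 / m, s2 / (n - m))
    }
  }
  sort(bestm)
}

#' Fit a small/large size-grouping model
#'
#' Divides training mass ratios into a small and a large group. The
#' `"quantile"` strategy thresholds at the median, `"value"` at the mean, and
#' `"cluster"` fits two 1-D k-means centers exactly (enumerating split points
#' of the sorted ratios) and assigns by nearest center.
#'
#' @param ratios numeric vector of training ratios, each in \[0, 1\].
#' @param strategy `"quantile"`, `"value"` or `"cluster"`.
#' @param k number of clusters; only `k = 2` is supported (binary grouping).
#' @param seed integer, unused by the exact fit; kept for API symmetry.
#' @return a [GroupingModel-class].
#' @examples
#' fitGrouping(c(0.01, 0.02, 0.03, 0.04), "quantile")  # threshold 0.025
#' fitGrouping(c(0.01, 0.02, 0.03, 0.06), "value")     # threshold 0.03
#' @export
fitGrouping <- function(ratios, strategy = c("quantile", "value", "cluster"),
                        k = 2L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (length(ratios) == 0L) stop("ratios must be nonempty", call. = FALSE)
  if (anyNA(ratios) || any(ratios < 0 | ratios > 1))
    stop("ratios must lie in [0, 1]", call. = FALSE)
  if (strategy == "cluster" && k != 2L)
    stop("only k = 2 clusters are supported for binary grouping", call. = FALSE)
  n <- as.integer(length(ratios))
  switch(strategy,
    quantile = new("GroupingModel", strategy = "quantile",
                   threshold = median(ratios), fittedOn = n),
    value = new("GroupingModel", strategy = "value",
                threshold = mean(ratios), fittedOn = n),
    cluster = {
      centers <- .exactKmeans2(ratios)
      if (!(centers[1] < centers[2]))
        stop("degenerate clustering: all ratios equal", call. = FALSE)
      new("GroupingModel", strategy = "cluster", centers = centers, fittedOn = n)
    })
}

#' Assign a ratio to the small (0) or large (1) group
#'
#' Quantile/value strategies: 0 iff `ratio <= threshold` (a ratio exactly at
#' the threshold goes to the small group). Cluster strategy: 0 iff the ratio
#' is nearer the small center, ties toward small.
#'
#' @param model a fitted [GroupingModel-class].
#' @param ratio numeric vector of ratios.
#' @return integer vector of 0/1 group indicators.
#' @examples
#' m <- fitGrouping(c(0.01, 0.02, 0.03, 0.04), "quantile")
#' assignGroup(m, c(0.01, 0.04))  # 0 1
#' @export
assignGroup <- function(model, ratio) {
  if (!is(model, "GroupingModel")) stop("model must be a GroupingModel", call. = FALSE)
  validObject(model)
  if (model@fittedOn < 1L) stop("grouping model is not fitted", call. = FALSE)
  if (anyNA(ratio)) stop("ratio must not contain NA", call. = FALSE)
  if (model@strategy %in% c("quantile", "value")) {
    as.integer(ratio > model@threshold)
  } else {
    ds <- abs(ratio - model@centers[1])
    dl <- abs(ratio - model@centers[2])
    as.integer(ds > dl)  # tie (ds == dl) -> small group
  }
}

#' Serialize / restore a grouping model as JSON
#'
#' @param model a [GroupingModel-class].
#' @param path file path.
#' @return `writeGroupingModel` invisibly returns `path`;
#'   `readGroupingModel` returns the restored [GroupingModel-class].
#' @export
writeGroupingModel <- function(model, path) {
  stopifnot(is(model, "GroupingModel"))
  obj <- list(strategy = model@strategy, fitted_on = model@fittedOn)
  if (length(model@threshold)) obj$threshold <- model@threshold
  if (length(model@centers)) obj$centers <- model@centers
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroupingModel
#' @export
readGroupingModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GroupingModel", strategy = obj$strategy,
      threshold = if (!is.null(obj$threshold)) as.numeric(obj$threshold) else numeric(0),
      centers = if (!is.null(obj$centers)) as.numeric(obj$centers) else numeric(0),
      fittedOn = as.integer(obj$fitted_on))
}
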