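## Region-level losses: structural-similarity loss and the covariance
## lower-bound surrogate of regional mutual information, plus their static
## hybrid. Windowed statistics use separable valid-mode correlation (no
## padding); adjoint operators give exact analytic gradients w.r.t. the
## prediction. Covariance and determinant work is done in double precision
## throughout, which matters on near-binary masks.

## ---- separable valid-mode filtering -------------------------------------

.window1d <- function(cfg) {
  k <- cfg@windowSize
  if (cfg@windowKind == "uniform") {
    w <- rep(1, k)
  } else {
    t <- seq_len(k) - (k + 1) / 2
    w <- exp(-t^2 / (2 * cfg@gaussianSigma^2))
  }
  w / sum(w)  # 2-D window = outer product, sums to 1
}

.corrRows <- function(x, w) {
  k <- length(w); Ho <- nrow(x) - k + 1
  out <- matrix(0, Ho, ncol(x))
  for (t in seq_len(k)) out <- out + w[t] * x[t:(t + Ho - 1), , drop = FALSE]
  out
}

.corrCols <- function(x, w) {
  k <- length(w); Wo <- ncol(x) - k + 1
  out <- matrix(0, nrow(x), Wo)
  for (t in seq_len(k)) out <- out + w[t] * x[, t:(t + Wo - 1), drop = FALSE]
  out
}

.filt2 <- function(x, w) .corrCols(.corrRows(x, w), w)

.adjRows <- function(g, w, H) {
  k <- length(w); Ho <- H - k + 1
  out <- matrix(0, H, ncol(g))
  for (t in seq_len(k))
    out[t:(t + Ho - 1), ] <- out[t:(t + Ho - 1), ] + w[t] * g
  out
}

.adjCols <- function(g, w, W) {
  k <- length(w); Wo <- W - k + 1
  out <- matrix(0, nrow(g), W)
  for (t in seq_len(k))
    out[, t:(t + Wo - 1)] <- out[, t:(t + Wo - 1)] + w[t] * g
  out
}

## adjoint of .filt2: scatter window-position gradients back onto pixels
.adjFilt2 <- function(g, w, H, W) .adjRows(.adjCols(g, w, W), w, H)

## ---- SSIM loss ----------------------------------------------------------

#' Structural-similarity loss
#'
#' Mean over valid window positions of `1 - SSIM`, where SSIM compares
#' windowed means, variances and covariance of the two masks with the usual
#' stabilization constants. SSIM lies in \[-1, 1\], so the loss lies in
#' \[0, 2\]; it is 0 when the masks are identical and exceeds 1 when they are
#' anti-correlated. Symmetric in its two arguments.
#'
#' @param pred numeric H x W probability matrix.
#' @param gt numeric H x W matrix in \[0, 1\]; a binary mask is used as real
#'   0/1 values without smoothing.
#' @param cfg an [SsimConfig-class].
#' @param gradient if `TRUE`, also return the gradient w.r.t. `pred`.
#' @return scalar in \[0, 2\], or `list(value, grad)`.
#' @examples
#' gt <- matrix(0, 16, 16); gt[4:9, 5:12] <- 1
#' ssimLoss(gt, gt)  # 0: identical signals
#' @export
ssimLoss <- function(pred, gt, cfg = ssimConfig(), gradient = FALSE) {
  stopifnot(is(cfg, "SsimConfig")); validObject(cfg)
  checkProbMask(pred); checkProbMask(gt); checkSameShape(pred, gt)
  k <- cfg@windowSize
  if (min(dim(pred)) < k)
    stop("image smaller than the SSIM window", call. = FALSE)
  w <- .window1d(cfg)
  x <- pred; y <- gt
  a <- .filt2(x, w); b <- .filt2(y, w)
  v <- .filt2(x * x, w); vy <- .filt2(y * y, w); z <- .filt2(x * y, w)
  sx <- v - a^2; sy <- vy - b^2; cxy <- z - a * b
  A1 <- 2 * a * b + cfg@c1; A2 <- 2 * cxy + cfg@c2
  B1 <- a^2 + b^2 + cfg@c1; B2 <- sx + sy + cfg@c2
  s <- (A1 * A2) / (B1 * B2)
  value <- mean(1 - s)
  if (!gradient) return(value)
  m <- length(s)
  gs <- -1 / m  # dL/ds at every window position
  dsdA1 <- A2 / (B1 * B2); dsdA2 <- A1 / (B1 * B2)
  dsdB1 <- -s / B1; dsdB2 <- -s / B2
  ## A2 = 2(z - ab) + C2 and B2 = (v - a^2) + sy + C2, so dA2/dz = 2,
  ## dA2/da = -2b, dB2/dv = 1, dB2/da = -2a
  dsda <- 2 * b * dsdA1 + 2 * a * dsdB1 - 2 * a * dsdB2 - 2 * b * dsdA2
  H <- nrow(x); W <- ncol(x)
  grad <- .adjFilt2(gs * dsda, w, H, W) +
    2 * x * .adjFilt2(gs * dsdB2, w, H, W) +
    2 * y * .adjFilt2(gs * dsdA2, w, H, W)
  list(value = value, grad = grad)
}

## ---- pooling helpers ----------------------------------------------------

.poolAvg <- function(x, f) {
  H <- (nrow(x) %/% f) * f; W <- (ncol(x) %/% f) * f
  x <- x[seq_len(H), seq_len(W), drop = FALSE]
  out <- matrix(0, H %/% f, W %/% f)
  for (di in 0:(f - 1)) for (dj in 0:(f - 1))
    out <- out + x[seq(1 + di, H, by = f), seq(1 + dj, W, by = f), drop = FALSE]
  out / f^2
}

.poolMax <- function(x, f) {
  H <- (nrow(x) %/% f) * f; W <- (ncol(x) %/% f) * f
  xc <- x[seq_len(H), seq_len(W), drop = FALSE]
  best <- matrix(-Inf, H %/% f, W %/% f)
  arg <- matrix(0L, H %/% f, W %/% f)  # linear index into the cropped matrix
  ri <- seq(1, H, by = f); cj <- seq(1, W, by = f)
  for (di in 0:(f - 1)) for (dj in 0:(f - 1)) {
    blk <- xc[ri + di, cj + dj, drop = FALSE]
    lin <- outer(ri + di, (cj + dj - 1) * H, "+")
    upd <- blk > best
    best[upd] <- blk[upd]
    arg[upd] <- lin[upd]
  }
  list(y = best, arg = arg, H = H, W = W)
}

## ---- regional mutual information loss -----------------------------------

.extractPoints <- function(x, r) {
  Ho <- nrow(x) - r + 1; Wo <- ncol(x) - r + 1
  P <- matrix(0, r * r, Ho * Wo)
  row <- 1L
  for (dj in 0:(r - 1)) for (di in 0:(r - 1)) {
    P[row, ] <- as.vector(x[(1 + di):(di + Ho), (1 + dj):(dj + Wo)])
    row <- row + 1L
  }
  P
}

.scatterPoints <- function(G, r, H, W) {
  Ho <- H - r + 1; Wo <- W - r + 1
  out <- matrix(0, H, W)
  row <- 1L
  for (dj in 0:(r - 1)) for (di in 0:(r - 1)) {
    out[(1 + di):(di + Ho), (1 + dj):(dj + Wo)] <-
      out[(1 + di):(di + Ho), (1 + dj):(dj + Wo)] + matrix(G[row, ], Ho, Wo)
    row <- row + 1L
  }
  out
}

.logdet <- function(M) {
  d <- determinant(M, logarithm = TRUE)
  if (d$sign <= 0 || !is.finite(d$modulus))
    stop("singular covariance despite regularization; increase regularizationEpsilon",
         call. = FALSE)
  as.numeric(d$modulus)
}

#' Regional mutual-information loss
#'
#' Tractable surrogate of the mutual information between `regionSize^2`-
#' dimensional points built from neighborhoods of the ground truth and the
#' prediction. Under a Gaussian model the MI admits the lower bound
#' \deqn{I \ge \tfrac12[\log\det(\Sigma_Y + \epsilon I) -
#'   \log\det(\Sigma_{Y|\hat Y} + \epsilon I)]}
#' with the posterior covariance
#' \eqn{\Sigma_{Y|\hat Y} = \Sigma_Y - \Sigma_{Y\hat Y}(\Sigma_{\hat Y} +
#' \epsilon I)^{-1}\Sigma_{\hat Y Y}}. The loss is the negative bound
#' normalized per dimension: 0 when prediction and ground truth carry no
#' mutual information (and for constant masks, where only the regularizer
#' remains), increasingly negative as the prediction becomes informative.
#' The ridge \eqn{\epsilon} is scaled by the mean ground-truth variance (plus
#' a tiny absolute floor), so gradients w.r.t. the prediction do not flow
#' through it.
#'
#' @inheritParams ssimLoss
#' @param cfg an [RmiConfig-class].
#' @return scalar (<= 0 up to numerical regularization), or
#'   `list(value, grad)`.
#' @examples
#' set.seed(1)
#' gt <- matrix(rbinom(256, 1, 0.3), 16, 16)
#' rmiLoss(gt, gt) < rmiLoss(matrix(sample(gt), 16, 16), gt)
#' @export
rmiLoss <- function(pred, gt, cfg = rmiConfig(), gradient = FALSE) {
  stopifnot(is(cfg, "RmiConfig")); validObject(cfg)
  checkProbMask(pred); checkProbMask(gt); checkSameShape(pred, gt)
  r <- cfg@regionSize; f <- cfg@downsampleFactor
  H0 <- nrow(pred); W0 <- ncol(pred)
  pool <- if (f > 1L) cfg@pooling else "none"
  if (pool == "avg") {
    xp <- .poolAvg(pred, f); yp <- .poolAvg(gt, f)
  } else if (pool == "max") {
    mp <- .poolMax(pred, f); xp <- mp$y
    yp <- .poolMax(gt, f)$y
  } else {
    xp <- pred; yp <- gt
  }
  if (min(dim(xp)) < r)
    stop("image too small for the region size after downsampling", call. = FALSE)
  P <- .extractPoints(xp, r)
  Y <- .extractPoints(yp, r)
  d <- r * r; N <- ncol(P)
  Yc <- Y - rowMeans(Y)
  Pc <- P - rowMeans(P)
  Sy <- tcrossprod(Yc) / N
  Sp <- tcrossprod(Pc) / N
  A <- tcrossprod(Yc, Pc) / N
  eps <- cfg@regularizationEpsilon * mean(diag(Sy)) + 1e-8
  B <- Sp + diag(eps, d)
  Bi <- solve(B)
  M <- Sy - A %*% Bi %*% t(A)
  M <- (M + t(M)) / 2
  value <- (.logdet(M + diag(eps, d)) - .logdet(Sy + diag(eps, d))) / (2 * d)
  if (!gradient) return(value)
  G <- solve(M + diag(eps, d)) / (2 * d)
  G <- (G + t(G)) / 2
  dA <- -2 * G %*% A %*% Bi
  dB <- Bi %*% t(A) %*% G %*% A %*% Bi
  dP <- (t(dA) %*% Yc + 2 * dB %*% Pc) / N
  dP <- dP - rowMeans(dP)  # adjoint of column centering
  gpool <- .scatterPoints(dP, r, nrow(xp), ncol(xp))
  grad <- matrix(0, H0, W0)
  if (pool == "avg") {
    Hc <- (H0 %/% f) * f; Wc <- (W0 %/% f) * f
    grad[seq_len(Hc), seq_len(Wc)] <-
      gpool[rep(seq_len(nrow(gpool)), each = f), rep(seq_len(ncol(gpool)), each = f)] / f^2
  } else if (pool == "max") {
    Hc <- mp$H; Wc <- mp$W
    sub <- matrix(0, Hc, Wc)
    sub[mp$arg] <- gpool
    grad[seq_len(Hc), seq_len(Wc)] <- sub
  } else {
    grad <- gpool
  }
  list(value = value, grad = grad)
}

#' Static region-level hybrid loss
#'
#' `eta * RMI + tau * SSIM` with weights from a [RegionLossConfig-class].
#'
#' @inheritParams ssimLoss
#' @param cfg a [RegionLossConfig-class].
#' @return scalar, or `list(value, grad)`.
#' @export
hybridRegionLoss <- function(pred, gt, cfg = regionLossConfig(), gradient = FALSE) {
  stopifnot(is(cfg, "RegionLossConfig")); validObject(cfg)
  rm <- if (cfg@eta != 0) rmiLoss(pred, gt, cfg@rmi, gradient = gradient) else
    if (gradient) list(value = 0, grad = 0) else 0
  ss <- if (cfg@tau != 0) ssimLoss(pred, gt, cfg@ssim, gradient = gradient) else
    if (gradient) list(value = 0, grad = 0) else 0
  if (!gradient) return(cfg@eta * rm + cfg@tau * ss)
  list(value = cfg@eta * rm$value + cfg@tau * ss$value,
       grad = cfg@eta * rm$grad + cfg@tau * ss$grad)
}
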