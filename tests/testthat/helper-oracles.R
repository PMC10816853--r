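# Independent scalar-loop oracles. These deliberately avoid every vectorized
# code path of the package: plain double loops over pixels / window
# positions, so they can serve as ground truth for the loss implementations.

oracleBce <- function(pred, gt, clamp = 1e-7) {
  tot <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- min(max(pred[i, j], clamp), 1 - clamp)
    tot <- tot + if (gt[i, j] == 1) -log(p) else -log(1 - p)
  }
  tot / (nrow(pred) * ncol(pred))
}

oracleDice <- function(pred, gt, eps = 1, twice = FALSE) {
  num <- 0; sp <- 0; sg <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    num <- num + pred[i, j] * gt[i, j]
    sp <- sp + pred[i, j]; sg <- sg + gt[i, j]
  }
  k <- if (twice) 2 else 1
  1 - (k * num + eps) / (sp + sg + eps)
}

oracleFocal <- function(pred, gt, upsilon, clamp = 1e-7) {
  tot <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- min(max(pred[i, j], clamp), 1 - clamp)
    pt <- if (gt[i, j] == 1) p else 1 - p
    tot <- tot - (1 - pt)^upsilon * log(pt)
  }
  tot / (nrow(pred) * ncol(pred))
}

# mean over valid positions of 1 - SSIM with a uniform k x k window
oracleSsimUniform <- function(pred, gt, k, c1, c2) {
  H <- nrow(pred); W <- ncol(pred)
  tot <- 0; m <- 0
  for (i in 1:(H - k + 1)) for (j in 1:(W - k + 1)) {
    xs <- 0; ys <- 0; xx <- 0; yy <- 0; xy <- 0
    for (a in 0:(k - 1)) for (b in 0:(k - 1)) {
      xv <- pred[i + a, j + b]; yv <- gt[i + a, j + b]
      xs <- xs + xv; ys <- ys + yv
      xx <- xx + xv^2; yy <- yy + yv^2; xy <- xy + xv * yv
    }
    n <- k * k
    mx <- xs / n; my <- ys / n
    vx <- xx / n - mx^2; vy <- yy / n - my^2
    cxy <- xy / n - mx * my
    s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
    tot <- tot + (1 - s); m <- m + 1
  }
  tot / m
}

oracleConfusion <- function(predBin, gt) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
    if (predBin[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1
    if (predBin[i, j] == 0 && gt[i, j] == 0) tn <- tn + 1
    if (predBin[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1
    if (predBin[i, j] == 0 && gt[i, j] == 1) fn <- fn + 1
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# exact brute-force 1-D 2-means over all split points of the sorted sample
oracleKmeans2 <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf; centers <- NULL
  for (m in 1:(n - 1)) {
    c1 <- mean(xs[1:m]); c2 <- mean(xs[(m + 1):n])
    wss <- sum((xs[1:m] - c1)^2) + sum((xs[(m + 1):n] - c2)^2)
    if (wss < best) { best <- wss; centers <- c(c1, c2) }
  }
  sort(centers)
}

randProbMask <- function(n, m = n, lo = 0.02, hi = 0.98)
  matrix(runif(n * m, lo, hi), n, m)

randBinMask <- function(n, m = n, p = 0.4)
  matrix(as.numeric(rbinom(n * m, 1, p)), n, m)

# central finite-difference gradient at selected linear indices
fdGrad <- function(f, x, idx, h = 1e-5) {
  vapply(idx, function(i) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + h; x2[i] <- x2[i] - h
    (f(x1) - f(x2)) / (2 * h)
  }, 0)
}
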