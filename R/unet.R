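## Tiny encoder-decoder segmentation network with hand-derived
## backpropagation. Convolutions run through im2col + GEMM in compiled code
## (src/convops.cpp); pooling, upsampling and activations are vectorized R.
## Layout: 3 levels, 16 base channels, one 3x3 convolution per stage,
## nearest-neighbor upsampling with skip concatenation, sigmoid 1x1 head.

.reluF <- function(z) { z[z < 0] <- 0; z }

.poolMaxCube <- function(a) {
  r <- .poolMax2C(a)
  r$inDim <- dim(a)
  r
}

.unpoolMaxCube <- function(g, pool)
  .unpoolMax2C(g, pool$arg, pool$inDim[1], pool$inDim[2])

.upsample2 <- function(a) .upsample2C(a)

## adjoint of nearest-neighbor x2 upsampling: sum each 2x2 block
.downsum2 <- function(g) .downsum2C(g)

.convLayer <- function(cin, cout, k) {
  list(W = NULL, b = NULL, k = k, cin = cin, cout = cout)
}

#' Build the tiny segmentation model
#'
#' @param descriptor architecture name; only `"unet3-16"` (3 levels, 16 base
#'   channels, sigmoid output) is registered.
#' @param seed integer controlling weight initialization (He-scaled normal).
#' @return a [UNetModel-class].
#' @examples
#' m <- buildModel(seed = 1)
#' p <- predictMask(m, matrix(runif(64 * 64), 64, 64))
#' range(p)  # within (0, 1)
#' @export
buildModel <- function(descriptor = "unet3-16", seed = 1L) {
  if (!identical(descriptor, "unet3-16"))
    stop("unknown model descriptor: ", descriptor, call. = FALSE)
  ch <- c(16L, 32L, 64L)
  layers <- list(
    enc1 = .convLayer(1L, ch[1], 3L),
    enc2 = .convLayer(ch[1], ch[2], 3L),
    bott = .convLayer(ch[2], ch[3], 3L),
    dec2 = .convLayer(ch[3] + ch[2], ch[2], 3L),
    dec1 = .convLayer(ch[2] + ch[1], ch[1], 3L),
    head = .convLayer(ch[1], 1L, 1L))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    fanIn <- l$k^2 * l$cin
    layers[[nm]]$W <- matrix(rnorm(l$cout * fanIn, sd = sqrt(2 / fanIn)),
                             l$cout, fanIn)
    layers[[nm]]$b <- numeric(l$cout)
  }
  new("UNetModel", descriptor = descriptor, params = layers, channels = ch)
}

.conv <- function(x, l) .conv2dForward(x, l$W, l$b, l$k, (l$k - 1L) %/% 2L)

## convolution keeping the patch matrix and input dims for the backward pass
.convC <- function(x, l) {
  r <- .conv2dForwardCache(x, l$W, l$b, l$k, (l$k - 1L) %/% 2L)
  r$inDim <- dim(x)
  r
}

.convBwd <- function(cv, l, dz)
  .conv2dBackward(cv$cols, l$W, dz, cv$inDim[1], cv$inDim[2], cv$inDim[3],
                  l$k, (l$k - 1L) %/% 2L)

.unetForward <- function(model, image, cache = FALSE) {
  if (any(dim(image) %% 4L != 0L))
    stop("image height and width must be multiples of 4", call. = FALSE)
  ## z-score standardization of the input
  x <- (image - mean(image)) / max(sd(image), 1e-6)
  p <- model@params
  a0 <- array(x, c(dim(x), 1L))
  if (!cache) {
    a1 <- .reluF(.conv(a0, p$enc1))
    p1 <- .poolMaxCube(a1)
    a2 <- .reluF(.conv(p1$y, p$enc2))
    p2 <- .poolMaxCube(a2)
    a3 <- .reluF(.conv(p2$y, p$bott))
    c2 <- array(c(.upsample2(a3), a2), c(dim(a2)[1:2], dim(a3)[3] + dim(a2)[3]))
    a4 <- .reluF(.conv(c2, p$dec2))
    c1 <- array(c(.upsample2(a4), a1), c(dim(a1)[1:2], dim(a4)[3] + dim(a1)[3]))
    a5 <- .reluF(.conv(c1, p$dec1))
    z6 <- .conv(a5, p$head)
    return(1 / (1 + exp(-z6[, , 1])))
  }
  v1 <- .convC(a0, p$enc1); z1 <- v1$y; a1 <- .reluF(z1)
  p1 <- .poolMaxCube(a1)
  v2 <- .convC(p1$y, p$enc2); z2 <- v2$y; a2 <- .reluF(z2)
  p2 <- .poolMaxCube(a2)
  v3 <- .convC(p2$y, p$bott); z3 <- v3$y; a3 <- .reluF(z3)
  u2 <- .upsample2(a3)
  c2 <- array(c(u2, a2), c(dim(a2)[1:2], dim(u2)[3] + dim(a2)[3]))
  v4 <- .convC(c2, p$dec2); z4 <- v4$y; a4 <- .reluF(z4)
  u1 <- .upsample2(a4)
  c1 <- array(c(u1, a1), c(dim(a1)[1:2], dim(u1)[3] + dim(a1)[3]))
  v5 <- .convC(c1, p$dec1); z5 <- v5$y; a5 <- .reluF(z5)
  v6 <- .convC(a5, p$head); z6 <- v6$y
  pred <- 1 / (1 + exp(-z6[, , 1]))
  list(pred = pred,
       cache = list(v1 = v1, z1 = z1, p1 = p1, v2 = v2, z2 = z2, p2 = p2,
                    v3 = v3, z3 = z3, v4 = v4, z4 = z4, v5 = v5, z5 = z5,
                    v6 = v6, pred = pred))
}

## returns per-layer parameter gradients for one sample
.unetBackward <- function(model, cache, dpred) {
  p <- model@params
  ch <- model@channels
  dz6 <- array(dpred * cache$pred * (1 - cache$pred), c(dim(dpred), 1L))
  g6 <- .convBwd(cache$v6, p$head, dz6)
  dz5 <- g6$dx * (cache$z5 > 0)
  g5 <- .convBwd(cache$v5, p$dec1, dz5)
  du1 <- g5$dx[, , seq_len(ch[2]), drop = FALSE]
  da1skip <- g5$dx[, , ch[2] + seq_len(ch[1]), drop = FALSE]
  da4 <- .downsum2(du1)
  dz4 <- da4 * (cache$z4 > 0)
  g4 <- .convBwd(cache$v4, p$dec2, dz4)
  du2 <- g4$dx[, , seq_len(ch[3]), drop = FALSE]
  da2skip <- g4$dx[, , ch[3] + seq_len(ch[2]), drop = FALSE]
  da3 <- .downsum2(du2)
  dz3 <- da3 * (cache$z3 > 0)
  g3 <- .convBwd(cache$v3, p$bott, dz3)
  da2 <- .unpoolMaxCube(g3$dx, cache$p2) + da2skip
  dz2 <- da2 * (cache$z2 > 0)
  g2 <- .convBwd(cache$v2, p$enc2, dz2)
  da1 <- .unpoolMaxCube(g2$dx, cache$p1) + da1skip
  dz1 <- da1 * (cache$z1 > 0)
  g1 <- .convBwd(cache$v1, p$enc1, dz1)
  list(enc1 = g1, enc2 = g2, bott = g3, dec2 = g4, dec1 = g5, head = g6)
}

#' Predict a probability mask
#'
#' @param model a [UNetModel-class].
#' @param image numeric H x W matrix (H, W multiples of 4).
#' @return numeric H x W probability matrix in (0, 1).
#' @export
predictMask <- function(model, image) {
  stopifnot(is(model, "UNetModel"))
  .unetForward(model, image, cache = FALSE)
}

## ---- Adam ---------------------------------------------------------------

.adamInit <- function(params) {
  lapply(params, function(l)
    list(mW = matrix(0, nrow(l$W), ncol(l$W)), vW = matrix(0, nrow(l$W), ncol(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b))))
}

.adamStep <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (nm in names(params)) {
    st <- state[[nm]]
    st$mW <- beta1 * st$mW + (1 - beta1) * grads[[nm]]$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * grads[[nm]]$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * grads[[nm]]$db
    st$vb <- beta2 * st$vb + (1 - beta2) * grads[[nm]]$db^2
    params[[nm]]$W <- params[[nm]]$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
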