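#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Patch matrix in column-major-friendly layout: one row per output position
// (column-major over the Ho x Wo grid), one column per (di, dj, c) patch
// offset, ordered di + k*dj + k*k*c. A weight matrix of shape
// (Cout x k*k*Cin) then gives y = cols * W.t().
static mat im2col_pad(const cube& x, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  mat out(Ho * Wo, k * k * C);
  mat xp(H + 2 * pad, W + 2 * pad, fill::zeros);
  for (int c = 0; c < C; ++c) {
    xp.zeros();
    xp.submat(pad, pad, pad + H - 1, pad + W - 1) = x.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        out.col(col) = vectorise(xp.submat(di, dj, di + Ho - 1, dj + Wo - 1));
      }
    }
  }
  return out;
}

// adjoint: scatter-add patch columns back onto the image grid
static cube col2im_pad(const mat& cols, const int H, const int W, const int C,
                       const int k, const int pad) {
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  cube dx(H, W, C, fill::zeros);
  mat xp(H + 2 * pad, W + 2 * pad);
  for (int c = 0; c < C; ++c) {
    xp.zeros();
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        xp.submat(di, dj, di + Ho - 1, dj + Wo - 1) +=
          reshape(cols.col(col), Ho, Wo);
      }
    }
    dx.slice(c) = xp.submat(pad, pad, pad + H - 1, pad + W - 1);
  }
  return dx;
}

static cube mat2cube(const mat& y, const int Ho, const int Wo) {
  const int Cout = y.n_cols;
  cube out(Ho, Wo, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export(name = ".conv2dForward")]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& Wm,
                          const arma::vec& b, const int k, const int pad) {
  const int Ho = x.n_rows + 2 * pad - k + 1, Wo = x.n_cols + 2 * pad - k + 1;
  mat cols = im2col_pad(x, k, pad);
  mat y = cols * Wm.t();
  y.each_row() += b.t();
  return mat2cube(y, Ho, Wo);
}

// [[Rcpp::export(name = ".conv2dForwardCache")]]
Rcpp::List conv2d_forward_cache(const arma::cube& x, const arma::mat& Wm,
                                const arma::vec& b, const int k, const int pad) {
  const int Ho = x.n_rows + 2 * pad - k + 1, Wo = x.n_cols + 2 * pad - k + 1;
  mat cols = im2col_pad(x, k, pad);
  mat y = cols * Wm.t();
  y.each_row() += b.t();
  return Rcpp::List::create(Rcpp::Named("y") = mat2cube(y, Ho, Wo),
                            Rcpp::Named("cols") = cols);
}

// Backward from the cached patch matrix; inH/inW/inC describe the layer
// input whose gradient is needed.
// [[Rcpp::export(name = ".conv2dBackward")]]
Rcpp::List conv2d_backward(const arma::mat& cols, const arma::mat& Wm,
                           const arma::cube& dy, const int inH, const int inW,
                           const int inC, const int k, const int pad) {
  const int Cout = dy.n_slices, npos = dy.n_rows * dy.n_cols;
  mat dym(const_cast<double*>(dy.memptr()), npos, Cout, false, true);
  mat dW = dym.t() * cols;
  vec db = sum(dym, 0).t();
  mat dcols = dym * Wm;
  cube dx = col2im_pad(dcols, inH, inW, inC, k, pad);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling over an H x W x C cube; arg holds column-major linear
// indices into the input for gradient routing.
// [[Rcpp::export(name = ".poolMax2C")]]
Rcpp::List pool_max2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = H / 2, ow = W / 2;
  cube y(oh, ow, C);
  Rcpp::IntegerVector arg(oh * ow * C);
  int t = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double best = -arma::datum::inf; int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = (2 * i + di) + H * (2 * j + dj) + H * W * c; }
          }
        y(i, j, c) = best;
        arg[t++] = bi + 1;  // 1-based for R
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("arg") = arg);
}

// [[Rcpp::export(name = ".unpoolMax2C")]]
arma::cube unpool_max2(const arma::cube& g, const Rcpp::IntegerVector& arg,
                       const int H, const int W) {
  cube out(H, W, g.n_slices, fill::zeros);
  const double* gp = g.memptr();
  double* op = out.memptr();
  for (int t = 0; t < (int)g.n_elem; ++t) op[arg[t] - 1] += gp[t];
  return out;
}

// [[Rcpp::export(name = ".upsample2C")]]
arma::cube upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v; out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v; out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

// adjoint of nearest-neighbor x2 upsampling
// [[Rcpp::export(name = ".downsum2C")]]
arma::cube downsum2(const arma::cube& g) {
  const int H = g.n_rows / 2, W = g.n_cols / 2, C = g.n_slices;
  cube out(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j, c) = g(2 * i, 2 * j, c) + g(2 * i + 1, 2 * j, c) +
                       g(2 * i, 2 * j + 1, c) + g(2 * i + 1, 2 * j + 1, c);
  return out;
}
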