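// Low-level kernels for the fully-convolutional classifier.
// Convolutions use im2col + GEMM, in single precision by default (the
// standard deep-learning arithmetic; roughly doubles throughput on one
// core) with a double-precision path for exact gradient verification.
// All shapes are (H, W, C) column-major arrays as produced by R. Weight
// matrices are (k*k*c_in) x c_out with the row index running over
// (dy, dx, channel) in R's array order, i.e. the flattening of a
// (k, k, c_in, c_out) array.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col with output pixels as rows: cols(p, di + k*dj + k*k*c) holds
// input channel c at offset (di - pad, dj - pad) from output pixel p.
// Row-major-in-pixels keeps every fill and the GEMM operands contiguous.
template <typename eT>
static Mat<eT> im2col_same(const Cube<eT>& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  Mat<eT> cols((size_t)H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const Mat<eT>& xc = x.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        eT* col = cols.colptr(di + k * dj + k * k * c);
        // output pixel (i, j) reads input (i + di - pad, j + dj - pad)
        const int i0 = std::max(0, pad - di);
        const int i1 = std::min(H, H + pad - di);
        const int j0 = std::max(0, pad - dj);
        const int j1 = std::min(W, W + pad - dj);
        for (int j = j0; j < j1; ++j) {
          const eT* src = xc.colptr(j + dj - pad) + (i0 + di - pad);
          eT* dst = col + (size_t)j * H + i0;
          std::copy(src, src + (i1 - i0), dst);
        }
      }
    }
  }
  return cols;
}

template <typename eT>
static cube conv2d_fwd_impl(const cube& x, const mat& wmat, const vec& bias,
                            const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = wmat.n_cols;
  const Cube<eT> xf = conv_to<Cube<eT>>::from(x);
  const Mat<eT> wf = conv_to<Mat<eT>>::from(wmat);
  const Col<eT> bf = conv_to<Col<eT>>::from(bias);
  Mat<eT> out;
  if (k == 1) {
    // 1x1 convolution is a pure channel mix; skip im2col
    const Mat<eT> xm(const_cast<eT*>(xf.memptr()), (size_t)H * W,
                     xf.n_slices, false);
    out = xm * wf;                 // (HW x cout)
  } else {
    out = im2col_same<eT>(xf, k) * wf;
  }
  out.each_row() += bf.t();
  return conv_to<cube>::from(Cube<eT>(out.memptr(), H, W, cout));
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& wmat,
                          const arma::vec& bias, const int k,
                          const bool single = true) {
  return single ? conv2d_fwd_impl<float>(x, wmat, bias, k)
                : conv2d_fwd_impl<double>(x, wmat, bias, k);
}

template <typename eT>
static Rcpp::List conv2d_bwd_impl(const cube& x, const mat& wmat,
                                  const cube& dy, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  const int cout = dy.n_slices;
  const Cube<eT> xf = conv_to<Cube<eT>>::from(x);
  const Cube<eT> dyf = conv_to<Cube<eT>>::from(dy);
  const Mat<eT> wf = conv_to<Mat<eT>>::from(wmat);
  // a (H,W,C) cube is exactly an (HW x C) column-major matrix
  const Mat<eT> dym(const_cast<eT*>(dyf.memptr()), (size_t)H * W, cout,
                    false);
  if (k == 1) {
    const Mat<eT> xm(const_cast<eT*>(xf.memptr()), (size_t)H * W, C, false);
    Mat<eT> dw = xm.t() * dym;                // (C x cout)
    Col<eT> db = sum(dym, 0).t();
    Mat<eT> dxm = dym * wf.t();               // (HW x C)
    return Rcpp::List::create(
      Rcpp::Named("dx") = conv_to<cube>::from(Cube<eT>(dxm.memptr(), H, W, C)),
      Rcpp::Named("dw") = conv_to<mat>::from(dw),
      Rcpp::Named("db") = conv_to<vec>::from(db));
  }
  Mat<eT> cols = im2col_same<eT>(xf, k);
  Mat<eT> dw = cols.t() * dym;                // (k*k*C x cout)
  Col<eT> db = sum(dym, 0).t();
  Mat<eT> dcols = dym * wf.t();               // (HW x k*k*C)
  Cube<eT> dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    Mat<eT>& dxc = dx.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const eT* col = dcols.colptr(di + k * dj + k * k * c);
        const int i0 = std::max(0, pad - di);
        const int i1 = std::min(H, H + pad - di);
        const int j0 = std::max(0, pad - dj);
        const int j1 = std::min(W, W + pad - dj);
        for (int j = j0; j < j1; ++j) {
          eT* dst = dxc.colptr(j + dj - pad) + (i0 + di - pad);
          const eT* src = col + (size_t)j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = conv_to<cube>::from(dx),
                            Rcpp::Named("dw") = conv_to<mat>::from(dw),
                            Rcpp::Named("db") = conv_to<vec>::from(db));
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& wmat,
                          const arma::cube& dy, const int k,
                          const bool single = true) {
  return single ? conv2d_bwd_impl<float>(x, wmat, dy, k)
                : conv2d_bwd_impl<double>(x, wmat, dy, k);
}

// 2x2 max pooling, stride 2; trailing odd row/column dropped.
// idx holds the 1-based linear index (within the H x W input plane) of the
// argmax feeding each pooled value, for the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int r = 2 * i, cc = 2 * j;
        double best = xc(r, cc);
        int bi = r, bj = cc;
        if (xc(r + 1, cc) > best) { best = xc(r + 1, cc); bi = r + 1; }
        if (xc(r, cc + 1) > best) { best = xc(r, cc + 1); bi = r; bj = cc + 1; }
        if (xc(r + 1, cc + 1) > best) {
          best = xc(r + 1, cc + 1); bi = r + 1; bj = cc + 1;
        }
        y(i, j, c) = best;
        idx(i, j, c) = (size_t)bj * H + bi + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::ucube& idx, const arma::cube& dy,
                            const int H, const int W) {
  const int C = dy.n_slices, Ho = dy.n_rows, Wo = dy.n_cols;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dxc = dx.slice(c);
    const mat& dyc = dy.slice(c);
    const umat& ic = idx.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dxc(ic(i, j) - 1) += dyc(i, j);
  }
  return dx;
}

// Per-channel sum and sum of squares of one activation cube (accumulated
// over the batch in R to form batch-norm statistics).
// [[Rcpp::export]]
Rcpp::List cpp_bn_stats(const arma::cube& x) {
  const int C = x.n_slices;
  vec s(C), s2(C);
  for (int c = 0; c < C; ++c) {
    s(c) = accu(x.slice(c));
    s2(c) = accu(square(x.slice(c)));
  }
  return Rcpp::List::create(Rcpp::Named("sum") = s,
                            Rcpp::Named("sumsq") = s2);
}

// Batch-norm affine transform + ReLU: relu(gamma * (x - mu) * inv_sd + beta)
// [[Rcpp::export]]
arma::cube cpp_bn_relu_fwd(const arma::cube& x, const arma::vec& gamma,
                           const arma::vec& beta, const arma::vec& mu,
                           const arma::vec& inv_sd) {
  cube y(x.n_rows, x.n_cols, x.n_slices);
  for (unsigned c = 0; c < x.n_slices; ++c) {
    const double a = gamma(c) * inv_sd(c);
    const double b = beta(c) - gamma(c) * inv_sd(c) * mu(c);
    y.slice(c) = clamp(a * x.slice(c) + b, 0.0, datum::inf);
  }
  return y;
}

// First backward pass of BN+ReLU: per-channel sums of the ReLU-masked
// gradient and of (masked gradient * xhat), over one cube.
// [[Rcpp::export]]
Rcpp::List cpp_bn_relu_bwd_sums(const arma::cube& x, const arma::cube& dy,
                                const arma::vec& gamma, const arma::vec& beta,
                                const arma::vec& mu, const arma::vec& inv_sd) {
  const int C = x.n_slices;
  vec sdy(C), sdyx(C);
  for (int c = 0; c < C; ++c) {
    const double a = gamma(c) * inv_sd(c);
    const double b = beta(c) - a * mu(c);
    const mat& xc = x.slice(c);
    const mat& dc = dy.slice(c);
    double s1 = 0, s2 = 0;
    const double* xp = xc.memptr();
    const double* dp = dc.memptr();
    for (size_t i = 0; i < xc.n_elem; ++i) {
      if (a * xp[i] + b > 0) {
        const double xh = (xp[i] - mu(c)) * inv_sd(c);
        s1 += dp[i];
        s2 += dp[i] * xh;
      }
    }
    sdy(c) = s1; sdyx(c) = s2;
  }
  return Rcpp::List::create(Rcpp::Named("sum_dy") = sdy,
                            Rcpp::Named("sum_dy_xhat") = sdyx);
}

// Second backward pass: gradient w.r.t. the convolution output.
// dx = gamma*inv_sd * (dy_masked - mean_dy - xhat * mean_dy_xhat)
// where the means are over the full batch (passed in from R).
// [[Rcpp::export]]
arma::cube cpp_bn_relu_bwd_dx(const arma::cube& x, const arma::cube& dy,
                              const arma::vec& gamma, const arma::vec& beta,
                              const arma::vec& mu, const arma::vec& inv_sd,
                              const arma::vec& mean_dy,
                              const arma::vec& mean_dy_xhat) {
  cube dx(x.n_rows, x.n_cols, x.n_slices);
  for (unsigned c = 0; c < x.n_slices; ++c) {
    const double a = gamma(c) * inv_sd(c);
    const double b = beta(c) - a * mu(c);
    const mat& xc = x.slice(c);
    const mat& dc = dy.slice(c);
    mat& oc = dx.slice(c);
    const double* xp = xc.memptr();
    const double* dp = dc.memptr();
    double* op = oc.memptr();
    for (size_t i = 0; i < xc.n_elem; ++i) {
      const double g = (a * xp[i] + b > 0) ? dp[i] : 0.0;
      const double xh = (xp[i] - mu(c)) * inv_sd(c);
      op[i] = a * (g - mean_dy(c) - xh * mean_dy_xhat(c));
    }
  }
  return dx;
}
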