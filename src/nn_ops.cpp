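// Minimal convolution kernels backing the reverse-mode tape in R/tape.R.
// Array layouts follow R column-major conventions:
//   images  (H, W, C, N)           h fastest
//   volumes (D1, D2, D3, C, N)
//   conv weights   (kh, kw, Cin, Cout)
//   tconv weights  (kh, kw, Cout, Cin)
// The im2col buffer is L x K (L = output pixels, K = kh*kw*C) so that both
// the patch gather and the GEMMs run over contiguous memory:
//   forward  y (L x Cout) = col (L x K) * W (K x Cout)
//   dW (K x Cout) += col' * dy;   dcol (L x K) = dy * W'
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc_arr(std::initializer_list<int> dims) {
  IntegerVector d(dims);
  double prod = 1; for (int v : dims) prod *= v;
  NumericVector x((R_xlen_t)prod);
  x.attr("dim") = d;
  return x;
}

static IntegerVector alloc_iarr(std::initializer_list<int> dims) {
  IntegerVector d(dims);
  double prod = 1; for (int v : dims) prod *= v;
  IntegerVector x((R_xlen_t)prod);
  x.attr("dim") = d;
  return x;
}

static IntegerVector need_dim(const RObject& x, const char* who, int nd) {
  RObject d = x.attr("dim");
  if (d.isNULL()) stop("argument '%s' has no dim attribute", who);
  IntegerVector dv(d);
  if (dv.size() != nd) stop("argument '%s' must have %d dims, has %d", who, nd, (int)dv.size());
  return dv;
}

// col is L x K with L = Ho*Wo, K = kh*kw*C; column r = ki + kh*(kj + kw*c)
static void im2col2d(const double* x, int H, int W, int C,
                     int kh, int kw, int stride, int pad,
                     int Ho, int Wo, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* colr = col.colptr(ki + kh * (kj + kw * c));
        // valid ho range: 0 <= ho*stride - pad + ki < H
        const int ho_lo = std::max(0, (pad - ki + stride - 1) / stride);
        const int ho_hi = std::min(Ho - 1, (H - 1 + pad - ki) / stride);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          const double* xcol = xc + (size_t)w * H;
          double* dst = colr + (size_t)wo * Ho;
          if (stride == 1) {
            const double* src = xcol - pad + ki;
            for (int ho = ho_lo; ho <= ho_hi; ++ho) dst[ho] = src[ho];
          } else {
            for (int ho = ho_lo; ho <= ho_hi; ++ho)
              dst[ho] = xcol[ho * stride - pad + ki];
          }
        }
      }
    }
  }
}

static void col2im2d(const arma::mat& col, double* x, int H, int W, int C,
                     int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* colr = col.colptr(ki + kh * (kj + kw * c));
        const int ho_lo = std::max(0, (pad - ki + stride - 1) / stride);
        const int ho_hi = std::min(Ho - 1, (H - 1 + pad - ki) / stride);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          double* xcol = xc + (size_t)w * H;
          const double* src = colr + (size_t)wo * Ho;
          if (stride == 1) {
            double* dst = xcol - pad + ki;
            for (int ho = ho_lo; ho <= ho_hi; ++ho) dst[ho] += src[ho];
          } else {
            for (int ho = ho_lo; ho <= ho_hi; ++ho)
              xcol[ho * stride - pad + ki] += src[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = need_dim(x, "x", 4), wd = need_dim(w, "w", 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C, L = Ho * Wo;
  NumericVector y = alloc_arr({Ho, Wo, Cout, N});
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat col(L, K);
  for (int n = 0; n < N; ++n) {
    im2col2d(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat ym(y.begin() + (size_t)n * L * Cout, L, Cout, false, true);
    ym = col * Wm;
    ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad, bool need_dx) {
  IntegerVector xd = need_dim(x, "x", 4), wd = need_dim(w, "w", 4), yd = need_dim(dy, "dy", 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * C, L = Ho * Wo;
  NumericVector dx = alloc_arr({H, W, C, need_dx ? N : 0});
  NumericVector dw = alloc_arr({kh, kw, C, Cout});
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat col(L, K), dcol(L, K);
  for (int n = 0; n < N; ++n) {
    arma::mat dym(const_cast<double*>(dy.begin()) + (size_t)n * L * Cout, L, Cout, false, true);
    im2col2d(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    dWm += col.t() * dym;
    dbv += arma::sum(dym, 0);
    if (need_dx) {
      dcol = dym * Wm.t();
      col2im2d(dcol, dx.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution; weights (kh, kw, Cout, Cin), pad = 0.
// [[Rcpp::export]]
NumericVector cpp_tconv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                             int stride) {
  IntegerVector xd = need_dim(x, "x", 4), wd = need_dim(w, "w", 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[2], Cin = wd[3];
  if (Cin != C) stop("tconv2d: channel mismatch");
  const int Ho = (H - 1) * stride + kh;
  const int Wo = (W - 1) * stride + kw;
  const int K = kh * kw * Cout, L = H * W;
  NumericVector y = alloc_arr({Ho, Wo, Cout, N});
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cin, false, true);
  arma::mat col(L, K);
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * L * C, L, C, false, true);
    col = xm * Wm.t();
    col2im2d(col, y.begin() + (size_t)n * Ho * Wo * Cout, Ho, Wo, Cout,
             kh, kw, stride, 0, H, W);
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      double* yp = y.begin() + (size_t)n * Ho * Wo * Cout + (size_t)c * Ho * Wo;
      const double bc = b[c];
      for (int i = 0; i < Ho * Wo; ++i) yp[i] += bc;
    }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv2d_bw(NumericVector x, NumericVector w, NumericVector dy, int stride) {
  IntegerVector xd = need_dim(x, "x", 4), wd = need_dim(w, "w", 4), yd = need_dim(dy, "dy", 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[2];
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * Cout, L = H * W;
  NumericVector dx = alloc_arr({H, W, C, N});
  NumericVector dw = alloc_arr({kh, kw, Cout, C});
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), K, C, false, true);
  arma::mat dWm(dw.begin(), K, C, false, true);
  arma::mat dcol(L, K);
  for (int n = 0; n < N; ++n) {
    im2col2d(dy.begin() + (size_t)n * Ho * Wo * Cout, Ho, Wo, Cout,
             kh, kw, stride, 0, H, W, dcol);
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * L * C, L, C, false, true);
    dWm += dcol.t() * xm;
    arma::mat dxm(dx.begin() + (size_t)n * L * C, L, C, false, true);
    dxm = dcol * Wm;
    for (int c = 0; c < Cout; ++c) {
      const double* dyp = dy.begin() + (size_t)n * Ho * Wo * Cout + (size_t)c * Ho * Wo;
      double s = 0;
      for (int i = 0; i < Ho * Wo; ++i) s += dyp[i];
      db[c] += s;
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax indices.
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector xd = need_dim(x, "x", 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc_arr({Ho, Wo, C, N});
  IntegerVector idx = alloc_iarr({Ho, Wo, C, N});
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      const size_t obase = ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const size_t ii = base + (size_t)(2 * wo + dj) * H + (2 * ho + di);
              if (x[ii] > best) { best = x[ii]; bi = ii; }
            }
          const size_t o = obase + (size_t)wo * Ho + ho;
          y[o] = best;
          idx[o] = (int)(bi + 1);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector dy, IntegerVector idx, IntegerVector dimx) {
  NumericVector dx((R_xlen_t)dimx[0] * dimx[1] * dimx[2] * dimx[3]);
  dx.attr("dim") = dimx;
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// ---------------- 3D ----------------

// col is L x K with L = O1*O2*O3, K = k^3*C
static void im2col3d(const double* x, int D1, int D2, int D3, int C,
                     int k, int stride, int pad,
                     int O1, int O2, int O3, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * D1 * D2 * D3;
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1) {
          double* colr = col.colptr(k1 + k * (k2 + k * (k3 + k * c)));
          const int lo = std::max(0, (pad - k1 + stride - 1) / stride);
          const int hi = std::min(O1 - 1, (D1 - 1 + pad - k1) / stride);
          for (int o3 = 0; o3 < O3; ++o3) {
            const int d3 = o3 * stride - pad + k3;
            if (d3 < 0 || d3 >= D3) continue;
            for (int o2 = 0; o2 < O2; ++o2) {
              const int d2 = o2 * stride - pad + k2;
              if (d2 < 0 || d2 >= D2) continue;
              const double* xcol = xc + ((size_t)d3 * D2 + d2) * D1;
              double* dst = colr + ((size_t)o3 * O2 + o2) * O1;
              for (int o1 = lo; o1 <= hi; ++o1)
                dst[o1] = xcol[o1 * stride - pad + k1];
            }
          }
        }
  }
}

static void col2im3d(const arma::mat& col, double* x, int D1, int D2, int D3, int C,
                     int k, int stride, int pad, int O1, int O2, int O3) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * D1 * D2 * D3;
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1) {
          const double* colr = col.colptr(k1 + k * (k2 + k * (k3 + k * c)));
          const int lo = std::max(0, (pad - k1 + stride - 1) / stride);
          const int hi = std::min(O1 - 1, (D1 - 1 + pad - k1) / stride);
          for (int o3 = 0; o3 < O3; ++o3) {
            const int d3 = o3 * stride - pad + k3;
            if (d3 < 0 || d3 >= D3) continue;
            for (int o2 = 0; o2 < O2; ++o2) {
              const int d2 = o2 * stride - pad + k2;
              if (d2 < 0 || d2 >= D2) continue;
              double* xcol = xc + ((size_t)d3 * D2 + d2) * D1;
              const double* src = colr + ((size_t)o3 * O2 + o2) * O1;
              for (int o1 = lo; o1 <= hi; ++o1)
                xcol[o1 * stride - pad + k1] += src[o1];
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = need_dim(x, "x", 5), wd = need_dim(w, "w", 5);
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], C = xd[3], N = xd[4];
  const int k = wd[0], Cout = wd[4];
  const int O1 = (D1 + 2 * pad - k) / stride + 1;
  const int O2 = (D2 + 2 * pad - k) / stride + 1;
  const int O3 = (D3 + 2 * pad - k) / stride + 1;
  const int K = k * k * k * C;
  const size_t L = (size_t)O1 * O2 * O3;
  NumericVector y = alloc_arr({O1, O2, O3, Cout, N});
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat col(L, K);
  for (int n = 0; n < N; ++n) {
    im2col3d(x.begin() + (size_t)n * D1 * D2 * D3 * C, D1, D2, D3, C,
             k, stride, pad, O1, O2, O3, col);
    arma::mat ym(y.begin() + (size_t)n * L * Cout, L, Cout, false, true);
    ym = col * Wm;
    ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad, bool need_dx) {
  IntegerVector xd = need_dim(x, "x", 5), wd = need_dim(w, "w", 5), yd = need_dim(dy, "dy", 5);
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], C = xd[3], N = xd[4];
  const int k = wd[0], Cout = wd[4];
  const int O1 = yd[0], O2 = yd[1], O3 = yd[2];
  const int K = k * k * k * C;
  const size_t L = (size_t)O1 * O2 * O3;
  NumericVector dx = alloc_arr({D1, D2, D3, C, need_dx ? N : 0});
  NumericVector dw = alloc_arr({k, k, k, C, Cout});
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat col(L, K), dcol(L, K);
  for (int n = 0; n < N; ++n) {
    arma::mat dym(const_cast<double*>(dy.begin()) + (size_t)n * L * Cout, L, Cout, false, true);
    im2col3d(x.begin() + (size_t)n * D1 * D2 * D3 * C, D1, D2, D3, C,
             k, stride, pad, O1, O2, O3, col);
    dWm += col.t() * dym;
    dbv += arma::sum(dym, 0);
    if (need_dx) {
      dcol = dym * Wm.t();
      col2im3d(dcol, dx.begin() + (size_t)n * D1 * D2 * D3 * C, D1, D2, D3, C,
               k, stride, pad, O1, O2, O3);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2x2 max pooling, stride 2.
// [[Rcpp::export]]
List cpp_maxpool3_fw(NumericVector x) {
  IntegerVector xd = need_dim(x, "x", 5);
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], C = xd[3], N = xd[4];
  const int O1 = D1 / 2, O2 = D2 / 2, O3 = D3 / 2;
  NumericVector y = alloc_arr({O1, O2, O3, C, N});
  IntegerVector idx = alloc_iarr({O1, O2, O3, C, N});
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * D1 * D2 * D3;
      const size_t obase = ((size_t)n * C + c) * O1 * O2 * O3;
      for (int o3 = 0; o3 < O3; ++o3)
        for (int o2 = 0; o2 < O2; ++o2)
          for (int o1 = 0; o1 < O1; ++o1) {
            double best = -std::numeric_limits<double>::infinity();
            size_t bi = 0;
            for (int z = 0; z < 2; ++z)
              for (int j = 0; j < 2; ++j)
                for (int i = 0; i < 2; ++i) {
                  const size_t ii = base +
                    ((size_t)(2 * o3 + z) * D2 + (2 * o2 + j)) * D1 + (2 * o1 + i);
                  if (x[ii] > best) { best = x[ii]; bi = ii; }
                }
            const size_t o = obase + ((size_t)o3 * O2 + o2) * O1 + o1;
            y[o] = best;
            idx[o] = (int)(bi + 1);
          }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3_bw(NumericVector dy, IntegerVector idx, IntegerVector dimx) {
  double prodd = 1; for (int v : dimx) prodd *= v;
  NumericVector dx((R_xlen_t)prodd);
  dx.attr("dim") = dimx;
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// ReLU forward/backward kept in C++ to avoid R-level copies in the hot path.
// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector y = clone(x);
  for (R_xlen_t i = 0; i < y.size(); ++i) if (y[i] < 0) y[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector y, NumericVector dy) {
  NumericVector dx = clone(dy);
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (y[i] <= 0) dx[i] = 0;
  return dx;
}
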