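// Minimal convolutional kernels for the multimodal dissolution network.
// Layout convention follows R arrays (column-major): images are
// H x W x C x N, kernels kh x kw x C x F. Convolution is "valid",
// cross-correlation form (no kernel flip), as in mainstream DL frameworks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const arma::cube& x, int kh, int kw, arma::mat& out) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = H - kh + 1, W2 = W - kw + 1;
  out.set_size(H2 * W2, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * kj + kh * kw * c;
        double* dst = out.colptr(col);
        for (int j2 = 0; j2 < W2; ++j2) {
          const double* src = sl.colptr(j2 + kj) + ki;
          std::memcpy(dst + j2 * H2, src, H2 * sizeof(double));
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward_cpp")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int H2 = H - kh + 1, W2 = W - kw + 1;
  arma::mat wm(w.begin(), kh * kw * C, F, false);
  arma::vec bv(b.begin(), F, false);
  NumericVector out(H2 * W2 * F * N);
  out.attr("dim") = IntegerVector::create(H2, W2, F, N);
  arma::mat xcol;
  for (int n = 0; n < N; ++n) {
    arma::cube xc(x.begin() + (size_t)n * H * W * C, H, W, C, false);
    im2col(xc, kh, kw, xcol);
    arma::mat y = xcol * wm;           // (H2*W2) x F
    y.each_row() += bv.t();
    std::memcpy(out.begin() + (size_t)n * H2 * W2 * F, y.memptr(),
                (size_t)H2 * W2 * F * sizeof(double));
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward_cpp")]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int H2 = H - kh + 1, W2 = W - kw + 1;
  arma::mat wm(w.begin(), kh * kw * C, F, false);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat dwm(kh * kw * C, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  arma::mat xcol;
  for (int n = 0; n < N; ++n) {
    arma::cube xc(x.begin() + (size_t)n * H * W * C, H, W, C, false);
    arma::mat dym(dy.begin() + (size_t)n * H2 * W2 * F, H2 * W2, F, false);
    im2col(xc, kh, kw, xcol);
    dwm += xcol.t() * dym;
    db += arma::sum(dym, 0).t();
    arma::mat dxcol = dym * wm.t();    // (H2*W2) x (kh*kw*C)
    arma::cube dxc(dx.begin() + (size_t)n * H * W * C, H, W, C, false, true);
    for (int c = 0; c < C; ++c) {
      arma::mat& sl = dxc.slice(c);
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const int col = ki + kh * kj + kh * kw * c;
          const double* src = dxcol.colptr(col);
          for (int j2 = 0; j2 < W2; ++j2) {
            double* dst = sl.colptr(j2 + kj) + ki;
            const double* s = src + j2 * H2;
            for (int i2 = 0; i2 < H2; ++i2) dst[i2] += s[i2];
          }
        }
      }
    }
  }
  NumericVector dwv(dwm.begin(), dwm.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2, floor semantics; idx stores the linear offset of
// the argmax within each (slice, sample) plane for exact gradient routing.
// [[Rcpp::export(name = ".maxpool2_forward_cpp")]]
List maxpool2_forward_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int H2 = H / 2, W2 = W / 2;
  NumericVector out((size_t)H2 * W2 * C * N);
  IntegerVector idx((size_t)H2 * W2 * C * N);
  out.attr("dim") = IntegerVector::create(H2, W2, C, N);
  const double* px = x.begin();
  double* po = out.begin();
  int* pi = idx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* plane = px + cn * H * W;
    double* oplane = po + cn * H2 * W2;
    int* iplane = pi + cn * H2 * W2;
    for (int j2 = 0; j2 < W2; ++j2) {
      for (int i2 = 0; i2 < H2; ++i2) {
        int base = 2 * i2 + H * 2 * j2;
        int best = base;
        double bv = plane[base];
        const int cand[3] = {base + 1, base + H, base + H + 1};
        for (int k = 0; k < 3; ++k)
          if (plane[cand[k]] > bv) { bv = plane[cand[k]]; best = cand[k]; }
        oplane[i2 + H2 * j2] = bv;
        iplane[i2 + H2 * j2] = best;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward_cpp")]]
NumericVector maxpool2_backward_cpp(NumericVector dy, IntegerVector idx,
                                    IntegerVector dim_in) {
  const int H = dim_in[0], W = dim_in[1], C = dim_in[2], N = dim_in[3];
  const int H2 = H / 2, W2 = W / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = dim_in;
  const double* pdy = dy.begin();
  const int* pi = idx.begin();
  double* pdx = dx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    double* plane = pdx + cn * H * W;
    const double* dplane = pdy + cn * H2 * W2;
    const int* iplane = pi + cn * H2 * W2;
    for (int k = 0; k < H2 * W2; ++k) plane[iplane[k]] += dplane[k];
  }
  return dx;
}
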