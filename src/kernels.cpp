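// Low-level kernels: im2col/col2im convolution primitives used by the
// network layers, plus labelling utilities for mask extraction.
// Feature maps are R arrays [H, W, C] (column-major). Patch matrices are
// laid out [P, kh*kw*C] with P = outH*outW and column r = i + kh*(j + kw*c),
// so the inner spatial loop writes contiguously and the convolution is a
// single GEMM `cols %*% K` against the kernel reshaped to [kh*kw*Cin, Cout].
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int outH = (H + 2 * pad - kh) / stride + 1;
  const int outW = (W + 2 * pad - kw) / stride + 1;
  const int P = outH * outW;
  arma::mat cols(P, kh * kw * C, arma::fill::zeros);
  const double* xp = x.memptr();
  double* cp = cols.memptr();
  for (int c = 0; c < C; ++c) {
    const double* xs = xp + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        double* col = cp + (size_t)(i + kh * (j + kw * c)) * P;
        for (int ow = 0; ow < outW; ++ow) {
          const int wx = ow * stride + j - pad;
          if (wx < 0 || wx >= W) continue;
          const double* src = xs + (size_t)wx * H;
          double* dst = col + (size_t)ow * outH;
          int oh0 = 0, oh1 = outH;                    // hx = oh*stride + i - pad in [0, H)
          while (oh0 < oh1 && oh0 * stride + i - pad < 0) ++oh0;
          while (oh1 > oh0 && (oh1 - 1) * stride + i - pad >= H) --oh1;
          if (stride == 1) {
            const int off = i - pad;
            for (int oh = oh0; oh < oh1; ++oh) dst[oh] = src[oh + off];
          } else {
            for (int oh = oh0; oh < oh1; ++oh) dst[oh] = src[oh * stride + i - pad];
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col_cpp: scatter-add patch rows back onto an [H, W, C] grid.
// [[Rcpp::export]]
arma::cube col2im_cpp(const arma::mat& cols, int H, int W, int C,
                      int kh, int kw, int stride, int pad) {
  const int outH = (H + 2 * pad - kh) / stride + 1;
  const int outW = (W + 2 * pad - kw) / stride + 1;
  const int P = outH * outW;
  arma::cube x(H, W, C, arma::fill::zeros);
  const double* cp = cols.memptr();
  double* xp = x.memptr();
  for (int c = 0; c < C; ++c) {
    double* xs = xp + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const double* col = cp + (size_t)(i + kh * (j + kw * c)) * P;
        for (int ow = 0; ow < outW; ++ow) {
          const int wx = ow * stride + j - pad;
          if (wx < 0 || wx >= W) continue;
          double* dst = xs + (size_t)wx * H;
          const double* src = col + (size_t)ow * outH;
          int oh0 = 0, oh1 = outH;
          while (oh0 < oh1 && oh0 * stride + i - pad < 0) ++oh0;
          while (oh1 > oh0 && (oh1 - 1) * stride + i - pad >= H) --oh1;
          if (stride == 1) {
            const int off = i - pad;
            for (int oh = oh0; oh < oh1; ++oh) dst[oh + off] += src[oh];
          } else {
            for (int oh = oh0; oh < oh1; ++oh) dst[oh * stride + i - pad] += src[oh];
          }
        }
      }
    }
  }
  return x;
}

// 6-connected component labelling of a binary 3-D grid (BFS).
// Returns integer labels 0 (background), 1..n; label order is scan order.
// [[Rcpp::export]]
IntegerVector label_components_3d(const LogicalVector& mask, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      const R_xlen_t v = queue.back();
      queue.pop_back();
      const int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / sz);
      const R_xlen_t nb[6] = {v - sx, v + sx, v - sy, v + sy, v - sz, v + sz};
      const bool ok[6] = {x > 0, x < nx - 1, y > 0, y < ny - 1, z > 0, z < nz - 1};
      for (int k = 0; k < 6; ++k) {
        if (ok[k] && mask[nb[k]] && lab[nb[k]] == 0) {
          lab[nb[k]] = next;
          queue.push_back(nb[k]);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Fill interior cavities of a 2-D binary mask: background connected to the
// slice border (4-connectivity) stays background, everything else becomes 1.
// [[Rcpp::export]]
LogicalMatrix fill_holes_2d(const LogicalMatrix& m) {
  const int H = m.nrow(), W = m.ncol();
  std::vector<char> outside((size_t)H * W, 0);
  std::vector<int> queue;
  auto push = [&](int i, int j) {
    const int v = i + H * j;
    if (!m(i, j) && !outside[v]) { outside[v] = 1; queue.push_back(v); }
  };
  for (int i = 0; i < H; ++i) { push(i, 0); push(i, W - 1); }
  for (int j = 0; j < W; ++j) { push(0, j); push(H - 1, j); }
  while (!queue.empty()) {
    const int v = queue.back();
    queue.pop_back();
    const int i = v % H, j = v / H;
    if (i > 0) push(i - 1, j);
    if (i < H - 1) push(i + 1, j);
    if (j > 0) push(i, j - 1);
    if (j < W - 1) push(i, j + 1);
  }
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = !outside[(size_t)i + H * j];
  return out;
}

// ---- fused layer kernels ----------------------------------------------------
// Hot-path layers avoid Rcpp copy overhead: R arrays are wrapped as
// Armadillo views (no copy) and outputs are written straight into
// pre-allocated R vectors. The backward pass recomputes im2col from the
// cached layer input instead of shipping the patch matrix back to R.

static arma::cube cube_view(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
}

static NumericVector alloc3(int a, int b, int c) {
  NumericVector out((R_xlen_t)a * b * c);
  out.attr("dim") = IntegerVector::create(a, b, c);
  return out;
}

static arma::cube reflect_pad_cube(const arma::cube& x, int p) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube xp(H + 2 * p, W + 2 * p, C);
  auto src_idx = [&](int i, int n) {
    int s = i - p;
    if (s < 0) s = -s;
    if (s >= n) s = 2 * n - 2 - s;
    return s;
  };
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W + 2 * p; ++j) {
      const int sj = src_idx(j, W);
      for (int i = 0; i < H + 2 * p; ++i)
        xp(i, j, c) = x(src_idx(i, H), sj, c);
    }
  return xp;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(const NumericVector& x, const arma::mat& K,
                             const arma::vec& b, int kh, int kw, int stride,
                             int pad, bool reflect) {
  arma::cube xv = cube_view(x);
  arma::cube xp = reflect ? reflect_pad_cube(xv, pad) : arma::cube();
  const arma::cube& xr = reflect ? xp : xv;
  const int padc = reflect ? 0 : pad;
  arma::mat cols = im2col_cpp(xr, kh, kw, stride, padc);
  const int outH = (xr.n_rows + 2 * padc - kh) / stride + 1;
  const int outW = (xr.n_cols + 2 * padc - kw) / stride + 1;
  NumericVector out = alloc3(outH, outW, K.n_cols);
  arma::mat Y(out.begin(), outH * outW, K.n_cols, false, true);
  Y = cols * K;
  Y.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const NumericVector& dy, const NumericVector& x,
                    const arma::mat& K, int kh, int kw, int stride, int pad,
                    bool reflect, bool accumulate) {
  arma::cube dyv = cube_view(dy), xv = cube_view(x);
  arma::cube xp = reflect ? reflect_pad_cube(xv, pad) : arma::cube();
  const arma::cube& xr = reflect ? xp : xv;
  const int padc = reflect ? 0 : pad;
  const int P = dyv.n_rows * dyv.n_cols;
  const arma::mat dY(const_cast<double*>(dyv.memptr()), P, dyv.n_slices, false, true);
  List res;
  NumericVector dx = alloc3(xv.n_rows, xv.n_cols, xv.n_slices);
  if (accumulate) {
    arma::mat cols = im2col_cpp(xr, kh, kw, stride, padc);
    res["dW"] = wrap(arma::mat(cols.t() * dY));
    res["db"] = wrap(arma::vec(arma::sum(dY, 0).t()));
  }
  arma::mat dcols = dY * K.t();
  arma::cube dxp = col2im_cpp(dcols, xr.n_rows, xr.n_cols, xr.n_slices,
                              kh, kw, stride, padc);
  arma::cube dxv(dx.begin(), xv.n_rows, xv.n_cols, xv.n_slices, false, true);
  if (reflect && pad > 0) {
    const int H = xv.n_rows, W = xv.n_cols;
    auto src_idx = [&](int i, int n) {
      int s = i - pad;
      if (s < 0) s = -s;
      if (s >= n) s = 2 * n - 2 - s;
      return s;
    };
    for (unsigned c = 0; c < xv.n_slices; ++c)
      for (unsigned j = 0; j < dxp.n_cols; ++j) {
        const int sj = src_idx(j, W);
        for (unsigned i = 0; i < dxp.n_rows; ++i)
          dxv(src_idx(i, H), sj, c) += dxp(i, j, c);
      }
  } else {
    dxv = dxp;
  }
  res["dx"] = dx;
  return res;
}

// Transposed conv, kernel 3, stride 2, pad 1, output padding 1 (doubles H,W).
// K is the kernel reshaped [9*Cout, Cin].
// [[Rcpp::export]]
NumericVector convt2d_fwd_cpp(const NumericVector& x, const arma::mat& K,
                              const arma::vec& b) {
  arma::cube xv = cube_view(x);
  const int h = xv.n_rows, w = xv.n_cols, cin = xv.n_slices;
  const int cout = K.n_rows / 9;
  const arma::mat Xm(const_cast<double*>(xv.memptr()), h * w, cin, false, true);
  arma::mat cols = Xm * K.t();                       // [h*w, 9*cout]
  NumericVector out = alloc3(2 * h, 2 * w, cout);
  arma::cube yv(out.begin(), 2 * h, 2 * w, cout, false, true);
  yv = col2im_cpp(cols, 2 * h, 2 * w, cout, 3, 3, 2, 1);
  for (int c = 0; c < cout; ++c) yv.slice(c) += b(c);
  return out;
}

// [[Rcpp::export]]
List convt2d_bwd_cpp(const NumericVector& dy, const NumericVector& x,
                     const arma::mat& K, bool accumulate) {
  arma::cube dyv = cube_view(dy), xv = cube_view(x);
  const int h = xv.n_rows, w = xv.n_cols, cin = xv.n_slices;
  const arma::mat Xm(const_cast<double*>(xv.memptr()), h * w, cin, false, true);
  arma::mat dcols = im2col_cpp(dyv, 3, 3, 2, 1);     // [h*w, 9*cout]
  List res;
  if (accumulate) {
    res["dW"] = wrap(arma::mat(dcols.t() * Xm));     // [9*cout, cin]
    arma::vec db(dyv.n_slices);
    for (unsigned c = 0; c < dyv.n_slices; ++c) db(c) = arma::accu(dyv.slice(c));
    res["db"] = wrap(db);
  }
  NumericVector dx = alloc3(h, w, cin);
  arma::mat dXv(dx.begin(), h * w, cin, false, true);
  dXv = dcols * K;
  res["dx"] = dx;
  return res;
}

// Instance normalisation without affine parameters, per channel over H x W.
// [[Rcpp::export]]
List inorm_fwd_cpp(const NumericVector& x, double eps) {
  arma::cube xv = cube_view(x);
  const int n = xv.n_rows * xv.n_cols, C = xv.n_slices;
  NumericVector out = alloc3(xv.n_rows, xv.n_cols, C);
  arma::vec istd(C);
  for (int c = 0; c < C; ++c) {
    const arma::vec xs(const_cast<double*>(xv.slice(c).memptr()), n, false, true);
    arma::vec ys(out.begin() + (R_xlen_t)c * n, n, false, true);
    const double mu = arma::mean(xs);
    const double v = arma::mean(arma::square(xs - mu));
    const double is = 1.0 / std::sqrt(v + eps);
    istd(c) = is;
    ys = (xs - mu) * is;
  }
  return List::create(_["y"] = out, _["istd"] = wrap(istd));
}

// [[Rcpp::export]]
NumericVector inorm_bwd_cpp(const NumericVector& dy, const NumericVector& xhat,
                            const arma::vec& istd) {
  arma::cube dyv = cube_view(dy), hv = cube_view(xhat);
  const int n = dyv.n_rows * dyv.n_cols, C = dyv.n_slices;
  NumericVector out = alloc3(dyv.n_rows, dyv.n_cols, C);
  for (int c = 0; c < C; ++c) {
    const arma::vec dv(const_cast<double*>(dyv.slice(c).memptr()), n, false, true);
    const arma::vec hs(const_cast<double*>(hv.slice(c).memptr()), n, false, true);
    arma::vec ov(out.begin() + (R_xlen_t)c * n, n, false, true);
    const double m1 = arma::mean(dv);
    const double m2 = arma::mean(dv % hs);
    ov = (dv - m1 - hs * m2) * istd(c);
  }
  return out;
}
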