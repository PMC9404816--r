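// Minimal CNN primitives for the semi-Siamese U-Net: same-padded stride-1
// convolution (im2col + GEMM), 2x2 max-pooling and 2x nearest upsampling,
// each with its reverse-mode gradient.  Tensors are H x W x C arrays; the
// convolution weight is a (k*k*c_in) x c_out matrix whose row index runs
// fastest over the kernel row offset, then the kernel column offset, then
// the input channel (the layout im2col_same produces).  R arrays and
// matrices are wrapped as Armadillo views without copying.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static cube cube_view(const Rcpp::NumericVector& a) {
  Rcpp::IntegerVector d = a.attr("dim");
  const int C = d.size() == 3 ? d[2] : 1;
  return cube(const_cast<double*>(a.begin()), d[0], d[1], C, false, true);
}

static mat mat_view(const Rcpp::NumericMatrix& m) {
  return mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(), false, true);
}

static Rcpp::NumericVector alloc_cube(const int H, const int W, const int C) {
  Rcpp::NumericVector out(H * W * C);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, C);
  return out;
}

static mat im2col_same(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  mat cols(H * W, k * k * C);
  mat P(H + 2 * p, W + 2 * p, fill::zeros);
  for (int c = 0; c < C; ++c) {
    P.submat(p, p, p + H - 1, p + W - 1) = x.slice(c);
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di)
        cols.col(c * k * k + dj * k + di) =
          vectorise(P.submat(di, dj, di + H - 1, dj + W - 1));
  }
  return cols;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv_fwd(const Rcpp::NumericVector& x,
                                 const Rcpp::NumericMatrix& w,
                                 const arma::vec& b, const int k) {
  const cube xc = cube_view(x);
  const mat wm = mat_view(w);
  const int H = xc.n_rows, W = xc.n_cols, cout = wm.n_cols;
  Rcpp::NumericVector res = alloc_cube(H, W, cout);
  mat out(res.begin(), H * W, cout, false, true);
  if (k == 1) {
    const mat xm(const_cast<double*>(xc.memptr()), H * W, xc.n_slices, false, true);
    out = xm * wm;
  } else {
    out = im2col_same(xc, k) * wm;
  }
  out.each_row() += b.t();
  return res;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const Rcpp::NumericVector& x,
                        const Rcpp::NumericMatrix& w,
                        const Rcpp::NumericVector& dy, const int k) {
  const cube xc = cube_view(x);
  const mat wm = mat_view(w);
  const cube dyc = cube_view(dy);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int cout = dyc.n_slices, p = (k - 1) / 2;
  const mat dy_mat(const_cast<double*>(dyc.memptr()), H * W, cout, false, true);

  Rcpp::NumericMatrix dw_r(wm.n_rows, wm.n_cols);
  mat dw(dw_r.begin(), wm.n_rows, wm.n_cols, false, true);
  Rcpp::NumericVector dx_r = alloc_cube(H, W, C);
  cube dx(dx_r.begin(), H, W, C, false, true);
  vec db = sum(dy_mat, 0).t();

  if (k == 1) {
    const mat xm(const_cast<double*>(xc.memptr()), H * W, C, false, true);
    dw = xm.t() * dy_mat;
    mat dxm(dx.memptr(), H * W, C, false, true);
    dxm = dy_mat * wm.t();
  } else {
    mat cols = im2col_same(xc, k);
    dw = cols.t() * dy_mat;
    mat dcols = dy_mat * wm.t();               // (H*W) x (k*k*C)
    mat dP(H + 2 * p, W + 2 * p);
    for (int c = 0; c < C; ++c) {
      dP.zeros();
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di)
          dP.submat(di, dj, di + H - 1, dj + W - 1) +=
            reshape(dcols.col(c * k * k + dj * k + di), H, W);
      dx.slice(c) = dP.submat(p, p, p + H - 1, p + W - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx_r,
                            Rcpp::Named("dw") = dw_r,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fwd(const Rcpp::NumericVector& x) {
  const cube xc = cube_view(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int h = H / 2, w = W / 2;
  Rcpp::NumericVector out_r = alloc_cube(h, w, C);
  cube out(out_r.begin(), h, w, C, false, true);
  umat idx(h * w, C);                          // linear argmax inside each slice
  for (int c = 0; c < C; ++c) {
    const mat& s = xc.slice(c);
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        int bi = 2 * i, bj = 2 * j, mi = bi, mj = bj;
        double m = s(bi, bj);
        if (s(bi + 1, bj) > m) { m = s(bi + 1, bj); mi = bi + 1; mj = bj; }
        if (s(bi, bj + 1) > m) { m = s(bi, bj + 1); mi = bi; mj = bj + 1; }
        if (s(bi + 1, bj + 1) > m) { m = s(bi + 1, bj + 1); mi = bi + 1; mj = bj + 1; }
        out(i, j, c) = m;
        idx(i + j * h, c) = mi + mj * H;
      }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out_r, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_maxpool_bwd(const Rcpp::NumericVector& dy,
                                    const arma::umat& idx,
                                    const int H, const int W) {
  const cube dyc = cube_view(dy);
  const int C = dyc.n_slices, hw = dyc.n_rows * dyc.n_cols;
  Rcpp::NumericVector dx_r = alloc_cube(H, W, C);
  cube dx(dx_r.begin(), H, W, C, false, true);
  dx.zeros();
  for (int c = 0; c < C; ++c) {
    const double* g = dyc.slice(c).memptr();
    double* d = dx.slice_memptr(c);
    for (int t = 0; t < hw; ++t) d[idx(t, c)] += g[t];
  }
  return dx_r;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_upsample2_fwd(const Rcpp::NumericVector& x) {
  const cube xc = cube_view(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  Rcpp::NumericVector out_r = alloc_cube(2 * H, 2 * W, C);
  cube out(out_r.begin(), 2 * H, 2 * W, C, false, true);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = xc(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out_r;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_upsample2_bwd(const Rcpp::NumericVector& dy) {
  const cube dyc = cube_view(dy);
  const int H = dyc.n_rows / 2, W = dyc.n_cols / 2, C = dyc.n_slices;
  Rcpp::NumericVector dx_r = alloc_cube(H, W, C);
  cube dx(dx_r.begin(), H, W, C, false, true);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dyc(2 * i, 2 * j, c) + dyc(2 * i + 1, 2 * j, c) +
                      dyc(2 * i, 2 * j + 1, c) + dyc(2 * i + 1, 2 * j + 1, c);
  return dx_r;
}
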