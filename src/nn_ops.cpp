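// Compute kernels for the network layers and image filters.
// Tensors are arma::cube (H, W, C), matching R's (H, W, C) arrays
// (both column-major). Convolution weights arrive as flat vectors with a
// (kh, kw, cin, cout) dim attribute; they are viewed as a
// (kh*kw*cin) x cout matrix, which matches the im2col column ordering
// below (kernel row fastest, then kernel col, then input channel).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat weights_as_matrix(const Rcpp::NumericVector& w, int& kh, int& kw,
                             int& cin, int& cout) {
  Rcpp::IntegerVector d = w.attr("dim");
  if (d.size() != 4) Rcpp::stop("conv weights must have a 4-d dim attribute");
  kh = d[0]; kw = d[1]; cin = d[2]; cout = d[3];
  // no copy: view the flat vector as a matrix
  return mat(const_cast<double*>(w.begin()), kh * kw * cin, cout, false, true);
}

static cube pad_zero(const cube& x, int p) {
  if (p == 0) return x;
  cube out(x.n_rows + 2 * p, x.n_cols + 2 * p, x.n_slices, fill::zeros);
  out.subcube(p, p, 0, p + x.n_rows - 1, p + x.n_cols - 1, x.n_slices - 1) = x;
  return out;
}

static mat im2col_valid(const cube& x, int kh, int kw) {
  const int Ho = x.n_rows - kh + 1, Wo = x.n_cols - kw + 1;
  const int C = x.n_slices;
  mat X(Ho * Wo, kh * kw * C);
  for (int ci = 0; ci < C; ++ci)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * ci);
        X.col(k) = vectorise(x.slice(ci).submat(i, j, i + Ho - 1, j + Wo - 1));
      }
  return X;
}

static cube col2im_valid(const mat& G, int H, int W, int C, int kh, int kw) {
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  cube gx(H, W, C, fill::zeros);
  for (int ci = 0; ci < C; ++ci)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * ci);
        gx.slice(ci).submat(i, j, i + Ho - 1, j + Wo - 1) +=
            reshape(G.col(k), Ho, Wo);
      }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fw(const arma::cube& x, const Rcpp::NumericVector& w,
                         const arma::vec& b, int pad) {
  int kh, kw, cin, cout;
  mat W = weights_as_matrix(w, kh, kw, cin, cout);
  if ((int)x.n_slices != cin) Rcpp::stop("channel mismatch in conv2d");
  cube xp = pad_zero(x, pad);
  if ((int)xp.n_rows < kh || (int)xp.n_cols < kw)
    Rcpp::stop("input smaller than kernel");
  const int Ho = xp.n_rows - kh + 1, Wo = xp.n_cols - kw + 1;
  mat Y = im2col_valid(xp, kh, kw) * W;
  Y.each_row() += b.t();
  return cube(Y.memptr(), Ho, Wo, cout);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bw(const arma::cube& x, const Rcpp::NumericVector& w,
                         const arma::cube& gy, int pad) {
  int kh, kw, cin, cout;
  mat W = weights_as_matrix(w, kh, kw, cin, cout);
  cube xp = pad_zero(x, pad);
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  mat Gy(const_cast<double*>(gy.memptr()), Ho * Wo, cout, false, true);
  mat X = im2col_valid(xp, kh, kw);
  mat gW = X.t() * Gy;
  vec gb = sum(Gy, 0).t();
  mat Gx = Gy * W.t();
  cube gxp = col2im_valid(Gx, xp.n_rows, xp.n_cols, cin, kh, kw);
  cube gx = (pad == 0) ? gxp
                       : cube(gxp.subcube(pad, pad, 0, pad + x.n_rows - 1,
                                          pad + x.n_cols - 1, cin - 1));
  Rcpp::NumericVector gwv(gW.begin(), gW.end());
  gwv.attr("dim") = Rcpp::IntegerVector::create(kh, kw, cin, cout);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gwv,
                            Rcpp::Named("gb") = gb);
}

// 2x2 stride-2 transpose convolution: out(2i+a, 2j+b, :) = x(i,j,:) W[a,b]
// [[Rcpp::export]]
arma::cube cpp_tconv2_fw(const arma::cube& x, const Rcpp::NumericVector& w,
                         const arma::vec& b) {
  int kh, kw, cin, cout;
  mat W = weights_as_matrix(w, kh, kw, cin, cout);
  if (kh != 2 || kw != 2) Rcpp::stop("transpose conv kernel must be 2x2");
  const int H = x.n_rows, Wd = x.n_cols;
  mat X(const_cast<double*>(x.memptr()), H * Wd, cin, false, true);
  cube out(2 * H, 2 * Wd, cout, fill::zeros);
  for (int a = 0; a < 2; ++a)
    for (int bb = 0; bb < 2; ++bb) {
      // rows of W for kernel position (a, bb): index a + 2*(bb + 2*ci)
      mat Wab(cin, cout);
      for (int ci = 0; ci < cin; ++ci) Wab.row(ci) = W.row(a + 2 * (bb + 2 * ci));
      mat Y = X * Wab;  // (H*Wd) x cout
      for (int co = 0; co < cout; ++co) {
        mat Ym = reshape(Y.col(co), H, Wd);
        // stride-2 kernel-2: each output pixel written exactly once
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            out(2 * i + a, 2 * j + bb, co) = Ym(i, j);
      }
    }
  for (int co = 0; co < cout; ++co) out.slice(co) += b(co);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_tconv2_bw(const arma::cube& x, const Rcpp::NumericVector& w,
                         const arma::cube& gy) {
  int kh, kw, cin, cout;
  mat W = weights_as_matrix(w, kh, kw, cin, cout);
  const int H = x.n_rows, Wd = x.n_cols;
  mat X(const_cast<double*>(x.memptr()), H * Wd, cin, false, true);
  mat gX(H * Wd, cin, fill::zeros);
  mat gW(4 * cin, cout, fill::zeros);
  vec gb(cout, fill::zeros);
  for (int co = 0; co < cout; ++co) gb(co) = accu(gy.slice(co));
  for (int a = 0; a < 2; ++a)
    for (int bb = 0; bb < 2; ++bb) {
      // gather strided gy positions into (H*Wd) x cout
      mat Gab(H * Wd, cout);
      for (int co = 0; co < cout; ++co) {
        mat Gm(H, Wd);
        for (int i = 0; i < H; ++i)
          for (int j = 0; j < Wd; ++j) Gm(i, j) = gy(2 * i + a, 2 * j + bb, co);
        Gab.col(co) = vectorise(Gm);
      }
      mat Wab(cin, cout);
      for (int ci = 0; ci < cin; ++ci) Wab.row(ci) = W.row(a + 2 * (bb + 2 * ci));
      gX += Gab * Wab.t();
      mat gWab = X.t() * Gab;  // cin x cout
      for (int ci = 0; ci < cin; ++ci) gW.row(a + 2 * (bb + 2 * ci)) = gWab.row(ci);
    }
  cube gx(gX.memptr(), H, Wd, cin);
  Rcpp::NumericVector gwv(gW.begin(), gW.end());
  gwv.attr("dim") = Rcpp::IntegerVector::create(2, 2, cin, cout);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gwv,
                            Rcpp::Named("gb") = gb);
}

// 2x2 stride-2 max pooling; odd trailing row/col dropped (floor semantics)
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fw(const arma::cube& x) {
  const int Ho = x.n_rows / 2, Wo = x.n_cols / 2, C = x.n_slices;
  cube out(Ho, Wo, C);
  Rcpp::IntegerVector idx(Ho * Wo * C);  // linear index into x, 0-based
  int p = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bi = 2 * i, bj = 2 * j;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        out(i, j, c) = best;
        idx[p++] = bi + x.n_rows * (bj + x.n_cols * c);
      }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bw(const arma::cube& gy, const Rcpp::IntegerVector& idx,
                           int H, int W) {
  cube gx(H, W, gy.n_slices, fill::zeros);
  const double* g = gy.memptr();
  double* out = gx.memptr();
  for (int p = 0; p < (int)idx.size(); ++p) out[idx[p]] += g[p];
  return gx;
}

// ---- separable 1-D filtering along rows then columns ---------------------
// mode 0: valid, mode 1: full (zero-extended)

static mat conv1d_cols(const mat& x, const vec& k, int mode) {
  const int K = k.n_elem;
  if (mode == 0) {
    const int Ho = x.n_rows - K + 1;
    mat y(Ho, x.n_cols, fill::zeros);
    for (int i = 0; i < K; ++i) y += k(i) * x.rows(i, i + Ho - 1);
    return y;
  }
  const int Ho = x.n_rows + K - 1;
  mat y(Ho, x.n_cols, fill::zeros);
  for (int i = 0; i < K; ++i) y.rows(i, i + x.n_rows - 1) += k(i) * x;
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_sepfilter(const arma::cube& x, const arma::vec& krow,
                         const arma::vec& kcol, int mode) {
  int Ho, Wo;
  if (mode == 0) { Ho = x.n_rows - krow.n_elem + 1; Wo = x.n_cols - kcol.n_elem + 1; }
  else { Ho = x.n_rows + krow.n_elem - 1; Wo = x.n_cols + kcol.n_elem - 1; }
  if (Ho < 1 || Wo < 1) Rcpp::stop("filter larger than image in valid mode");
  cube out(Ho, Wo, x.n_slices);
  for (unsigned c = 0; c < x.n_slices; ++c) {
    mat t = conv1d_cols(x.slice(c), krow, mode);
    out.slice(c) = conv1d_cols(t.t(), kcol, mode).t();
  }
  return out;
}

// Direct 2-D correlation with a small kernel, reflect boundary, same size.
// flip = true convolves (kernel rotated 180) instead of correlating.
// [[Rcpp::export]]
arma::mat cpp_filter2_reflect(const arma::mat& x, const arma::mat& k,
                              bool flip) {
  const int H = x.n_rows, W = x.n_cols;
  const int kh = k.n_rows, kw = k.n_cols;
  const int ph = kh / 2, pw = kw / 2;
  mat xp(H + 2 * ph, W + 2 * pw);
  // reflect without repeating the edge pixel
  for (int i = 0; i < H + 2 * ph; ++i) {
    int ii = i - ph;
    if (ii < 0) ii = -ii;
    if (ii > H - 1) ii = 2 * (H - 1) - ii;
    for (int j = 0; j < W + 2 * pw; ++j) {
      int jj = j - pw;
      if (jj < 0) jj = -jj;
      if (jj > W - 1) jj = 2 * (W - 1) - jj;
      xp(i, j) = x(ii, jj);
    }
  }
  mat out(H, W, fill::zeros);
  for (int a = 0; a < kh; ++a)
    for (int b = 0; b < kw; ++b) {
      double kv = flip ? k(kh - 1 - a, kw - 1 - b) : k(a, b);
      if (kv == 0) continue;
      out += kv * xp.submat(a, b, a + H - 1, b + W - 1);
    }
  return out;
}
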