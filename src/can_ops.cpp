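// Numerical core of the context aggregation network and the SSIM filter.
//
// The network is a stack of 3x3 convolutions with exponentially growing
// dilation (padding == dilation, stride 1, so spatial size is preserved),
// each followed by adaptive normalization AN(x) = a*x + b*(gamma*IN(x) +
// beta) (IN = per-channel instance normalization) and a leaky ReLU, and a
// final 1x1 convolution to one channel trained with mean-squared error.
// Parameters live in one flat vector; per 3x3 level the layout is
// [W(3*3*Cin*Cout), bias(Cout), a, b, gamma(Cout), beta(Cout)], column-major
// W as an R array dim c(3, 3, Cin, Cout), then [W(M), bias(1)] for the 1x1
// head.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double IN_EPS = 1e-5;

// Dilated 3x3 convolution (zero padding = dilation, stride 1) via
// im2col + GEMM. A cube(H, W, C) is memory-identical to a column-major
// mat(H*W, C), so output/gradient cubes are aliased as matrices.

// column layout of the patch matrix: ky + 3*kx + 9*ci, matching the flat
// weight array W[ky + 3*kx + 9*ci + 9*Cin*co] == mat(9*Cin, Cout)
static mat im2col3(const cube& in, int d) {
  const int H = in.n_rows, Wd = in.n_cols, Cin = in.n_slices;
  mat X(H * (size_t)Wd, 9 * (size_t)Cin, fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const mat& sl = in.slice(ci);
    for (int kx = 0; kx < 3; ++kx) {
      int dx = (kx - 1) * d;
      int c0 = std::max(0, -dx), c1 = Wd - 1 - std::max(0, dx);
      if (c0 > c1) continue;
      for (int ky = 0; ky < 3; ++ky) {
        int dy = (ky - 1) * d;
        int r0 = std::max(0, -dy), r1 = H - 1 - std::max(0, dy);
        if (r0 > r1) continue;
        double* dst = X.colptr(ky + 3 * kx + 9 * ci);
        for (int j = c0; j <= c1; ++j) {
          const double* src = sl.colptr(j + dx) + r0 + dy;
          std::memcpy(dst + (size_t)H * j + r0, src,
                      (r1 - r0 + 1) * sizeof(double));
        }
      }
    }
  }
  return X;
}

// scatter-add of a patch-matrix gradient back to image space
static void col2im3(const mat& dX, cube& din, int d) {
  const int H = din.n_rows, Wd = din.n_cols, Cin = din.n_slices;
  din.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    mat& sl = din.slice(ci);
    for (int kx = 0; kx < 3; ++kx) {
      int dx = (kx - 1) * d;
      int c0 = std::max(0, -dx), c1 = Wd - 1 - std::max(0, dx);
      if (c0 > c1) continue;
      for (int ky = 0; ky < 3; ++ky) {
        int dy = (ky - 1) * d;
        int r0 = std::max(0, -dy), r1 = H - 1 - std::max(0, dy);
        if (r0 > r1) continue;
        const double* src = dX.colptr(ky + 3 * kx + 9 * ci);
        for (int j = c0; j <= c1; ++j) {
          double* dst = sl.colptr(j + dx) + r0 + dy;
          const double* s = src + (size_t)H * j + r0;
          for (int i = 0; i <= r1 - r0; ++i) dst[i] += s[i];
        }
      }
    }
  }
}

static void conv3_forward(const cube& in, cube& out, const double* W,
                          const double* b, int d) {
  const int Cin = in.n_slices, Cout = out.n_slices;
  const size_t npix = in.n_rows * (size_t)in.n_cols;
  mat X = im2col3(in, d);
  const mat Wm(const_cast<double*>(W), 9 * (size_t)Cin, Cout, false, true);
  mat out_alias(out.memptr(), npix, Cout, false, true);
  out_alias = X * Wm;
  for (int co = 0; co < Cout; ++co) out_alias.col(co) += b[co];
}

static void conv3_backward(const cube& in, const cube& dout, cube& din,
                           double* dW, double* db, const double* W, int d) {
  const int Cin = in.n_slices, Cout = dout.n_slices;
  const size_t npix = in.n_rows * (size_t)in.n_cols;
  mat X = im2col3(in, d);
  const mat dout_alias(const_cast<double*>(dout.memptr()), npix, Cout,
                       false, true);
  mat dWm(dW, 9 * (size_t)Cin, Cout, false, true);
  dWm += X.t() * dout_alias;
  for (int co = 0; co < Cout; ++co) db[co] = accu(dout_alias.col(co));
  const mat Wm(const_cast<double*>(W), 9 * (size_t)Cin, Cout, false, true);
  mat dX = dout_alias * Wm.t();
  col2im3(dX, din, d);
}

struct LevelCache {
  cube z;      // conv output (pre-norm)
  cube zh;     // instance-normalized z
  cube act;    // post-LReLU output (input to next level)
  vec inv_sd;  // per-channel 1/sqrt(var + eps)
};

// forward through the nine dilated levels + 1x1 head; caches per level if
// requested (training); params offsets computed on the fly
static mat forward_pass(const cube& x0, const std::vector<double>& par,
                        const Rcpp::IntegerVector& cin,
                        const Rcpp::IntegerVector& cout,
                        const Rcpp::IntegerVector& dil,
                        const Rcpp::NumericVector& lrelu,
                        std::vector<LevelCache>* caches,
                        std::vector<size_t>* offsets_out) {
  const int H = x0.n_rows, Wd = x0.n_cols;
  const int L = dil.size();
  size_t off = 0;
  cube cur = x0;
  for (int l = 0; l < L; ++l) {
    const int Ci = cin[l], Co = cout[l];
    const double* W = par.data() + off;
    const double* b = par.data() + off + 9 * Ci * Co;
    const double a = par[off + 9 * Ci * Co + Co];
    const double bm = par[off + 9 * Ci * Co + Co + 1];
    const double* gamma = par.data() + off + 9 * Ci * Co + Co + 2;
    const double* beta = gamma + Co;
    if (offsets_out) offsets_out->push_back(off);
    off += 9 * (size_t)Ci * Co + Co + 2 + 2 * (size_t)Co;

    cube z(H, Wd, Co);
    conv3_forward(cur, z, W, b, dil[l]);
    cube zh(H, Wd, Co), act(H, Wd, Co);
    vec inv_sd(Co);
    const double npix = (double)H * Wd;
    for (int c = 0; c < Co; ++c) {
      double m = accu(z.slice(c)) / npix;
      double v = accu(square(z.slice(c))) / npix - m * m;
      double is = 1.0 / std::sqrt(v + IN_EPS);
      inv_sd[c] = is;
      zh.slice(c) = (z.slice(c) - m) * is;
      mat an = a * z.slice(c) + bm * (gamma[c] * zh.slice(c) + beta[c]);
      const double s = lrelu[l];
      an.transform([s](double v) { return v >= 0 ? v : s * v; });
      act.slice(c) = an;
    }
    if (caches) {
      LevelCache lc;
      lc.z = z; lc.zh = zh; lc.act = act; lc.inv_sd = inv_sd;
      caches->push_back(std::move(lc));
    }
    cur = std::move(act);
  }
  // 1x1 head
  const int M = cur.n_slices;
  const double* W10 = par.data() + off;
  const double b10 = par[off + M];
  if (offsets_out) offsets_out->push_back(off);
  mat out(H, Wd, fill::value(b10));
  for (int c = 0; c < M; ++c) out += W10[c] * cur.slice(c);
  return out;
}

// [[Rcpp::export(name = ".can_forward_cpp")]]
arma::mat can_forward_cpp(const arma::cube& x,
                          const Rcpp::NumericVector& params,
                          const Rcpp::IntegerVector& cin,
                          const Rcpp::IntegerVector& cout,
                          const Rcpp::IntegerVector& dil,
                          const Rcpp::NumericVector& lrelu) {
  std::vector<double> par(params.begin(), params.end());
  return forward_pass(x, par, cin, cout, dil, lrelu, nullptr, nullptr);
}

// [[Rcpp::export(name = ".can_loss_grad_cpp")]]
Rcpp::List can_loss_grad_cpp(const arma::cube& x, const arma::mat& label,
                             const Rcpp::NumericVector& params,
                             const Rcpp::IntegerVector& cin,
                             const Rcpp::IntegerVector& cout,
                             const Rcpp::IntegerVector& dil,
                             const Rcpp::NumericVector& lrelu) {
  std::vector<double> par(params.begin(), params.end());
  std::vector<LevelCache> caches;
  std::vector<size_t> offs;
  mat pred = forward_pass(x, par, cin, cout, dil, lrelu, &caches, &offs);

  const int H = x.n_rows, Wd = x.n_cols, L = dil.size();
  const double npix = (double)H * Wd;
  mat resid = pred - label;
  double loss = accu(square(resid)) / npix;
  mat dout_head = (2.0 / npix) * resid;

  Rcpp::NumericVector grad(params.size());
  std::fill(grad.begin(), grad.end(), 0.0);

  // 1x1 head backward
  const int M = cout[L - 1];
  size_t off10 = offs[L];
  const cube& top = caches[L - 1].act;
  cube dcur(H, Wd, M);
  for (int c = 0; c < M; ++c) {
    grad[off10 + c] = accu(dout_head % top.slice(c));
    dcur.slice(c) = par[off10 + c] * dout_head;
  }
  grad[off10 + M] = accu(dout_head);

  for (int l = L - 1; l >= 0; --l) {
    const int Ci = cin[l], Co = cout[l];
    const size_t off = offs[l];
    const double* W = par.data() + off;
    const double a = par[off + 9 * Ci * Co + Co];
    const double bm = par[off + 9 * Ci * Co + Co + 1];
    const double* gamma = par.data() + off + 9 * Ci * Co + Co + 2;
    const LevelCache& lc = caches[l];
    const cube& below = (l == 0) ? x : caches[l - 1].act;

    cube dz(H, Wd, Co);
    double da = 0.0, dbm = 0.0;
    for (int c = 0; c < Co; ++c) {
      // leaky ReLU: slope 1 where pre-activation >= 0 (act >= 0) else s
      const double s = lrelu[l];
      mat mask = lc.act.slice(c);
      mask.transform([s](double v) { return v >= 0 ? 1.0 : s; });
      mat dan = dcur.slice(c) % mask;
      const mat& zc = lc.z.slice(c);
      const mat& zhc = lc.zh.slice(c);
      da += accu(dan % zc);
      double dgamma = accu(dan % zhc);
      double dbeta = accu(dan);
      dbm += gamma[c] * dgamma + par[off + 9 * Ci * Co + Co + 2 + Co + c] * dbeta;
      grad[off + 9 * Ci * Co + Co + 2 + c] += bm * dgamma;
      grad[off + 9 * Ci * Co + Co + 2 + Co + c] += bm * dbeta;
      // back through instance norm
      mat dzh = (bm * gamma[c]) * dan;
      double m_dzh = accu(dzh) / npix;
      double m_dzh_zh = accu(dzh % zhc) / npix;
      dz.slice(c) = lc.inv_sd[c] * (dzh - m_dzh - zhc * m_dzh_zh) + a * dan;
    }
    grad[off + 9 * Ci * Co + Co] += da;
    grad[off + 9 * Ci * Co + Co + 1] += dbm;

    cube dbelow(H, Wd, Ci);
    std::vector<double> db(Co, 0.0);
    conv3_backward(below, dz, dbelow, &grad[0] + off, db.data(), W, dil[l]);
    for (int c = 0; c < Co; ++c) grad[off + 9 * Ci * Co + c] += db[c];
    dcur = std::move(dbelow);
  }

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("pred") = pred);
}

// separable Gaussian filter with mirror (reflect-101) boundary, used by the
// SSIM metric
// [[Rcpp::export(name = ".gauss_filter2_cpp")]]
arma::mat gauss_filter2_cpp(const arma::mat& x, double sigma, int win) {
  const int pad = (win - 1) / 2;
  vec g(win);
  for (int i = 0; i < win; ++i) {
    double d = i - pad;
    g[i] = std::exp(-d * d / (2.0 * sigma * sigma));
  }
  g /= accu(g);
  const int H = x.n_rows, W = x.n_cols;
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i;
      if (i >= n) i = 2 * n - 2 - i;
    }
    return i;
  };
  mat tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j) { // filter along rows
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -pad; t <= pad; ++t) s += g[t + pad] * x(reflect(i + t, H), j);
      tmp(i, j) = s;
    }
  }
  for (int j = 0; j < W; ++j) { // filter along columns
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -pad; t <= pad; ++t) s += g[t + pad] * tmp(i, reflect(j + t, W));
      out(i, j) = s;
    }
  }
  return out;
}
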