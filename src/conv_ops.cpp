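// Convolution primitives for the cGAN layers.
//
// Tensor layout everywhere: column-major R arrays dim = c(H, W, C, N),
// matching arma::mat/cube storage per sample. Convolutions are computed by
// an im2col + GEMM pair; the backward pass uses the transposed GEMMs and a
// col2im scatter-add. The im2col matrix is laid out position-major
// ((Ho*Wo) x (k*k*C)): each column holds one (kh, kw, cin) tap over all
// output positions, so writes are contiguous and reads sweep the input
// linearly. Weight arrays have dim = c(k, k, Cin, Cout), so each
// output-channel kernel flattens to one contiguous column.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C,
                             int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Fill the position-major im2col matrix ((Ho*Wo) x (k*k*C)) for one sample.
static void im2col(const double* xp, int H, int W, int C, int k, int stride,
                   int pad, int Ho, int Wo, arma::mat& cols) {
  for (int cin = 0; cin < C; ++cin) {
    const double* xc = xp + (size_t)cin * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* col = cols.colptr((size_t)cin * k * k + kw * k + kh);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kw;
          double* dst = col + (size_t)wo * Ho;
          if (w < 0 || w >= W) {
            std::fill(dst, dst + Ho, 0.0);
            continue;
          }
          const double* xcol = xc + (size_t)w * H;
          // valid ho range: 0 <= ho*stride - pad + kh < H
          int lo = 0;
          while (lo < Ho && lo * stride - pad + kh < 0) ++lo;
          int hi = Ho;
          while (hi > lo && (hi - 1) * stride - pad + kh >= H) --hi;
          std::fill(dst, dst + lo, 0.0);
          const double* src = xcol + (size_t)lo * stride - pad + kh;
          if (stride == 1) {
            std::copy(src, src + (hi - lo), dst + lo);
          } else {
            for (int ho = lo; ho < hi; ++ho)
              dst[ho] = xcol[(size_t)ho * stride - pad + kh];
          }
          std::fill(dst + hi, dst + Ho, 0.0);
        }
      }
    }
  }
}

// Scatter-add of a ((Ho*Wo) x (k*k*C)) gradient matrix onto the input grid.
static void col2im(const arma::mat& cols, int H, int W, int C, int k,
                   int stride, int pad, int Ho, int Wo, double* dxp) {
  for (int cin = 0; cin < C; ++cin) {
    double* xc = dxp + (size_t)cin * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* col = cols.colptr((size_t)cin * k * k + kw * k + kh);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          double* xcol = xc + (size_t)w * H;
          const double* src = col + (size_t)wo * Ho;
          int lo = 0;
          while (lo < Ho && lo * stride - pad + kh < 0) ++lo;
          int hi = Ho;
          while (hi > lo && (hi - 1) * stride - pad + kh >= H) --hi;
          for (int ho = lo; ho < hi; ++ho)
            xcol[(size_t)ho * stride - pad + kh] += src[ho];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weight must have dim (k, k, Cin, Cout)");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("only square kernels are supported");
  if (Cin != C) stop("input channels do not match weight");
  if (b.size() != Cout) stop("bias length must equal Cout");
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("input smaller than the kernel's reduction");

  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::mat cols((size_t)Ho * Wo, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo,
           cols);
    arma::mat O(out.begin() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo,
                Cout, false, true);
    O = cols * Wm;
    for (int co = 0; co < Cout; ++co) O.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                     int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  int Ho, Wo, Cg, Ng;
  get_dims4(gout, Ho, Wo, Cg, Ng);
  if (Cg != Cout || Ng != N) stop("gradient dims do not match");

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((size_t)k * k * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector db(Cout);

  arma::mat Wm(w.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::mat cols((size_t)Ho * Wo, (size_t)k * k * C);
  arma::mat dcols((size_t)Ho * Wo, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * H * W * C;
    arma::mat G(const_cast<double*>(gout.begin()) + (size_t)n * Ho * Wo * Cout,
                (size_t)Ho * Wo, Cout, false, true);
    im2col(xp, H, W, C, k, stride, pad, Ho, Wo, cols);
    dWm += cols.t() * G;
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(G.col(co));
    dcols = G * Wm.t();
    col2im(dcols, H, W, C, k, stride, pad, Ho, Wo,
           dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// Nearest-neighbour 2x upsampling, forward.
// [[Rcpp::export(name = ".upsample2Forward")]]
NumericVector upsample2_forward(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector out((size_t)H2 * W2 * C * N);
  out.attr("dim") = IntegerVector::create(H2, W2, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* xs = xp + s * H * W;
    double* os = op + s * H2 * W2;
    for (int w = 0; w < W2; ++w) {
      const double* xcol = xs + (size_t)(w / 2) * H;
      double* ocol = os + (size_t)w * H2;
      for (int h = 0; h < H2; ++h) ocol[h] = xcol[h / 2];
    }
  }
  return out;
}

// Backward of nearest 2x upsampling: 2x2 block sum.
// [[Rcpp::export(name = ".upsample2Backward")]]
NumericVector upsample2_backward(NumericVector g) {
  int H2, W2, C, N;
  get_dims4(g, H2, W2, C, N);
  const int H = H2 / 2, W = W2 / 2;
  NumericVector out((size_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = g.begin();
  double* op = out.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* gs = gp + s * H2 * W2;
    double* os = op + s * H * W;
    for (int w = 0; w < W2; ++w) {
      const double* gcol = gs + (size_t)w * H2;
      double* ocol = os + (size_t)(w / 2) * H;
      for (int h = 0; h < H2; ++h) ocol[h / 2] += gcol[h];
    }
  }
  return out;
}

// ---- batch-instance normalization (fused, training forward/backward) ----
//
// x has dim (H, W, C, N). Instance statistics pool over H*W per (c, n);
// batch statistics pool over H*W*N per channel.

// [[Rcpp::export(name = ".binForwardC")]]
List bin_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                 NumericVector rho, double eps) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector out((size_t)HW * C * N);
  out.attr("dim") = x.attr("dim");
  NumericVector xhatB((size_t)HW * C * N), xhatI((size_t)HW * C * N);
  NumericVector sI(C * N), sB(C);
  std::vector<double> mI(C * N), eI2(C * N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = x.begin() + HW * cn;
    double s = 0, s2 = 0;
    for (size_t i = 0; i < HW; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
    mI[cn] = s / HW; eI2[cn] = s2 / HW;
    double v = eI2[cn] - mI[cn] * mI[cn];
    sI[cn] = std::sqrt((v > 0 ? v : 0) + eps);
  }
  NumericVector mB(C), vB(C);
  for (int c = 0; c < C; ++c) {
    double m = 0, e2 = 0;
    for (int n = 0; n < N; ++n) { m += mI[c + C * n]; e2 += eI2[c + C * n]; }
    m /= N; e2 /= N;
    mB[c] = m;
    double v = e2 - m * m;
    vB[c] = v > 0 ? v : 0;
    sB[c] = std::sqrt(vB[c] + eps);
  }
  for (int cn = 0; cn < C * N; ++cn) {
    const int c = cn % C;
    const double* xs = x.begin() + HW * cn;
    double* hb = xhatB.begin() + HW * cn;
    double* hi = xhatI.begin() + HW * cn;
    double* o = out.begin() + HW * cn;
    const double mi = mI[cn], si = sI[cn], mb = mB[c], sb = sB[c];
    const double r = rho[c], g = gamma[c], b = beta[c];
    for (size_t i = 0; i < HW; ++i) {
      const double xb = (xs[i] - mb) / sb, xi = (xs[i] - mi) / si;
      hb[i] = xb; hi[i] = xi;
      o[i] = g * (r * xb + (1 - r) * xi) + b;
    }
  }
  return List::create(Named("out") = out, Named("xhatB") = xhatB,
                      Named("xhatI") = xhatI, Named("sI") = sI,
                      Named("sB") = sB, Named("mB") = mB, Named("vB") = vB);
}

// [[Rcpp::export(name = ".binBackwardC")]]
List bin_backward(NumericVector gout, NumericVector xhatB,
                  NumericVector xhatI, NumericVector sI, NumericVector sB,
                  NumericVector gamma, NumericVector rho) {
  int H, W, C, N;
  get_dims4(gout, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector dx((size_t)HW * C * N);
  dx.attr("dim") = gout.attr("dim");
  NumericVector dgamma(C), dbeta(C), drho(C);
  // per-(c, n) reductions for the IN part and channel accumulators
  std::vector<double> mI1(C * N), mI2(C * N), mB1(C, 0.0), mB2(C, 0.0);
  for (int cn = 0; cn < C * N; ++cn) {
    const int c = cn % C;
    const double* gy = gout.begin() + HW * cn;
    const double* hb = xhatB.begin() + HW * cn;
    const double* hi = xhatI.begin() + HW * cn;
    const double r = rho[c], g = gamma[c];
    double sg = 0, sgu = 0, sgr = 0, s1 = 0, s2 = 0, b1 = 0, b2 = 0;
    for (size_t i = 0; i < HW; ++i) {
      const double u = r * hb[i] + (1 - r) * hi[i];
      sg += gy[i];
      sgu += gy[i] * u;
      sgr += gy[i] * (hb[i] - hi[i]);
      const double dhi = gy[i] * g * (1 - r);
      const double dhb = gy[i] * g * r;
      s1 += dhi; s2 += dhi * hi[i];
      b1 += dhb; b2 += dhb * hb[i];
    }
    dbeta[c] += sg; dgamma[c] += sgu; drho[c] += g * sgr;
    mI1[cn] = s1 / HW; mI2[cn] = s2 / HW;
    mB1[c] += b1; mB2[c] += b2;
  }
  for (int c = 0; c < C; ++c) { mB1[c] /= HW * N; mB2[c] /= HW * N; }
  for (int cn = 0; cn < C * N; ++cn) {
    const int c = cn % C;
    const double* gy = gout.begin() + HW * cn;
    const double* hb = xhatB.begin() + HW * cn;
    const double* hi = xhatI.begin() + HW * cn;
    double* d = dx.begin() + HW * cn;
    const double r = rho[c], g = gamma[c];
    const double si = sI[cn], sb = sB[c];
    const double i1 = mI1[cn], i2 = mI2[cn], b1 = mB1[c], b2 = mB2[c];
    for (size_t i = 0; i < HW; ++i) {
      const double dhi = gy[i] * g * (1 - r);
      const double dhb = gy[i] * g * r;
      d[i] = (dhi - i1 - hi[i] * i2) / si + (dhb - b1 - hb[i] * b2) / sb;
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta, Named("drho") = drho);
}

// Evaluation-mode batch-instance norm: the BN component uses running
// statistics accumulated during training; the IN component always uses
// per-sample instance statistics.
// [[Rcpp::export(name = ".binEvalC")]]
NumericVector bin_eval(NumericVector x, NumericVector gamma,
                       NumericVector beta, NumericVector rho,
                       NumericVector run_mean, NumericVector run_var,
                       double eps) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector out((size_t)HW * C * N);
  out.attr("dim") = x.attr("dim");
  for (int cn = 0; cn < C * N; ++cn) {
    const int c = cn % C;
    const double* xs = x.begin() + HW * cn;
    double* o = out.begin() + HW * cn;
    double s = 0, s2 = 0;
    for (size_t i = 0; i < HW; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
    const double mi = s / HW;
    double vi = s2 / HW - mi * mi;
    const double si = std::sqrt((vi > 0 ? vi : 0) + eps);
    const double mb = run_mean[c];
    const double sb = std::sqrt((run_var[c] > 0 ? run_var[c] : 0) + eps);
    const double r = rho[c], g = gamma[c], b = beta[c];
    for (size_t i = 0; i < HW; ++i)
      o[i] = g * (r * (xs[i] - mb) / sb + (1 - r) * (xs[i] - mi) / si) + b;
  }
  return out;
}
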