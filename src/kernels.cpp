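// Convolution / pooling kernels for the layer-graph engine.
//
// Feature maps are R arrays in [H, W, C, N] column-major layout; convolution
// kernels are [kh, kw, C, F].  Convolutions are computed by im2col + a single
// float32 GEMM (Armadillo, backed by the BLAS R links against); float32 is the
// working precision deep-learning frameworks use and roughly doubles GEMM
// throughput over double.  Padding is explicit and may be asymmetric so that
// the TensorFlow-style "same" arithmetic of the reference architectures is
// reproduced exactly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#define ENDOFUSE_HAS_MXCSR 1
#endif
using namespace Rcpp;

// Converged training produces float32-denormal gradient values, whose
// hardware arithmetic is orders of magnitude slower than normal floats;
// flush-to-zero / denormals-are-zero during the GEMM-heavy kernels is the
// standard deep-learning-framework setting.  The control register is
// restored on scope exit so R's double-precision semantics are untouched.
struct FlushDenormals {
#ifdef ENDOFUSE_HAS_MXCSR
  unsigned int csr;
  FlushDenormals() : csr(_mm_getcsr()) { _mm_setcsr(csr | 0x8040); }
  ~FlushDenormals() { _mm_setcsr(csr); }
#endif
};

static inline int out_dim(int in, int k, int s, int p0, int p1) {
  return (in + p0 + p1 - k) / s + 1;
}

// Fill colT (P x K) for image n: row p = ho + Ho*wo, col r = ki + kh*(kj + kw*c).
static void im2col_t(const double* x, int H, int W, int C, long n_off,
                     int kh, int kw, int sh, int sw, int pt, int pl,
                     int Ho, int Wo, arma::fmat& colT) {
  const int P = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + n_off + (long)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        float* dst = colT.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w_in = wo * sw - pl + kj;
          float* d = dst + (long)Ho * wo;
          if (w_in < 0 || w_in >= W) {
            for (int ho = 0; ho < Ho; ++ho) d[ho] = 0.0f;
            continue;
          }
          const double* xcol = xc + (long)H * w_in;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h_in = ho * sh - pt + ki;
            d[ho] = (h_in >= 0 && h_in < H) ? (float)xcol[h_in] : 0.0f;
          }
        }
      }
    }
  }
  (void)P;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector b,
                             int sh, int sw, int pt, int pb, int pl, int pr) {
  FlushDenormals ftz;
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], F = wdim[3];
  if (wdim[2] != C) stop("conv2d: kernel expects %d input channels, got %d", wdim[2], C);
  const int Ho = out_dim(H, kh, sh, pt, pb), Wo = out_dim(W, kw, sw, pl, pr);
  if (Ho < 1 || Wo < 1) stop("conv2d: non-positive output size (%d x %d)", Ho, Wo);
  const int K = kh * kw * C, P = Ho * Wo;

  arma::fmat Wmat(K, F);
  { const double* wp = w.begin(); float* d = Wmat.memptr();
    for (long i = 0; i < (long)K * F; ++i) d[i] = (float)wp[i]; }
  arma::frowvec bias;
  const bool has_b = b.size() > 0;
  if (has_b) { bias.set_size(F); for (int f = 0; f < F; ++f) bias[f] = (float)b[f]; }

  NumericVector y((long)P * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::fmat colT(P, K);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin(), H, W, C, (long)H * W * C * n, kh, kw, sh, sw, pt, pl, Ho, Wo, colT);
    arma::fmat Y = colT * Wmat;          // P x F
    if (has_b) Y.each_row() += bias;
    double* yp = y.begin() + (long)P * F * n;
    const float* s = Y.memptr();
    for (long i = 0; i < (long)P * F; ++i) yp[i] = (double)s[i];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector dy, bool has_bias,
                    int sh, int sw, int pt, int pb, int pl, int pr,
                    bool need_dx) {
  FlushDenormals ftz;
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], F = wdim[3];
  const int Ho = out_dim(H, kh, sh, pt, pb), Wo = out_dim(W, kw, sw, pl, pr);
  const int K = kh * kw * C, P = Ho * Wo;

  arma::fmat Wmat(K, F);
  { const double* wp = w.begin(); float* d = Wmat.memptr();
    for (long i = 0; i < (long)K * F; ++i) d[i] = (float)wp[i]; }

  arma::fmat dW(K, F, arma::fill::zeros);
  arma::frowvec dB(F, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) { dx = NumericVector((long)H * W * C * N); dx.attr("dim") = xdim; }

  arma::fmat colT(P, K), dY(P, F);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (long)P * F * n;
    { float* d = dY.memptr();
      for (long i = 0; i < (long)P * F; ++i) d[i] = (float)dyp[i]; }
    im2col_t(x.begin(), H, W, C, (long)H * W * C * n, kh, kw, sh, sw, pt, pl, Ho, Wo, colT);
    dW += colT.t() * dY;
    if (has_bias) dB += arma::sum(dY, 0);
    if (need_dx) {
      arma::fmat dColT = dY * Wmat.t();  // P x K
      double* dxp = dx.begin() + (long)H * W * C * n;
      for (int c = 0; c < C; ++c) {
        double* dxc = dxp + (long)H * W * c;
        for (int kj = 0; kj < kw; ++kj) {
          for (int ki = 0; ki < kh; ++ki) {
            const int r = ki + kh * (kj + kw * c);
            const float* src = dColT.colptr(r);
            for (int wo = 0; wo < Wo; ++wo) {
              const int w_in = wo * sw - pl + kj;
              if (w_in < 0 || w_in >= W) continue;
              double* dcol = dxc + (long)H * w_in;
              const float* s = src + (long)Ho * wo;
              for (int ho = 0; ho < Ho; ++ho) {
                const int h_in = ho * sh - pt + ki;
                if (h_in >= 0 && h_in < H) dcol[h_in] += (double)s[ho];
              }
            }
          }
        }
      }
    }
  }

  NumericVector dwv((long)K * F);
  dwv.attr("dim") = wdim;
  { const float* s = dW.memptr(); double* d = dwv.begin();
    for (long i = 0; i < (long)K * F; ++i) d[i] = (double)s[i]; }
  NumericVector dbv(has_bias ? F : 0);
  if (has_bias) for (int f = 0; f < F; ++f) dbv[f] = (double)dB[f];
  return List::create(_["dw"] = dwv, _["db"] = dbv, _["dx"] = dx);
}

// Depthwise convolution, forward only (used inside frozen backbones).
// w is [kh, kw, C]; one filter per input channel.
// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector b,
                             int sh, int sw, int pt, int pb, int pl, int pr) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1];
  if (wdim[2] != C) stop("dwconv: kernel expects %d channels, got %d", wdim[2], C);
  const int Ho = out_dim(H, kh, sh, pt, pb), Wo = out_dim(W, kw, sw, pl, pr);
  if (Ho < 1 || Wo < 1) stop("dwconv: non-positive output size (%d x %d)", Ho, Wo);
  const bool has_b = b.size() > 0;

  NumericVector y((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (long)H * W * (c + (long)C * n);
      const double* wc = w.begin() + (long)kh * kw * c;
      double* yc = y.begin() + (long)Ho * Wo * (c + (long)C * n);
      const double bias = has_b ? b[c] : 0.0;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bias;
          for (int kj = 0; kj < kw; ++kj) {
            const int w_in = wo * sw - pl + kj;
            if (w_in < 0 || w_in >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int h_in = ho * sh - pt + ki;
              if (h_in >= 0 && h_in < H)
                acc += xc[h_in + (long)H * w_in] * wc[ki + kh * kj];
            }
          }
          yc[ho + (long)Ho * wo] = acc;
        }
      }
    }
  }
  return y;
}

// Max pooling; out-of-range window cells behave as explicit zero padding
// (matching ZeroPadding + valid pooling in the reference architectures).
// [[Rcpp::export]]
NumericVector cpp_maxpool_fwd(NumericVector x, IntegerVector xdim,
                              int ph, int pw, int sh, int sw,
                              int pt, int pb, int pl, int pr) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_dim(H, ph, sh, pt, pb), Wo = out_dim(W, pw, sw, pl, pr);
  if (Ho < 1 || Wo < 1) stop("maxpool: non-positive output size");
  NumericVector y((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xc = x.begin() + (long)H * W * cn;
    double* yc = y.begin() + (long)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double m = -HUGE_VAL;
        for (int kj = 0; kj < pw; ++kj) {
          const int w_in = wo * sw - pl + kj;
          for (int ki = 0; ki < ph; ++ki) {
            const int h_in = ho * sh - pt + ki;
            const bool inb = h_in >= 0 && h_in < H && w_in >= 0 && w_in < W;
            const double v = inb ? xc[h_in + (long)H * w_in] : 0.0;
            if (v > m) m = v;
          }
        }
        yc[ho + (long)Ho * wo] = m;
      }
    }
  }
  return y;
}

// Average pooling, valid padding only (the auxiliary-head setting).
// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, IntegerVector xdim,
                              int ph, int pw, int sh, int sw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_dim(H, ph, sh, 0, 0), Wo = out_dim(W, pw, sw, 0, 0);
  if (Ho < 1 || Wo < 1) stop("avgpool: non-positive output size");
  const double inv = 1.0 / (ph * pw);
  NumericVector y((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xc = x.begin() + (long)H * W * cn;
    double* yc = y.begin() + (long)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = 0.0;
        for (int kj = 0; kj < pw; ++kj)
          for (int ki = 0; ki < ph; ++ki)
            acc += xc[(ho * sh + ki) + (long)H * (wo * sw + kj)];
        yc[ho + (long)Ho * wo] = acc * inv;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector dy, IntegerVector ydim,
                              int H, int W, int ph, int pw, int sh, int sw) {
  const int Ho = ydim[0], Wo = ydim[1], C = ydim[2], N = ydim[3];
  const double inv = 1.0 / (ph * pw);
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* dyc = dy.begin() + (long)Ho * Wo * cn;
    double* dxc = dx.begin() + (long)H * W * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dyc[ho + (long)Ho * wo] * inv;
        for (int kj = 0; kj < pw; ++kj)
          for (int ki = 0; ki < ph; ++ki)
            dxc[(ho * sh + ki) + (long)H * (wo * sw + kj)] += g;
      }
    }
  }
  return dx;
}

// y = x * scale + shift per channel; scale/shift are length C (shared across
// the batch, e.g. batch-norm) or C*N (per image, e.g. squeeze-excitation gates).
// [[Rcpp::export]]
NumericVector cpp_chan_affine(NumericVector x, IntegerVector xdim,
                              NumericVector scale, NumericVector shift) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const long HW = (long)H * W;
  const bool per_image = scale.size() == (long)C * N;
  if (!per_image && scale.size() != C) stop("chan_affine: bad scale length");
  if (shift.size() != scale.size()) stop("chan_affine: scale/shift length mismatch");
  NumericVector y((long)HW * C * N);
  y.attr("dim") = xdim;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const long idx = per_image ? cn : (cn % C);
    const double a = scale[idx], b0 = shift[idx];
    const double* xc = x.begin() + HW * cn;
    double* yc = y.begin() + HW * cn;
    for (long i = 0; i < HW; ++i) yc[i] = xc[i] * a + b0;
  }
  return y;
}

// One Adam update for a parameter tensor.  The first/second-moment
// buffers m and v are updated in place (the optimizer state is their sole
// owner); a freshly allocated updated weight tensor is returned so that
// checkpointed copies of the old weights stay intact.
// [[Rcpp::export]]
NumericVector cpp_adam_step(NumericVector w, NumericVector g,
                            NumericVector m, NumericVector v,
                            double lr, double b1, double b2,
                            double bc1, double bc2, double eps) {
  const long n = w.size();
  if (g.size() != n || m.size() != n || v.size() != n) stop("adam: length mismatch");
  NumericVector wn(n);
  double* mp = m.begin(); double* vp = v.begin();
  const double* wp = w.begin(); const double* gp = g.begin();
  double* op = wn.begin();
  for (long i = 0; i < n; ++i) {
    const double gi = gp[i];
    mp[i] = b1 * mp[i] + (1 - b1) * gi;
    vp[i] = b2 * vp[i] + (1 - b2) * gi * gi;
    op[i] = wp[i] - lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
  if (w.hasAttribute("dim")) wn.attr("dim") = w.attr("dim");
  return wn;
}

// Pack a double array into float32 raw bytes (cached branch features are
// float-precision anyway; this halves their resident size).
// [[Rcpp::export]]
RawVector cpp_pack_f32(NumericVector x) {
  RawVector out(x.size() * 4);
  float* fp = reinterpret_cast<float*>(RAW(out));
  const double* xp = x.begin();
  for (long i = 0; i < (long)x.size(); ++i) fp[i] = (float)xp[i];
  return out;
}

// Stack n packed [H,W,C] float feature maps into one [H,W,C,n] double array.
// [[Rcpp::export]]
NumericVector cpp_stack_f32(List packed, IntegerVector dim3) {
  const int n = packed.size();
  const long sz = (long)dim3[0] * dim3[1] * dim3[2];
  NumericVector out(sz * n);
  out.attr("dim") = IntegerVector::create(dim3[0], dim3[1], dim3[2], n);
  for (int i = 0; i < n; ++i) {
    RawVector r = packed[i];
    if ((long)r.size() != sz * 4) stop("stack_f32: size mismatch at element %d", i + 1);
    const float* fp = reinterpret_cast<const float*>(RAW(r));
    double* op = out.begin() + sz * i;
    for (long j = 0; j < sz; ++j) op[j] = (double)fp[j];
  }
  return out;
}
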