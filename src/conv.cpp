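// Convolution primitives for the Morpho-VAE network.
//
// Arrays follow R's column-major layout:
//   images  x : (H, W, C, N)       weights w : (K, K, Cin, Cout)
//
// Convolutions are computed as a sum over the K*K kernel offsets: for each
// offset the (shifted, zero-padded) input block is gathered into a
// (P x Cin) buffer and multiplied against the (Cin x Cout) weight slice,
// which keeps the inner loops branch-free and leaves the heavy lifting to
// BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3", "unroll-loops", "tree-vectorize")
#endif

// valid output range [lo, hi) for input index i = o*stride + k - pad in [0, n)
static inline void out_range(int n, int no, int stride, int k, int pad,
                             int& lo, int& hi) {
  int off = k - pad;
  lo = off < 0 ? ((-off) + stride - 1) / stride : 0;
  // need o*stride + off <= n-1  ->  o <= (n-1-off)/stride
  hi = (n - 1 - off) / stride + 1;
  if (hi > no) hi = no;
  if (lo > hi) lo = hi;
}

// gather shifted block into B (P x C), zero-padding out-of-range entries
static void gather(const double* x, int H, int W, int C,
                   int Ho, int Wo, int stride, int kh, int kw, int pad,
                   arma::mat& B) {
  const int P = Ho * Wo;
  int ho0, ho1, wo0, wo1;
  out_range(H, Ho, stride, kh, pad, ho0, ho1);
  out_range(W, Wo, stride, kw, pad, wo0, wo1);
  B.set_size(P, C);
  const int hoff = kh - pad, woff = kw - pad;
  for (int c = 0; c < C; ++c) {
    double* bc = B.colptr(c);
    const double* xc = x + (size_t)H * W * c;
    // zero only the out-of-range border region
    if (wo0 > 0) std::fill(bc, bc + (size_t)Ho * wo0, 0.0);
    if (wo1 < Wo) std::fill(bc + (size_t)Ho * wo1, bc + P, 0.0);
    for (int wo = wo0; wo < wo1; ++wo) {
      const double* xw = xc + (size_t)H * (wo * stride + woff);
      double* bj = bc + (size_t)Ho * wo;
      if (ho0 > 0) std::fill(bj, bj + ho0, 0.0);
      if (ho1 < Ho) std::fill(bj + ho1, bj + Ho, 0.0);
      if (stride == 1) {
        std::copy(xw + hoff + ho0, xw + hoff + ho1, bj + ho0);
      } else {
        for (int ho = ho0; ho < ho1; ++ho) bj[ho] = xw[ho * stride + hoff];
      }
    }
  }
}

// scatter-add G (P x C) into dx at the shifted positions
static void scatter_add(double* dx, int H, int W, int C,
                        int Ho, int Wo, int stride, int kh, int kw, int pad,
                        const arma::mat& G) {
  int ho0, ho1, wo0, wo1;
  out_range(H, Ho, stride, kh, pad, ho0, ho1);
  out_range(W, Wo, stride, kw, pad, wo0, wo1);
  const int hoff = kh - pad, woff = kw - pad;
  for (int c = 0; c < C; ++c) {
    const double* gc = G.colptr(c);
    double* xc = dx + (size_t)H * W * c;
    for (int wo = wo0; wo < wo1; ++wo) {
      double* xw = xc + (size_t)H * (wo * stride + woff);
      const double* gj = gc + (size_t)Ho * wo;
      if (stride == 1) {
        double* dst = xw + hoff + ho0;
        for (int ho = ho0; ho < ho1; ++ho) dst[ho - ho0] += gj[ho];
      } else {
        for (int ho = ho0; ho < ho1; ++ho) xw[ho * stride + hoff] += gj[ho];
      }
    }
  }
}

// weight slice for offset (kh, kw): (Cin x Cout)
static void w_slice(const double* w, int K, int C, int Cout,
                    int kh, int kw, arma::mat& Wk) {
  Wk.set_size(C, Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int c = 0; c < C; ++c) {
      Wk(c, co) = w[kh + K * (kw + K * (c + (size_t)C * co))];
    }
  }
}

// direct stride-1 same-padding conv: out[h,w,co] += sum w[kh,kw,c,co] x[h+kh-p, w+kw-p, c]
static void conv_s1_fwd(const double* x, const double* w, const double* b,
                        int H, int W, int C, int K, int pad, int Cout,
                        double* out) {
  const size_t P = (size_t)H * W;
  // specialised for K = 3, pad = 1 (the only stride-1 case the model uses);
  // the three vertical taps of one kernel column are fused into one pass.
  for (int co = 0; co < Cout; ++co) {
    double* oc = out + P * co;
    std::fill(oc, oc + P, b[co]);
    for (int c = 0; c < C; ++c) {
      const double* xc = x + P * c;
      const double* wc = w + K * K * (c + (size_t)C * co);
      for (int kw = 0; kw < K; ++kw) {
        const int woff = kw - pad;
        const int w0 = woff < 0 ? -woff : 0;
        const int w1 = woff > 0 ? W - woff : W;
        const double c0 = wc[0 + K * kw], c1 = wc[1 + K * kw], c2 = wc[2 + K * kw];
        for (int wo = w0; wo < w1; ++wo) {
          const double* __restrict src = xc + (size_t)H * (wo + woff);
          double* __restrict dst = oc + (size_t)H * wo;
          dst[0] += c1 * src[0] + c2 * src[1];
          for (int h = 1; h < H - 1; ++h) {
            dst[h] += c0 * src[h - 1] + c1 * src[h] + c2 * src[h + 1];
          }
          dst[H - 1] += c0 * src[H - 2] + c1 * src[H - 1];
        }
      }
    }
  }
}

// gradients for the direct stride-1 case (K = 3, pad = 1)
static void conv_s1_bwd(const double* x, const double* w, const double* dout,
                        int H, int W, int C, int K, int pad, int Cout,
                        double* dx, double* dw, double* db, bool need_dx) {
  const size_t P = (size_t)H * W;
  for (int co = 0; co < Cout; ++co) {
    const double* dc = dout + P * co;
    double s = 0;
    for (size_t i = 0; i < P; ++i) s += dc[i];
    db[co] += s;
    for (int c = 0; c < C; ++c) {
      const double* xc = x + P * c;
      double* dxc = dx + P * c;
      const size_t wbase = K * K * (c + (size_t)C * co);
      const double* wc = w + wbase;
      for (int kw = 0; kw < K; ++kw) {
        const int woff = kw - pad;
        const int w0 = woff < 0 ? -woff : 0;
        const int w1 = woff > 0 ? W - woff : W;
        const double c0 = wc[0 + K * kw], c1 = wc[1 + K * kw], c2 = wc[2 + K * kw];
        double a0 = 0, a1 = 0, a2 = 0;
        for (int wo = w0; wo < w1; ++wo) {
          const double* __restrict xs = xc + (size_t)H * (wo + woff);
          const double* __restrict ds = dc + (size_t)H * wo;
          a1 += xs[0] * ds[0];
          a2 += xs[1] * ds[0];
          for (int h = 1; h < H - 1; ++h) {
            const double d = ds[h];
            a0 += xs[h - 1] * d;
            a1 += xs[h] * d;
            a2 += xs[h + 1] * d;
          }
          a0 += xs[H - 2] * ds[H - 1];
          a1 += xs[H - 1] * ds[H - 1];
          if (need_dx) {
            double* __restrict dxs = dxc + (size_t)H * (wo + woff);
            dxs[0] += c1 * ds[0] + c0 * ds[1];
            for (int h = 1; h < H - 1; ++h) {
              dxs[h] += c2 * ds[h - 1] + c1 * ds[h] + c0 * ds[h + 1];
            }
            dxs[H - 1] += c2 * ds[H - 2] + c1 * ds[H - 1];
          }
        }
        dw[wbase + 0 + K * kw] += a0;
        dw[wbase + 1 + K * kw] += a1;
        dw[wbase + 2 + K * kw] += a2;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and kernel");
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  const int P = Ho * Wo;

  NumericVector out((R_xlen_t)P * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  if (stride == 1 && K == 3 && pad == 1 && Ho == H && Wo == W) {
    for (int n = 0; n < N; ++n) {
      conv_s1_fwd(x.begin() + (size_t)H * W * C * n, w.begin(), b.begin(),
                  H, W, C, K, pad, Cout, out.begin() + (size_t)P * Cout * n);
    }
    return out;
  }

  arma::mat B, Wk;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    arma::mat on(out.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    for (int co = 0; co < Cout; ++co) on.col(co).fill(b[co]);
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        gather(xn, H, W, C, Ho, Wo, stride, kh, kw, pad, B);
        w_slice(w.begin(), K, C, Cout, kh, kw, Wk);
        on += B * Wk;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dout,
                    int stride, int pad, bool need_dx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), od = dout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int Ho = od[0], Wo = od[1];
  const int P = Ho * Wo;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  if (stride == 1 && K == 3 && pad == 1 && Ho == H && Wo == W) {
    for (int n = 0; n < N; ++n) {
      conv_s1_bwd(x.begin() + (size_t)H * W * C * n, w.begin(),
                  dout.begin() + (size_t)P * Cout * n,
                  H, W, C, K, pad, Cout,
                  dx.begin() + (size_t)H * W * C * n, dw.begin(), db.begin(),
                  need_dx);
    }
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  }

  arma::mat B, Wk, G, dWk(C, Cout);
  arma::vec dbv(db.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    arma::mat don(const_cast<double*>(dout.begin()) + (size_t)P * Cout * n,
                  P, Cout, false, true);
    dbv += arma::sum(don, 0).t();
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        gather(xn, H, W, C, Ho, Wo, stride, kh, kw, pad, B);
        dWk = B.t() * don; // (C x Cout)
        for (int co = 0; co < Cout; ++co) {
          for (int c = 0; c < C; ++c) {
            dw[kh + K * (kw + K * (c + (size_t)C * co))] += dWk(c, co);
          }
        }
        if (need_dx) {
          w_slice(w.begin(), K, C, Cout, kh, kw, Wk);
          G = don * Wk.t(); // (P x C)
          scatter_add(dxn, H, W, C, Ho, Wo, stride, kh, kw, pad, G);
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// nearest-neighbour 2x upsampling of (H, W, C, N)
// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], CN = xd[2] * xd[3];
  NumericVector out((R_xlen_t)4 * H * W * CN);
  out.attr("dim") = IntegerVector::create(2 * H, 2 * W, xd[2], xd[3]);
  const double* src = x.begin();
  double* dst = out.begin();
  for (int p = 0; p < CN; ++p) {
    const double* xs = src + (size_t)H * W * p;
    double* os = dst + (size_t)4 * H * W * p;
    for (int w = 0; w < W; ++w) {
      const double* col = xs + (size_t)H * w;
      double* o1 = os + (size_t)2 * H * (2 * w);
      double* o2 = o1 + (size_t)2 * H;
      for (int h = 0; h < H; ++h) {
        const double v = col[h];
        o1[2 * h] = v;
        o1[2 * h + 1] = v;
        o2[2 * h] = v;
        o2[2 * h + 1] = v;
      }
    }
  }
  return out;
}

// adjoint of cpp_upsample2: sum each 2x2 block
// [[Rcpp::export]]
NumericVector cpp_downsample2_sum(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H2 = xd[0], W2 = xd[1], CN = xd[2] * xd[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector out((R_xlen_t)H * W * CN);
  out.attr("dim") = IntegerVector::create(H, W, xd[2], xd[3]);
  const double* src = x.begin();
  double* dst = out.begin();
  for (int p = 0; p < CN; ++p) {
    const double* xs = src + (size_t)H2 * W2 * p;
    double* os = dst + (size_t)H * W * p;
    for (int w = 0; w < W; ++w) {
      const double* c1 = xs + (size_t)H2 * (2 * w);
      const double* c2 = c1 + (size_t)H2;
      double* oc = os + (size_t)H * w;
      for (int h = 0; h < H; ++h) {
        oc[h] = c1[2 * h] + c1[2 * h + 1] + c2[2 * h] + c2[2 * h + 1];
      }
    }
  }
  return out;
}
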