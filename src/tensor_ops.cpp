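#include <Rcpp.h>
using namespace Rcpp;

// All tensors are column-major R arrays laid out (H, W, B, C): spatial rows,
// spatial cols, batch, channel. Channel-last keeps the (H*W*B) x C matrix view
// of an activation free of any permutation, so batch-norm and the conv GEMM
// operate on the same memory.

static void get_dims(const NumericVector& x, int& H, int& W, int& B, int& C) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, B, C) array");
  H = d[0]; W = d[1]; B = d[2]; C = d[3];
}

// 3x3 patch extraction with zero padding 1, stride 1.
// Row r = h + H*(w + W*b); column = kh + 3*kw + 9*c holds x[h+kh-1, w+kw-1, b, c].
// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x) {
  int H, W, B, C;
  get_dims(x, H, W, B, C);
  R_xlen_t rows = (R_xlen_t)H * W * B;
  NumericMatrix out(no_init(rows, 9 * C));
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        double* dst0 = po + ((R_xlen_t)(kh + 3 * kw + 9 * c)) * rows;
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            double* dcol = dst0 + (R_xlen_t)H * (w + (R_xlen_t)W * b);
            int ws = w + kw - 1;
            if (ws < 0 || ws >= W) {
              for (int h = 0; h < H; ++h) dcol[h] = 0.0;
              continue;
            }
            const double* scol =
                px + (R_xlen_t)H * (ws + (R_xlen_t)W * (b + (R_xlen_t)B * c));
            for (int h = 0; h < H; ++h) {
              int hs = h + kh - 1;
              dcol[h] = (hs >= 0 && hs < H) ? scol[hs] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im3_cpp(NumericMatrix dP, int H, int W, int B, int C) {
  R_xlen_t n = (R_xlen_t)H * W * B * C;
  NumericVector dx(n);
  double* pdx = dx.begin();
  const double* pp = dP.begin();
  R_xlen_t rows = (R_xlen_t)H * W * B;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const double* src0 = pp + ((R_xlen_t)(kh + 3 * kw + 9 * c)) * rows;
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            int ws = w + kw - 1;
            if (ws < 0 || ws >= W) continue;
            const double* scol = src0 + (R_xlen_t)H * (w + (R_xlen_t)W * b);
            double* dcol =
                pdx + (R_xlen_t)H * (ws + (R_xlen_t)W * (b + (R_xlen_t)B * c));
            for (int h = 0; h < H; ++h) {
              int hs = h + kh - 1;
              if (hs >= 0 && hs < H) dcol[hs] += scol[h];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, B, C);
  return dx;
}

// Non-overlapping max pooling, kernel k = stride k, floor division of the grid.
// Returns the pooled array and 1-based argmax indices into the input (first
// maximum wins, scanned column-major), used by the backward pass.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k) {
  int H, W, B, C;
  get_dims(x, H, W, B, C);
  int Ho = H / k, Wo = W / k;
  if (Ho < 1 || Wo < 1) stop("pooling window larger than the feature map");
  R_xlen_t n_out = (R_xlen_t)Ho * Wo * B * C;
  NumericVector out(no_init(n_out));
  NumericVector idx(no_init(n_out));  // double-backed: indices can exceed 2^31 in principle
  const double* px = x.begin();
  double* po = out.begin();
  double* pi = idx.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      R_xlen_t in_plane = (R_xlen_t)H * (0 + (R_xlen_t)W * (b + (R_xlen_t)B * c));
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          R_xlen_t best_i = 0;
          for (int dw = 0; dw < k; ++dw) {
            int wi = wo * k + dw;
            const double* col = px + in_plane + (R_xlen_t)H * wi;
            for (int dh = 0; dh < k; ++dh) {
              int hi = ho * k + dh;
              double v = col[hi];
              if (v > best) {
                best = v;
                best_i = (R_xlen_t)hi + (R_xlen_t)H * (wi + (R_xlen_t)W * (b + (R_xlen_t)B * c));
              }
            }
          }
          R_xlen_t o = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (b + (R_xlen_t)B * c));
          po[o] = best;
          pi[o] = (double)(best_i + 1);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, NumericVector idx,
                              int H, int W, int B, int C) {
  R_xlen_t n = (R_xlen_t)H * W * B * C;
  NumericVector dx(n);
  double* pdx = dx.begin();
  const double* pd = dout.begin();
  const double* pi = idx.begin();
  R_xlen_t m = dout.size();
  for (R_xlen_t i = 0; i < m; ++i) pdx[(R_xlen_t)pi[i] - 1] += pd[i];
  dx.attr("dim") = IntegerVector::create(H, W, B, C);
  return dx;
}

// Global spatial max per (image, channel): (H, W, B, C) -> B x C matrix.
// [[Rcpp::export]]
List gpool_fwd_cpp(NumericVector x) {
  int H, W, B, C;
  get_dims(x, H, W, B, C);
  NumericMatrix out(B, C);
  NumericVector idx((R_xlen_t)B * C);
  const double* px = x.begin();
  double* po = out.begin();
  double* pi = idx.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const double* plane = px + (R_xlen_t)H * W * (b + (R_xlen_t)B * c);
      double best = R_NegInf;
      R_xlen_t best_i = 0;
      R_xlen_t hw = (R_xlen_t)H * W;
      for (R_xlen_t i = 0; i < hw; ++i) {
        if (plane[i] > best) { best = plane[i]; best_i = i; }
      }
      R_xlen_t o = (R_xlen_t)b + (R_xlen_t)B * c;
      po[o] = best;
      pi[o] = (double)(best_i + (R_xlen_t)H * W * (b + (R_xlen_t)B * c) + 1);
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector gpool_bwd_cpp(NumericMatrix g, NumericVector idx,
                            int H, int W, int B, int C) {
  R_xlen_t n = (R_xlen_t)H * W * B * C;
  NumericVector dx(n);
  double* pdx = dx.begin();
  const double* pg = g.begin();
  const double* pi = idx.begin();
  R_xlen_t m = g.size();
  for (R_xlen_t i = 0; i < m; ++i) pdx[(R_xlen_t)pi[i] - 1] += pg[i];
  dx.attr("dim") = IntegerVector::create(H, W, B, C);
  return dx;
}

// Single-pass per-column mean and (population) variance of an n x C matrix.
// [[Rcpp::export]]
List colstats_cpp(NumericMatrix A) {
  R_xlen_t n = A.nrow();
  int C = A.ncol();
  NumericVector mu(C), v(C);
  for (int c = 0; c < C; ++c) {
    const double* col = &A(0, c);
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < n; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    double m = s / n;
    mu[c] = m;
    double var = s2 / n - m * m;
    v[c] = var > 0 ? var : 0;
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}

// In place: A <- (A - mu[col]) * invstd[col]  (A becomes xhat).
// [[Rcpp::export]]
void bn_xhat_inplace_cpp(NumericMatrix A, NumericVector mu, NumericVector invstd) {
  R_xlen_t n = A.nrow();
  int C = A.ncol();
  for (int c = 0; c < C; ++c) {
    double m = mu[c], s = invstd[c];
    double* col = &A(0, c);
    for (R_xlen_t i = 0; i < n; ++i) col[i] = (col[i] - m) * s;
  }
}

// Z = max(0, gamma[col] * xhat + beta[col]) as a fresh (H, W, B, C) array.
// [[Rcpp::export]]
NumericVector relu_affine_cpp(NumericMatrix xhat, NumericVector gamma,
                              NumericVector beta, IntegerVector out_dim) {
  R_xlen_t n = xhat.nrow();
  int C = xhat.ncol();
  NumericVector Z(no_init((R_xlen_t)n * C));
  double* pz = Z.begin();
  for (int c = 0; c < C; ++c) {
    double g = gamma[c], b = beta[c];
    const double* col = &xhat(0, c);
    double* zcol = pz + (R_xlen_t)n * c;
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = g * col[i] + b;
      zcol[i] = v > 0 ? v : 0;
    }
  }
  Z.attr("dim") = out_dim;
  return Z;
}

// Fused ReLU + batch-norm backward (batch statistics). `g` is the gradient
// arriving at the ReLU output (overwritten in place with the gradient w.r.t.
// the convolution output); xhat is the cached normalized activation.
// Returns dgamma, dbeta.
// [[Rcpp::export]]
List bn_relu_bwd_inplace_cpp(NumericMatrix g, NumericMatrix xhat,
                             NumericVector gamma, NumericVector beta,
                             NumericVector invstd) {
  R_xlen_t n = g.nrow();
  int C = g.ncol();
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double ga = gamma[c], be = beta[c];
    double* gc = &g(0, c);
    const double* xc = &xhat(0, c);
    double sg = 0, sb = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      // ReLU mask: the block output was max(0, gamma*xhat + beta)
      if (ga * xc[i] + be <= 0) gc[i] = 0;
      sg += gc[i] * xc[i];
      sb += gc[i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    double k = ga * invstd[c];
    double mb = sb / n, mg = sg / n;
    for (R_xlen_t i = 0; i < n; ++i)
      gc[i] = k * (gc[i] - mb - xc[i] * mg);
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Eval-mode fused batch-norm + ReLU: Z = max(0, (A - mu)*invstd*gamma + beta),
// fresh array output; A untouched.
// [[Rcpp::export]]
NumericVector bn_relu_eval_cpp(NumericMatrix A, NumericVector mu,
                               NumericVector invstd, NumericVector gamma,
                               NumericVector beta, IntegerVector out_dim) {
  R_xlen_t n = A.nrow();
  int C = A.ncol();
  NumericVector Z(no_init((R_xlen_t)n * C));
  double* pz = Z.begin();
  for (int c = 0; c < C; ++c) {
    double sc = invstd[c] * gamma[c];
    double sh = beta[c] - mu[c] * sc;
    const double* col = &A(0, c);
    double* zcol = pz + (R_xlen_t)n * c;
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = col[i] * sc + sh;
      zcol[i] = v > 0 ? v : 0;
    }
  }
  Z.attr("dim") = out_dim;
  return Z;
}
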