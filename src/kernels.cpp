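#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Feature maps are R arrays with dim (N, C, H, W), column-major, so the
// linear index of (n, c, h, w) (0-based) is n + N*(c + C*(h + H*w)).
//
// im2col lowers a batched convolution to one matrix product:
//   rows    r = (c*K + kh)*K + kw           (c slowest)
//   columns j = n + N*(ho + Ho*wo)          (n fastest)
// so that reshaping W %*% cols to dim (Cout, N, Ho, Wo) and transposing the
// first two axes yields the output feature map.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int N, int C, int H, int W,
                         int K, int pad, int stride, int dilation) {
  const int Ho = (H + 2 * pad - dilation * (K - 1) - 1) / stride + 1;
  const int Wo = (W + 2 * pad - dilation * (K - 1) - 1) / stride + 1;
  NumericMatrix cols(C * K * K, (R_xlen_t)N * Ho * Wo);
  const double *px = x.begin();
  double *pc = cols.begin();
  const int nrow = C * K * K;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int n = 0; n < N; ++n) {
        R_xlen_t j = (R_xlen_t)n + (R_xlen_t)N * (ho + (R_xlen_t)Ho * wo);
        double *col = pc + j * nrow;
        for (int c = 0; c < C; ++c) {
          for (int kh = 0; kh < K; ++kh) {
            const int h = ho * stride - pad + kh * dilation;
            for (int kw = 0; kw < K; ++kw) {
              const int w = wo * stride - pad + kw * dilation;
              const int r = (c * K + kh) * K + kw;
              col[r] = (h >= 0 && h < H && w >= 0 && w < W)
                ? px[n + (R_xlen_t)N * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w))]
                : 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int N, int C, int H, int W,
                         int K, int pad, int stride, int dilation) {
  const int Ho = (H + 2 * pad - dilation * (K - 1) - 1) / stride + 1;
  const int Wo = (W + 2 * pad - dilation * (K - 1) - 1) / stride + 1;
  NumericVector x((R_xlen_t)N * C * H * W);
  double *px = x.begin();
  const double *pc = cols.begin();
  const int nrow = C * K * K;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int n = 0; n < N; ++n) {
        R_xlen_t j = (R_xlen_t)n + (R_xlen_t)N * (ho + (R_xlen_t)Ho * wo);
        const double *col = pc + j * nrow;
        for (int c = 0; c < C; ++c) {
          for (int kh = 0; kh < K; ++kh) {
            const int h = ho * stride - pad + kh * dilation;
            if (h < 0 || h >= H) continue;
            for (int kw = 0; kw < K; ++kw) {
              const int w = wo * stride - pad + kw * dilation;
              if (w < 0 || w >= W) continue;
              const int r = (c * K + kh) * K + kw;
              px[n + (R_xlen_t)N * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w))] += col[r];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(N, C, H, W);
  return x;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher):
// for every pixel, squared distance to the nearest nonzero pixel of `mask`.
// Pixels are taken at integer grid coordinates; distances are exact, which is
// what lets the fast Hausdorff path agree with the brute-force definition.

static void dt1d(const double *f, double *d, int n, int *v, double *z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DBL_MAX;
  z[1] = DBL_MAX;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DBL_MAX;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix d(H, W);
  const double INF = 1e20;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      d(i, j) = mask(i, j) != 0 ? 0.0 : INF;
  const int m = H > W ? H : W;
  std::vector<double> f(m), out(m), z(m + 1);
  std::vector<int> v(m);
  // columns
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = d(i, j);
    dt1d(f.data(), out.data(), H, v.data(), z.data());
    for (int i = 0; i < H; ++i) d(i, j) = out[i];
  }
  // rows
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = d(i, j);
    dt1d(f.data(), out.data(), W, v.data(), z.data());
    for (int j = 0; j < W; ++j) d(i, j) = out[j];
  }
  return d;
}
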