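#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Tensor layout throughout: R array dim = c(D, W, H, C), column-major, so the
// linear index of (d, w, h, c) (0-based) is d + D*(w + W*(h + H*c)).
// Patch-matrix layout: row r = od + Do*(ow + Wo*oh) over output positions,
// column q = kd + K*(kw + K*(kh + K*cin)) over kernel offsets and input
// channels.  This matches flattening a weight array dim c(K,K,K,Cin,Cout)
// into a (K^3*Cin x Cout) matrix with dim<-, so convolution is col %*% W.

static inline int outExtent(int L, int K, int stride, int pad) {
  return (L + 2 * pad - K) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_vol2col(NumericVector x, IntegerVector dims, int K,
                          IntegerVector stride, int pad) {
  const int D = dims[0], W = dims[1], H = dims[2], C = dims[3];
  const int sd = stride[0], sw = stride[1], sh = stride[2];
  const int Do = outExtent(D, K, sd, pad);
  const int Wo = outExtent(W, K, sw, pad);
  const int Ho = outExtent(H, K, sh, pad);
  const int N = Do * Wo * Ho;
  NumericMatrix col(N, K * K * K * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)D * W * H * c;
    for (int kh = 0; kh < K; ++kh)
      for (int kw = 0; kw < K; ++kw)
        for (int kd = 0; kd < K; ++kd) {
          const int q = kd + K * (kw + K * (kh + K * c));
          double* colq = &col(0, q);
          for (int oh = 0; oh < Ho; ++oh) {
            const int h = oh * sh - pad + kh;
            if (h < 0 || h >= H) continue;
            for (int ow = 0; ow < Wo; ++ow) {
              const int w = ow * sw - pad + kw;
              if (w < 0 || w >= W) continue;
              for (int od = 0; od < Do; ++od) {
                const int d = od * sd - pad + kd;
                if (d < 0 || d >= D) continue;
                colq[od + Do * (ow + Wo * oh)] =
                    xc[d + D * (w + W * h)];
              }
            }
          }
        }
  }
  return col;
}

// Adjoint of cpp_vol2col: scatter-add a patch matrix back into a volume of
// the stated dims.  Used for conv input-gradients and for transposed
// convolution forward passes.
// [[Rcpp::export]]
NumericVector cpp_col2vol(NumericMatrix col, IntegerVector dims, int K,
                          IntegerVector stride, int pad) {
  const int D = dims[0], W = dims[1], H = dims[2], C = dims[3];
  const int sd = stride[0], sw = stride[1], sh = stride[2];
  const int Do = outExtent(D, K, sd, pad);
  const int Wo = outExtent(W, K, sw, pad);
  const int Ho = outExtent(H, K, sh, pad);
  NumericVector x((size_t)D * W * H * C);
  double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)D * W * H * c;
    for (int kh = 0; kh < K; ++kh)
      for (int kw = 0; kw < K; ++kw)
        for (int kd = 0; kd < K; ++kd) {
          const int q = kd + K * (kw + K * (kh + K * c));
          const double* colq = &col(0, q);
          for (int oh = 0; oh < Ho; ++oh) {
            const int h = oh * sh - pad + kh;
            if (h < 0 || h >= H) continue;
            for (int ow = 0; ow < Wo; ++ow) {
              const int w = ow * sw - pad + kw;
              if (w < 0 || w >= W) continue;
              for (int od = 0; od < Do; ++od) {
                const int d = od * sd - pad + kd;
                if (d < 0 || d >= D) continue;
                xc[d + D * (w + W * h)] +=
                    colq[od + Do * (ow + Wo * oh)];
              }
            }
          }
        }
  }
  x.attr("dim") = IntegerVector::create(D, W, H, C);
  return x;
}

// ---- Euclidean distance transform ------------------------------------------
// Felzenszwalb & Huttenlocher lower-envelope transform, applied separably per
// axis with anisotropic voxel spacing; returns, for every voxel, the squared
// Euclidean distance (in physical units) to the nearest seed (TRUE) voxel.

static void dt1d(std::vector<double>& f, double w, std::vector<double>& out,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<int>& idx) {
  const int n = (int)f.size();
  const double w2 = w * w;
  const double INF = std::numeric_limits<double>::infinity();
  idx.clear();
  for (int q = 0; q < n; ++q)
    if (f[q] != INF) idx.push_back(q);
  if (idx.empty()) {
    std::fill(out.begin(), out.begin() + n, INF);
    return;
  }
  // lower envelope over the finite parabolas only
  int k = 0;
  v[0] = idx[0];
  z[0] = -INF;
  z[1] = INF;
  for (size_t t = 1; t < idx.size(); ++t) {
    const int q = idx[t];
    double s;
    for (;;) {
      const int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
          (2.0 * w2 * (q - p));
      if (s <= z[k]) --k; else break; // z[0] = -Inf keeps k >= 0
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    const double dq = w * (q - v[k]);
    out[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int D = dims[0], W = dims[1], H = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector g((size_t)D * W * H);
  for (size_t i = 0; i < g.size(); ++i)
    g[i] = mask[i] ? 0.0 : INF;
  const int maxn = std::max(D, std::max(W, H));
  std::vector<double> f(maxn), out(maxn), z(maxn + 1);
  std::vector<int> v(maxn), idx;
  idx.reserve(maxn);

  // axis 1 (d), spacing[0]
  for (int h = 0; h < H; ++h)
    for (int w = 0; w < W; ++w) {
      double* line = &g[0] + D * (w + (size_t)W * h);
      f.assign(line, line + D);
      dt1d(f, spacing[0], out, v, z, idx);
      std::copy(out.begin(), out.begin() + D, line);
    }
  // axis 2 (w), spacing[1]
  for (int h = 0; h < H; ++h)
    for (int d = 0; d < D; ++d) {
      f.resize(W);
      for (int w = 0; w < W; ++w) f[w] = g[d + D * (w + (size_t)W * h)];
      dt1d(f, spacing[1], out, v, z, idx);
      for (int w = 0; w < W; ++w) g[d + D * (w + (size_t)W * h)] = out[w];
    }
  // axis 3 (h), spacing[2]
  for (int w = 0; w < W; ++w)
    for (int d = 0; d < D; ++d) {
      f.resize(H);
      for (int h = 0; h < H; ++h) f[h] = g[d + D * (w + (size_t)W * h)];
      dt1d(f, spacing[2], out, v, z, idx);
      for (int h = 0; h < H; ++h) g[d + D * (w + (size_t)W * h)] = out[h];
    }
  g.attr("dim") = IntegerVector::create(D, W, H);
  return g;
}

// Surface voxels of a binary mask under 6-connectivity: a mask voxel with at
// least one face-neighbour that is background (out-of-bounds counts as
// background).
// [[Rcpp::export]]
LogicalVector cpp_surface(LogicalVector mask, IntegerVector dims) {
  const int D = dims[0], W = dims[1], H = dims[2];
  LogicalVector s((size_t)D * W * H);
  for (int h = 0; h < H; ++h)
    for (int w = 0; w < W; ++w)
      for (int d = 0; d < D; ++d) {
        const size_t i = d + (size_t)D * (w + (size_t)W * h);
        if (!mask[i]) continue;
        bool surf = false;
        if (d == 0 || !mask[i - 1]) surf = true;
        else if (d == D - 1 || !mask[i + 1]) surf = true;
        else if (w == 0 || !mask[i - D]) surf = true;
        else if (w == W - 1 || !mask[i + D]) surf = true;
        else if (h == 0 || !mask[i - (size_t)D * W]) surf = true;
        else if (h == H - 1 || !mask[i + (size_t)D * W]) surf = true;
        s[i] = surf;
      }
  s.attr("dim") = IntegerVector::create(D, W, H);
  return s;
}
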