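// Exact Euclidean distance transform for 3D binary masks, computed by the
// separable lower-envelope-of-parabolas algorithm (Felzenszwalb & Huttenlocher)
// applied along each axis with anisotropic voxel spacing. Returns, for every
// voxel, the squared Euclidean distance to the nearest feature (TRUE) voxel;
// +Inf if the mask has no feature voxel.

#include <Rcpp.h>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of sampled function f at spacing s. Only
// finite parabolas enter the lower envelope; an all-infinite row stays
// infinite.
static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  const double s2 = s * s;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double sint;
    for (;;) {
      sint = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
             (2.0 * s2 * (q - v[k]));
      if (sint <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dims,
                              NumericVector spacing) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const size_t nv = (size_t)D * H * W;
  NumericVector out(nv);
  for (size_t i = 0; i < nv; ++i) out[i] = mask[i] ? 0.0 : INF;

  const int nmax = std::max(D, std::max(H, W));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (d, fastest)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double* col = out.begin() + (size_t)D * (h + (size_t)H * w);
      for (int i = 0; i < D; ++i) f[i] = col[i];
      dt1d(f.data(), d.data(), D, spacing[0], v, z);
      for (int i = 0; i < D; ++i) col[i] = d[i];
    }
  // axis 2 (h)
  for (int w = 0; w < W; ++w)
    for (int dd = 0; dd < D; ++dd) {
      double* base = out.begin() + dd + (size_t)D * H * w;
      for (int i = 0; i < H; ++i) f[i] = base[(size_t)D * i];
      dt1d(f.data(), d.data(), H, spacing[1], v, z);
      for (int i = 0; i < H; ++i) base[(size_t)D * i] = d[i];
    }
  // axis 3 (w)
  for (int h = 0; h < H; ++h)
    for (int dd = 0; dd < D; ++dd) {
      double* base = out.begin() + dd + (size_t)D * h;
      for (int i = 0; i < W; ++i) f[i] = base[(size_t)D * H * i];
      dt1d(f.data(), d.data(), W, spacing[2], v, z);
      for (int i = 0; i < W; ++i) base[(size_t)D * H * i] = d[i];
    }
  out.attr("dim") = dims;
  return out;
}
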