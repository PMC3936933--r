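#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact 3-D Euclidean distance transform, Felzenszwalb-Huttenlocher
// separable lower-envelope algorithm on squared distances, with
// propagation of the nearest feature voxel (so labels such as atom
// indices can ride along). Distances are in voxel units.

static const double DINF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform along one scanline.
// f: squared distance so far (DINF where no site reachable), src: source id.
static void dt1d(const std::vector<double>& f, const std::vector<int>& src,
                 std::vector<double>& d, std::vector<int>& dsrc, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == DINF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -DINF; z[1] = DINF;
      continue;
    }
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -DINF; z[1] = DINF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = DINF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) { d[q] = DINF; dsrc[q] = NA_INTEGER; }
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < (double)q) ++j;
    double dq = (double)q - (double)v[j];
    d[q] = dq * dq + f[v[j]];
    dsrc[q] = src[v[j]];
  }
}

// [[Rcpp::export]]
List edt_cpp(LogicalVector feature, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (feature.size() != nvox) stop("feature mask does not match dims");

  std::vector<double> d2(nvox);
  std::vector<int> src(nvox);
  bool any_feature = false;
  for (R_xlen_t i = 0; i < nvox; ++i) {
    if (feature[i]) {
      d2[i] = 0.0; src[i] = (int)(i + 1);  // 1-based linear index of the site
      any_feature = true;
    } else {
      d2[i] = DINF; src[i] = NA_INTEGER;
    }
  }
  if (!any_feature) stop("mask has no feature voxels");

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dline(nmax), z(nmax + 1);
  std::vector<int> fs(nmax), dsrc(nmax), v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) { f[i] = d2[base + i]; fs[i] = src[base + i]; }
      dt1d(f, fs, dline, dsrc, nx, v, z);
      for (int i = 0; i < nx; ++i) { d2[base + i] = dline[i]; src[base + i] = dsrc[i]; }
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) { f[j] = d2[base + (R_xlen_t)nx * j]; fs[j] = src[base + (R_xlen_t)nx * j]; }
      dt1d(f, fs, dline, dsrc, ny, v, z);
      for (int j = 0; j < ny; ++j) { d2[base + (R_xlen_t)nx * j] = dline[j]; src[base + (R_xlen_t)nx * j] = dsrc[j]; }
    }
  // pass along z
  const R_xlen_t stz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) { f[k] = d2[base + stz * k]; fs[k] = src[base + stz * k]; }
      dt1d(f, fs, dline, dsrc, nz, v, z);
      for (int k = 0; k < nz; ++k) { d2[base + stz * k] = dline[k]; src[base + stz * k] = dsrc[k]; }
    }

  NumericVector dist(nvox);
  IntegerVector nearest(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) {
    dist[i] = std::sqrt(d2[i]);
    nearest[i] = src[i];
  }
  return List::create(_["dist"] = dist, _["nearest"] = nearest);
}
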