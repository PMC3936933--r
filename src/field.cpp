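#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum signed distance to a set of spheres, evaluated at every voxel
// center: value(v) = min_a ( ||v - c_a|| - R_a ). Atoms are visited in
// order with a strict '<' update, so the lowest atom index wins ties.
// O(n_voxels * n_atoms); grid dimensions are capped upstream.

// [[Rcpp::export]]
List min_signed_field_cpp(NumericMatrix xyz, NumericVector radius,
                          NumericVector origin, double spacing,
                          IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int natoms = xyz.nrow();
  if (radius.size() != natoms) stop("radius length must match atom count");

  NumericVector values(nvox, R_PosInf);
  IntegerVector nearest(nvox, NA_INTEGER);

  std::vector<double> dx2(nx), dy2(ny), dz2(nz);
  for (int a = 0; a < natoms; ++a) {
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2), R = radius[a];
    for (int i = 0; i < nx; ++i) { double t = origin[0] + i * spacing - ax; dx2[i] = t * t; }
    for (int j = 0; j < ny; ++j) { double t = origin[1] + j * spacing - ay; dy2[j] = t * t; }
    for (int k = 0; k < nz; ++k) { double t = origin[2] + k * spacing - az; dz2[k] = t * t; }
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        const double dyz = dy2[j] + dz2[k];
        for (int i = 0; i < nx; ++i, ++idx) {
          const double d = std::sqrt(dx2[i] + dyz) - R;
          if (d < values[idx]) { values[idx] = d; nearest[idx] = a + 1; }
        }
      }
    }
  }
  return List::create(_["values"] = values, _["nearest"] = nearest);
}
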