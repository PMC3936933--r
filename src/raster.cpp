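#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Deterministic z-buffer software rasterizer primitives. Images are R
// arrays with dim c(height, width, 3) in [0,1]; the z-buffer is a
// height x width matrix of depths in [0,1] (smaller = nearer). Screen
// vertices arrive pre-projected: x_px, y_px (y down), depth.

static inline R_xlen_t pix(int y, int x, int c, int h, int w) {
  return (R_xlen_t)y + (R_xlen_t)h * x + (R_xlen_t)h * w * c;
}

// [[Rcpp::export]]
void fill_triangles_cpp(NumericVector img, NumericMatrix zbuf,
                        NumericMatrix sv,      // n x 3: x_px, y_px, depth
                        NumericMatrix col,     // n x 3 shaded rgb
                        IntegerMatrix tri,     // m x 3, 1-based
                        double alpha, bool write_z) {
  const int h = zbuf.nrow(), w = zbuf.ncol();
  for (int t = 0; t < tri.nrow(); ++t) {
    const int a = tri(t, 0) - 1, b = tri(t, 1) - 1, c = tri(t, 2) - 1;
    const double x0 = sv(a, 0), y0 = sv(a, 1), z0 = sv(a, 2);
    const double x1 = sv(b, 0), y1 = sv(b, 1), z1 = sv(b, 2);
    const double x2 = sv(c, 0), y2 = sv(c, 1), z2 = sv(c, 2);
    if (!R_finite(x0) || !R_finite(x1) || !R_finite(x2) ||
        !R_finite(y0) || !R_finite(y1) || !R_finite(y2)) continue;
    const double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (area == 0.0) continue;
    int xmin = std::max(0, (int)std::floor(std::min({x0, x1, x2})));
    int xmax = std::min(w - 1, (int)std::ceil(std::max({x0, x1, x2})));
    int ymin = std::max(0, (int)std::floor(std::min({y0, y1, y2})));
    int ymax = std::min(h - 1, (int)std::ceil(std::max({y0, y1, y2})));
    for (int py = ymin; py <= ymax; ++py) {
      const double yc = py + 0.5;
      for (int px = xmin; px <= xmax; ++px) {
        const double xc = px + 0.5;
        double w0 = ((x1 - xc) * (y2 - yc) - (x2 - xc) * (y1 - yc)) / area;
        double w1 = ((x2 - xc) * (y0 - yc) - (x0 - xc) * (y2 - yc)) / area;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0.0 || w1 < 0.0 || w2 < 0.0) continue;
        const double depth = w0 * z0 + w1 * z1 + w2 * z2;
        if (depth < 0.0 || depth > 1.0) continue;
        if (depth >= zbuf(py, px)) continue;
        for (int ch = 0; ch < 3; ++ch) {
          const double cc = w0 * col(a, ch) + w1 * col(b, ch) + w2 * col(c, ch);
          const R_xlen_t id = pix(py, px, ch, h, w);
          img[id] = alpha * cc + (1.0 - alpha) * img[id];
        }
        if (write_z) zbuf(py, px) = depth;
      }
    }
  }
}

// [[Rcpp::export]]
void draw_lines_cpp(NumericVector img, NumericMatrix zbuf,
                    NumericMatrix sv, NumericMatrix col,
                    IntegerMatrix seg) {   // m x 2, 1-based
  const int h = zbuf.nrow(), w = zbuf.ncol();
  for (int s = 0; s < seg.nrow(); ++s) {
    const int a = seg(s, 0) - 1, b = seg(s, 1) - 1;
    double x0 = sv(a, 0), y0 = sv(a, 1), z0 = sv(a, 2);
    double x1 = sv(b, 0), y1 = sv(b, 1), z1 = sv(b, 2);
    if (!R_finite(x0) || !R_finite(x1) || !R_finite(y0) || !R_finite(y1)) continue;
    const double dx = x1 - x0, dy = y1 - y0;
    const int n = (int)std::ceil(std::max(std::fabs(dx), std::fabs(dy))) + 1;
    for (int i = 0; i < n; ++i) {
      const double t = n == 1 ? 0.0 : (double)i / (n - 1);
      const int px = (int)std::floor(x0 + t * dx);
      const int py = (int)std::floor(y0 + t * dy);
      if (px < 0 || px >= w || py < 0 || py >= h) continue;
      const double depth = z0 + t * (z1 - z0);
      if (depth < 0.0 || depth > 1.0 || depth >= zbuf(py, px)) continue;
      for (int ch = 0; ch < 3; ++ch)
        img[pix(py, px, ch, h, w)] = col(a, ch) + t * (col(b, ch) - col(a, ch));
      zbuf(py, px) = depth;
    }
  }
}

// [[Rcpp::export]]
void draw_points_cpp(NumericVector img, NumericMatrix zbuf,
                     NumericMatrix sv, NumericMatrix col,
                     IntegerVector idx) {  // 1-based vertex indices
  const int h = zbuf.nrow(), w = zbuf.ncol();
  for (int s = 0; s < idx.size(); ++s) {
    const int a = idx[s] - 1;
    if (!R_finite(sv(a, 0)) || !R_finite(sv(a, 1))) continue;
    const int px = (int)std::floor(sv(a, 0));
    const int py = (int)std::floor(sv(a, 1));
    if (px < 0 || px >= w || py < 0 || py >= h) continue;
    const double depth = sv(a, 2);
    if (depth < 0.0 || depth > 1.0 || depth >= zbuf(py, px)) continue;
    for (int ch = 0; ch < 3; ++ch)
      img[pix(py, px, ch, h, w)] = col(a, ch);
    zbuf(py, px) = depth;
  }
}
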