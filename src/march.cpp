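#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on the Kuhn 6-tetrahedra
// decomposition of each grid cell. The split is translation-consistent
// (shared cell faces carry the same diagonal on both sides), so the
// triangulation is crack-free and, for level sets strictly inside the
// grid, watertight. Surface vertices are linearly interpolated along
// cell edges / face diagonals / the body diagonal; normals come from
// central-difference gradients of the field; each vertex inherits the
// nearest-atom label of the edge endpoint with the smaller |value-iso|.
//
// Cube corner c in 0..7 encodes offsets: x = bit0, y = bit1, z = bit2.
// The six tetrahedra are the monotone bit-paths 0 -> a -> b -> 7.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

struct MeshAcc {
  std::vector<double> vx, vy, vz, nxv, nyv, nzv;
  std::vector<int> vatom;
  std::vector<int> tri;  // flat triples, 0-based
  std::unordered_map<uint64_t, int> edge_vertex;
};

class Marcher {
public:
  const double* val;
  const int* near_atom;   // may be null
  bool has_near;
  int nx, ny, nz;
  double ox, oy, oz, h, iso;
  MeshAcc m;

  inline R_xlen_t lin(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  }
  // nudge exact hits so every crossing is a proper interior point
  inline double v_at(R_xlen_t id) const {
    double v = val[id] - iso;
    if (v == 0.0) v = 1e-9;
    return v;
  }
  inline void pos_of(R_xlen_t id, double* p) const {
    int i = (int)(id % nx);
    int j = (int)((id / nx) % ny);
    int k = (int)(id / ((R_xlen_t)nx * ny));
    p[0] = ox + i * h; p[1] = oy + j * h; p[2] = oz + k * h;
  }
  inline void grad_at(R_xlen_t id, double* g) const {
    int i = (int)(id % nx);
    int j = (int)((id / nx) % ny);
    int k = (int)(id / ((R_xlen_t)nx * ny));
    int i0 = i > 0 ? i - 1 : i, i1 = i < nx - 1 ? i + 1 : i;
    int j0 = j > 0 ? j - 1 : j, j1 = j < ny - 1 ? j + 1 : j;
    int k0 = k > 0 ? k - 1 : k, k1 = k < nz - 1 ? k + 1 : k;
    g[0] = (val[lin(i1, j, k)] - val[lin(i0, j, k)]) / ((i1 - i0) * h);
    g[1] = (val[lin(i, j1, k)] - val[lin(i, j0, k)]) / ((j1 - j0) * h);
    g[2] = (val[lin(i, j, k1)] - val[lin(i, j, k0)]) / ((k1 - k0) * h);
  }

  // vertex on the segment between grid vertices a (inside) and b (outside)
  int edge_vert(R_xlen_t a, R_xlen_t b) {
    R_xlen_t lo = a < b ? a : b, hi = a < b ? b : a;
    uint64_t key = (uint64_t)lo * (uint64_t)((R_xlen_t)nx * ny * nz) + (uint64_t)hi;
    auto it = m.edge_vertex.find(key);
    if (it != m.edge_vertex.end()) return it->second;

    double va = v_at(lo), vb = v_at(hi);
    double t = va / (va - vb);  // crossing of the 0 level between lo and hi
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    double pa[3], pb[3], ga[3], gb[3];
    pos_of(lo, pa); pos_of(hi, pb);
    grad_at(lo, ga); grad_at(hi, gb);
    double p[3], g[3];
    for (int c = 0; c < 3; ++c) {
      p[c] = pa[c] + t * (pb[c] - pa[c]);
      g[c] = ga[c] + t * (gb[c] - ga[c]);
    }
    double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
    if (gn < 1e-12) { g[0] = 0; g[1] = 0; g[2] = 1; gn = 1; }
    int atom = NA_INTEGER;
    if (has_near) atom = std::fabs(va) <= std::fabs(vb) ? near_atom[lo] : near_atom[hi];

    int id = (int)m.vx.size();
    m.vx.push_back(p[0]); m.vy.push_back(p[1]); m.vz.push_back(p[2]);
    m.nxv.push_back(g[0] / gn); m.nyv.push_back(g[1] / gn); m.nzv.push_back(g[2] / gn);
    m.vatom.push_back(atom);
    m.edge_vertex.emplace(key, id);
    return id;
  }

  inline void vpos(int id, double* p) const {
    p[0] = m.vx[id]; p[1] = m.vy[id]; p[2] = m.vz[id];
  }

  // emit triangle (i0,i1,i2) oriented so its normal has positive dot with dir
  void emit(int i0, int i1, int i2, const double* dir) {
    double p0[3], p1[3], p2[3];
    vpos(i0, p0); vpos(i1, p1); vpos(i2, p2);
    double u[3], w[3], n[3];
    for (int c = 0; c < 3; ++c) { u[c] = p1[c] - p0[c]; w[c] = p2[c] - p0[c]; }
    n[0] = u[1] * w[2] - u[2] * w[1];
    n[1] = u[2] * w[0] - u[0] * w[2];
    n[2] = u[0] * w[1] - u[1] * w[0];
    double area2 = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    if (area2 == 0.0) return;  // exactly degenerate; slivers are welded later
    double dp = n[0] * dir[0] + n[1] * dir[1] + n[2] * dir[2];
    if (dp < 0.0) { int tmp = i1; i1 = i2; i2 = tmp; }
    m.tri.push_back(i0); m.tri.push_back(i1); m.tri.push_back(i2);
  }

  void do_tet(const R_xlen_t* corner) {
    double v[4];
    bool in[4];
    int nin = 0;
    for (int t = 0; t < 4; ++t) {
      v[t] = v_at(corner[t]);
      in[t] = v[t] < 0.0;  // solid convention: field < iso is inside
      if (in[t]) ++nin;
    }
    if (nin == 0 || nin == 4) return;

    int ins[4], outs[4];
    int a = 0, b = 0;
    for (int t = 0; t < 4; ++t) { if (in[t]) ins[a++] = t; else outs[b++] = t; }

    if (nin == 1) {
      // one triangle, normal pointing away from the inside vertex
      int p0 = edge_vert(corner[ins[0]], corner[outs[0]]);
      int p1 = edge_vert(corner[ins[0]], corner[outs[1]]);
      int p2 = edge_vert(corner[ins[0]], corner[outs[2]]);
      double A[3], cen[3], d0[3], d1[3], d2[3], dir[3];
      pos_of(corner[ins[0]], A);
      vpos(p0, d0); vpos(p1, d1); vpos(p2, d2);
      for (int c = 0; c < 3; ++c) {
        cen[c] = (d0[c] + d1[c] + d2[c]) / 3.0;
        dir[c] = cen[c] - A[c];
      }
      emit(p0, p1, p2, dir);
    } else if (nin == 3) {
      // one triangle, normal pointing toward the single outside vertex
      int p0 = edge_vert(corner[ins[0]], corner[outs[0]]);
      int p1 = edge_vert(corner[ins[1]], corner[outs[0]]);
      int p2 = edge_vert(corner[ins[2]], corner[outs[0]]);
      double D[3], cen[3], d0[3], d1[3], d2[3], dir[3];
      pos_of(corner[outs[0]], D);
      vpos(p0, d0); vpos(p1, d1); vpos(p2, d2);
      for (int c = 0; c < 3; ++c) {
        cen[c] = (d0[c] + d1[c] + d2[c]) / 3.0;
        dir[c] = D[c] - cen[c];
      }
      emit(p0, p1, p2, dir);
    } else {
      // quad cycle e00 - e01 - e11 - e10 split into two triangles
      int e00 = edge_vert(corner[ins[0]], corner[outs[0]]);
      int e01 = edge_vert(corner[ins[0]], corner[outs[1]]);
      int e10 = edge_vert(corner[ins[1]], corner[outs[0]]);
      int e11 = edge_vert(corner[ins[1]], corner[outs[1]]);
      double A0[3], A1[3], B0[3], B1[3], dir[3];
      pos_of(corner[ins[0]], A0); pos_of(corner[ins[1]], A1);
      pos_of(corner[outs[0]], B0); pos_of(corner[outs[1]], B1);
      for (int c = 0; c < 3; ++c)
        dir[c] = (B0[c] + B1[c] - A0[c] - A1[c]) * 0.5;
      emit(e00, e01, e11, dir);
      emit(e00, e11, e10, dir);
    }
  }

  void run() {
    R_xlen_t corner[8];
    for (int k = 0; k + 1 < nz; ++k)
      for (int j = 0; j + 1 < ny; ++j)
        for (int i = 0; i + 1 < nx; ++i) {
          for (int c = 0; c < 8; ++c)
            corner[c] = lin(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          R_xlen_t tc[4];
          for (int t = 0; t < 6; ++t) {
            for (int q = 0; q < 4; ++q) tc[q] = corner[TETS[t][q]];
            do_tet(tc);
          }
        }
  }
};

// [[Rcpp::export]]
List march_tets_cpp(NumericVector values, IntegerVector dims,
                    NumericVector origin, double spacing, double isovalue,
                    IntegerVector nearest) {
  Marcher mc;
  mc.val = REAL(values);
  mc.has_near = nearest.size() == values.size();
  mc.near_atom = mc.has_near ? INTEGER(nearest) : (const int*)nullptr;
  mc.nx = dims[0]; mc.ny = dims[1]; mc.nz = dims[2];
  if ((R_xlen_t)mc.nx * mc.ny * mc.nz != values.size())
    stop("values length does not match dims");
  mc.ox = origin[0]; mc.oy = origin[1]; mc.oz = origin[2];
  mc.h = spacing; mc.iso = isovalue;
  mc.run();

  const int nv = (int)mc.m.vx.size();
  const int nt = (int)(mc.m.tri.size() / 3);
  NumericMatrix V(nv, 3), N(nv, 3);
  IntegerVector atom(nv);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = mc.m.vx[i]; V(i, 1) = mc.m.vy[i]; V(i, 2) = mc.m.vz[i];
    N(i, 0) = mc.m.nxv[i]; N(i, 1) = mc.m.nyv[i]; N(i, 2) = mc.m.nzv[i];
    atom[i] = mc.m.vatom[i];
  }
  IntegerMatrix T(nt, 3);
  for (int t = 0; t < nt; ++t) {
    T(t, 0) = mc.m.tri[3 * t] + 1;
    T(t, 1) = mc.m.tri[3 * t + 1] + 1;
    T(t, 2) = mc.m.tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["normals"] = N,
                      _["triangles"] = T, _["vertex_atom"] = atom);
}
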