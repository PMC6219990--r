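#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), separable,
// with anisotropic voxel spacing.  Returns squared distance in mm^2 from every
// voxel to the nearest "on" voxel.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -HUGE_VAL;
  z[1] = HUGE_VAL;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = HUGE_VAL;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // large finite sentinel: +/-Inf breaks the lower-envelope intersection math
  const double BIG = 1e15;
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (mask[i] == TRUE) ? 0.0 : BIG;

  std::vector<double> f, d;
  // x axis
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // y axis
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // z axis
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
      dt1d(f, d, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra iso-surface extraction.  Each lattice cube is split into
// six tetrahedra sharing the main diagonal; crossing vertices are welded on
// shared lattice edges, so the resulting surface is watertight wherever the
// iso-surface does not touch the volume border.  Vertices are emitted in
// continuous 0-based index coordinates; triangle winding is fixed so normals
// point toward increasing field values.
// ---------------------------------------------------------------------------

struct MTState {
  std::unordered_map<uint64_t, int> edge_map;
  std::vector<double> verts;   // x,y,z triples
  std::vector<int> tris;       // 0-based triples
};

static int mt_edge_vertex(MTState& st, uint64_t ga, uint64_t gb,
                          const double* pa, const double* pb,
                          double va, double vb, double iso) {
  uint64_t lo = ga, hi = gb;
  const double *plo = pa, *phi = pb;
  double vlo = va, vhi = vb;
  if (lo > hi) {
    std::swap(lo, hi); std::swap(plo, phi); std::swap(vlo, vhi);
  }
  uint64_t key = (lo << 32) | hi;
  auto it = st.edge_map.find(key);
  if (it != st.edge_map.end()) return it->second;
  double t = (iso - vlo) / (vhi - vlo);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  int id = (int)(st.verts.size() / 3);
  for (int c = 0; c < 3; ++c)
    st.verts.push_back(plo[c] + t * (phi[c] - plo[c]));
  st.edge_map[key] = id;
  return id;
}

static void mt_emit(MTState& st, int a, int b, int c, bool flip) {
  st.tris.push_back(a);
  if (flip) { st.tris.push_back(c); st.tris.push_back(b); }
  else      { st.tris.push_back(b); st.tris.push_back(c); }
}

// exact orientation of a lattice tetrahedron: sign of det(B-A, C-A, D-A)
static double mt_orient(const double* A, const double* B, const double* C,
                        const double* D) {
  double u[3], v[3], w[3];
  for (int i = 0; i < 3; ++i) {
    u[i] = B[i] - A[i]; v[i] = C[i] - A[i]; w[i] = D[i] - A[i];
  }
  return u[0] * (v[1] * w[2] - v[2] * w[1]) -
         u[1] * (v[0] * w[2] - v[2] * w[0]) +
         u[2] * (v[0] * w[1] - v[1] * w[0]);
}

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dim, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  // snap values lying exactly on the iso level to avoid degenerate triangles
  std::vector<double> F(field.begin(), field.end());
  double eps = 1e-9;
  for (auto& v : F) if (v == iso) v = iso + eps;

  // tets sharing the 0-6 diagonal of each cube (corner bit order: x,y,z)
  static const int corner_off[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

  MTState st;
  R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double cv[8];
        uint64_t gid[8];
        double cp[8][3];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + corner_off[c][0];
          int cj = j + corner_off[c][1];
          int ck = k + corner_off[c][2];
          R_xlen_t lin = ci * sx + cj * sy + ck * sz;
          cv[c] = F[lin];
          gid[c] = (uint64_t)lin;
          cp[c][0] = ci; cp[c][1] = cj; cp[c][2] = ck;
          if (cv[c] < iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4];
          int nin = 0;
          int ins[4], outs[4];
          int nout = 0;
          for (int c = 0; c < 4; ++c) {
            vi[c] = tets[t][c];
            if (cv[vi[c]] < iso) ins[nin++] = vi[c];
            else outs[nout++] = vi[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            int A = ins[0], B = outs[0], C = outs[1], D = outs[2];
            int e1 = mt_edge_vertex(st, gid[A], gid[B], cp[A], cp[B], cv[A], cv[B], iso);
            int e2 = mt_edge_vertex(st, gid[A], gid[C], cp[A], cp[C], cv[A], cv[C], iso);
            int e3 = mt_edge_vertex(st, gid[A], gid[D], cp[A], cp[D], cv[A], cv[D], iso);
            mt_emit(st, e1, e2, e3, mt_orient(cp[A], cp[B], cp[C], cp[D]) < 0);
          } else if (nin == 3) {
            int A = ins[0], B = ins[1], C = ins[2], D = outs[0];
            int e1 = mt_edge_vertex(st, gid[A], gid[D], cp[A], cp[D], cv[A], cv[D], iso);
            int e2 = mt_edge_vertex(st, gid[C], gid[D], cp[C], cp[D], cv[C], cv[D], iso);
            int e3 = mt_edge_vertex(st, gid[B], gid[D], cp[B], cp[D], cv[B], cv[D], iso);
            mt_emit(st, e1, e2, e3, mt_orient(cp[D], cp[A], cp[B], cp[C]) < 0);
          } else { // nin == 2: quad in cyclic order
            int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            int q0 = mt_edge_vertex(st, gid[A], gid[C], cp[A], cp[C], cv[A], cv[C], iso);
            int q1 = mt_edge_vertex(st, gid[A], gid[D], cp[A], cp[D], cv[A], cv[D], iso);
            int q2 = mt_edge_vertex(st, gid[B], gid[D], cp[B], cp[D], cv[B], cv[D], iso);
            int q3 = mt_edge_vertex(st, gid[B], gid[C], cp[B], cp[C], cv[B], cv[C], iso);
            bool flip = mt_orient(cp[A], cp[B], cp[C], cp[D]) < 0;
            mt_emit(st, q0, q1, q2, flip);
            mt_emit(st, q0, q2, q3, flip);
          }
        }
      }

  int nv = (int)(st.verts.size() / 3);
  int nt = (int)(st.tris.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix T(nt, 3);
  for (int i = 0; i < nv; ++i)
    for (int c = 0; c < 3; ++c) V(i, c) = st.verts[3 * i + c];
  for (int i = 0; i < nt; ++i)
    for (int c = 0; c < 3; ++c) T(i, c) = st.tris[3 * i + c] + 1; // 1-based
  return List::create(_["vertices"] = V, _["triangles"] = T);
}

// ---------------------------------------------------------------------------
// Voxelization of a closed triangle mesh by x-axis ray parity in continuous
// index space.  Ray origins carry a tiny fixed offset so rays essentially
// never pass exactly through mesh edges or vertices; the fill is inclusive at
// crossings, so boundary-grazing voxel centers count as inside.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_voxelize(NumericMatrix verts, IntegerMatrix tris, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nt = tris.nrow();
  const double ey = 1.000000137e-4, ez = 2.000000731e-4;
  std::vector<std::vector<double> > rays((size_t)ny * nz);

  for (int t = 0; t < nt; ++t) {
    int a = tris(t, 0) - 1, b = tris(t, 1) - 1, c = tris(t, 2) - 1;
    double p0y = verts(a, 1), p0z = verts(a, 2);
    double p1y = verts(b, 1), p1z = verts(b, 2);
    double p2y = verts(c, 1), p2z = verts(c, 2);
    double ymin = std::min(p0y, std::min(p1y, p2y));
    double ymax = std::max(p0y, std::max(p1y, p2y));
    double zmin = std::min(p0z, std::min(p1z, p2z));
    double zmax = std::max(p0z, std::max(p1z, p2z));
    int j0 = std::max(0, (int)std::ceil(ymin - ey - 1.0));
    int j1 = std::min(ny - 1, (int)std::floor(ymax + 1.0));
    int k0 = std::max(0, (int)std::ceil(zmin - ez - 1.0));
    int k1 = std::min(nz - 1, (int)std::floor(zmax + 1.0));
    if (j0 > j1 || k0 > k1) continue;
    double e1y = p1y - p0y, e1z = p1z - p0z;
    double e2y = p2y - p0y, e2z = p2z - p0z;
    double det = e1y * e2z - e2y * e1z;
    if (std::fabs(det) < 1e-14) continue; // edge-on triangle: neighbors cover
    double x0 = verts(a, 0), x1 = verts(b, 0), x2 = verts(c, 0);
    for (int k = k0; k <= k1; ++k) {
      double rz = k + ez - p0z;
      for (int j = j0; j <= j1; ++j) {
        double ry = j + ey - p0y;
        double u = (ry * e2z - e2y * rz) / det;
        double v = (e1y * rz - ry * e1z) / det;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        double x = x0 + u * (x1 - x0) + v * (x2 - x0);
        rays[(size_t)k * ny + j].push_back(x);
      }
    }
  }

  LogicalVector mask((R_xlen_t)nx * ny * nz, FALSE);
  int odd_rays = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      std::vector<double>& cr = rays[(size_t)k * ny + j];
      if (cr.empty()) continue;
      std::sort(cr.begin(), cr.end());
      size_t m = cr.size();
      if (m % 2 == 1) { ++odd_rays; --m; }
      for (size_t s = 0; s + 1 < m; s += 2) {
        int i0 = (int)std::ceil(cr[s] - 1e-9);
        int i1 = (int)std::floor(cr[s + 1] + 1e-9);
        if (i0 < 0) i0 = 0;
        if (i1 > nx - 1) i1 = nx - 1;
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) mask[base + i] = TRUE;
      }
    }
  return List::create(_["mask"] = mask, _["odd_rays"] = odd_rays);
}

// ---------------------------------------------------------------------------
// Trilinear interpolation at arbitrary continuous 0-based index coordinates.
// Points outside the grid get NA and inside = FALSE.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_trilinear(NumericVector vol, IntegerVector dim, NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector val(n);
  LogicalVector inside(n);
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      val[p] = NA_REAL;
      inside[p] = FALSE;
      continue;
    }
    int i = (int)std::floor(x); if (i > nx - 2) i = nx - 2; if (i < 0) i = 0;
    int j = (int)std::floor(y); if (j > ny - 2) j = ny - 2; if (j < 0) j = 0;
    int k = (int)std::floor(z); if (k > nz - 2) k = nz - 2; if (k < 0) k = 0;
    double fx = x - i, fy = y - j, fz = z - k;
    R_xlen_t b = i + j * sy + k * sz;
    double c00 = vol[b] * (1 - fx) + vol[b + 1] * fx;
    double c10 = vol[b + sy] * (1 - fx) + vol[b + sy + 1] * fx;
    double c01 = vol[b + sz] * (1 - fx) + vol[b + sz + 1] * fx;
    double c11 = vol[b + sy + sz] * (1 - fx) + vol[b + sy + sz + 1] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    val[p] = c0 * (1 - fz) + c1 * fz;
    inside[p] = TRUE;
  }
  return List::create(_["values"] = val, _["inside"] = inside);
}

// ---------------------------------------------------------------------------
// Separable 1-D convolution along one axis with replicate padding.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, IntegerVector dim,
                                NumericVector kernel, int axis) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int kl = kernel.size();
  int half = kl / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int n_axis = dim[axis];
  int d1 = (axis == 0) ? 1 : 0;
  int d2 = (axis == 2) ? 1 : 2;
  int n1 = dim[d1], n2 = dim[d2];
  R_xlen_t sA = stride[axis], s1 = stride[d1], s2 = stride[d2];
  std::vector<double> line(n_axis);
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      R_xlen_t base = a * s1 + b * s2;
      for (int q = 0; q < n_axis; ++q) line[q] = vol[base + q * sA];
      for (int q = 0; q < n_axis; ++q) {
        double acc = 0.0;
        for (int m = 0; m < kl; ++m) {
          int idx = q + m - half;
          if (idx < 0) idx = 0;
          if (idx > n_axis - 1) idx = n_axis - 1;
          acc += line[idx] * kernel[m];
        }
        out[base + q * sA] = acc;
      }
    }
  return out;
}
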