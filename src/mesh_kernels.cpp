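#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Separable Gaussian blur of a 3D field (index-space sigma, zero-padded).
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double>& src, std::vector<double>& dst,
                      int nx, int ny, int nz, int axis,
                      const std::vector<double>& kern) {
  int r = (int)kern.size() / 2;
  int dims[3] = {nx, ny, nz};
  int n = dims[axis];
  long strides[3] = {1, (long)nx, (long)nx * ny};
  long s = strides[axis];
  // iterate over all lines along `axis`
  int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  for (int b = 0; b < dims[ob]; ++b) {
    for (int a = 0; a < dims[oa]; ++a) {
      long base = (long)a * strides[oa] + (long)b * strides[ob];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = -r; k <= r; ++k) {
          int j = i + k;
          if (j < 0 || j >= n) continue; // zero padding
          acc += kern[k + r] * src[base + (long)j * s];
        }
        dst[base + (long)i * s] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_blur3d")]]
NumericVector cpp_blur3d(NumericVector field, double sigma) {
  IntegerVector dim = field.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double ksum = 0.0;
  for (int k = -r; k <= r; ++k) {
    kern[k + r] = std::exp(-0.5 * k * k / (sigma * sigma));
    ksum += kern[k + r];
  }
  for (auto& v : kern) v /= ksum;
  std::vector<double> a(field.begin(), field.end()), b(n);
  blur_axis(a, b, nx, ny, nz, 0, kern);
  blur_axis(b, a, nx, ny, nz, 1, kern);
  blur_axis(a, b, nx, ny, nz, 2, kern);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra isosurface. Field values at voxel centres; output
// vertices in (0-based) continuous index coordinates. Each cube is split
// into 6 tetrahedra sharing the main diagonal, so shared faces match and the
// surface is watertight for any field. Field values must not equal `level`
// exactly (caller nudges them), which also excludes degenerate triangles.
// ---------------------------------------------------------------------------

struct V3 { double x, y, z; };

static inline V3 v3sub(const V3& a, const V3& b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline V3 v3cross(const V3& a, const V3& b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double v3dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }

// [[Rcpp::export(name = ".cpp_marching_tetrahedra")]]
List cpp_marching_tetrahedra(NumericVector field, double level) {
  IntegerVector dim = field.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* f = field.begin();
  auto lin = [&](int i, int j, int k) -> long { return (long)i + (long)nx * (j + (long)ny * k); };

  // 6-tet decomposition of the unit cube around diagonal c0-c7
  static const int tets[6][4] = {
    {0,1,3,7}, {0,3,2,7}, {0,2,6,7}, {0,6,4,7}, {0,4,5,7}, {0,5,1,7}
  };
  static const int corner_off[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
  };

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> verts; // flat xyz
  std::vector<int> tris;     // flat 0-based

  auto edge_point = [&](long ga, long gb, double fa, double fb,
                        const V3& pa, const V3& pb) -> int {
    uint64_t a = (uint64_t)std::min(ga, gb), b = (uint64_t)std::max(ga, gb);
    uint64_t key = a * (uint64_t)(nx * (long)ny * nz) + b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    if (ga > gb) t = 1.0 - t; // canonical direction a->b
    const V3& p0 = (ga <= gb) ? pa : pb;
    const V3& p1 = (ga <= gb) ? pb : pa;
    V3 p = {p0.x + t * (p1.x - p0.x), p0.y + t * (p1.y - p0.y), p0.z + t * (p1.z - p0.z)};
    int idx = (int)(verts.size() / 3);
    verts.push_back(p.x); verts.push_back(p.y); verts.push_back(p.z);
    edge_vertex.emplace(key, idx);
    return idx;
  };

  auto add_tri = [&](int a, int b, int c, const V3& outward_ref) {
    // orient so the normal points along outward_ref (toward the low side)
    V3 pa = {verts[3*a], verts[3*a+1], verts[3*a+2]};
    V3 pb = {verts[3*b], verts[3*b+1], verts[3*b+2]};
    V3 pc = {verts[3*c], verts[3*c+1], verts[3*c+2]};
    V3 n = v3cross(v3sub(pb, pa), v3sub(pc, pa));
    if (v3dot(n, outward_ref) < 0) std::swap(b, c);
    tris.push_back(a); tris.push_back(b); tris.push_back(c);
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double fc[8]; long gc[8]; V3 pc[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + corner_off[c][0], cj = j + corner_off[c][1], ck = k + corner_off[c][2];
          gc[c] = lin(ci, cj, ck);
          fc[c] = f[gc[c]];
          pc[c] = {(double)ci, (double)cj, (double)ck};
          if (fc[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (fc[id[c]] > level) in_idx[ni++] = id[c]; else out_idx[no++] = id[c];
          }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? in_idx[0] : out_idx[0];
            int base[3]; int nb = 0;
            for (int c = 0; c < 4; ++c) if (id[c] != apex) base[nb++] = id[c];
            int e0 = edge_point(gc[apex], gc[base[0]], fc[apex], fc[base[0]], pc[apex], pc[base[0]]);
            int e1 = edge_point(gc[apex], gc[base[1]], fc[apex], fc[base[1]], pc[apex], pc[base[1]]);
            int e2 = edge_point(gc[apex], gc[base[2]], fc[apex], fc[base[2]], pc[apex], pc[base[2]]);
            // outward = from inside material toward outside
            V3 ref;
            if (ni == 1) ref = v3sub(pc[base[0]], pc[apex]); // away from inside apex
            else ref = v3sub(pc[apex], pc[base[0]]);          // toward outside apex
            // use average direction for robustness
            if (ni == 1) {
              V3 m = {(pc[base[0]].x + pc[base[1]].x + pc[base[2]].x) / 3.0,
                      (pc[base[0]].y + pc[base[1]].y + pc[base[2]].y) / 3.0,
                      (pc[base[0]].z + pc[base[1]].z + pc[base[2]].z) / 3.0};
              ref = v3sub(m, pc[apex]);
            } else {
              V3 m = {(pc[base[0]].x + pc[base[1]].x + pc[base[2]].x) / 3.0,
                      (pc[base[0]].y + pc[base[1]].y + pc[base[2]].y) / 3.0,
                      (pc[base[0]].z + pc[base[1]].z + pc[base[2]].z) / 3.0};
              ref = v3sub(pc[apex], m);
            }
            add_tri(e0, e1, e2, ref);
          } else { // 2 in, 2 out -> quad
            int a = in_idx[0], b = in_idx[1], c = out_idx[0], d = out_idx[1];
            int eac = edge_point(gc[a], gc[c], fc[a], fc[c], pc[a], pc[c]);
            int ead = edge_point(gc[a], gc[d], fc[a], fc[d], pc[a], pc[d]);
            int ebd = edge_point(gc[b], gc[d], fc[b], fc[d], pc[b], pc[d]);
            int ebc = edge_point(gc[b], gc[c], fc[b], fc[c], pc[b], pc[c]);
            V3 min = {(pc[a].x + pc[b].x) / 2.0, (pc[a].y + pc[b].y) / 2.0, (pc[a].z + pc[b].z) / 2.0};
            V3 mout = {(pc[c].x + pc[d].x) / 2.0, (pc[c].y + pc[d].y) / 2.0, (pc[c].z + pc[d].z) / 2.0};
            V3 ref = v3sub(mout, min);
            add_tri(eac, ead, ebd, ref);
            add_tri(eac, ebd, ebc, ref);
          }
        }
      }

  int nv = (int)(verts.size() / 3), nt = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = verts[3*v]; V(v, 1) = verts[3*v+1]; V(v, 2) = verts[3*v+2];
  }
  IntegerMatrix T(nt, 3);
  for (int t = 0; t < nt; ++t) {
    T(t, 0) = tris[3*t]; T(t, 1) = tris[3*t+1]; T(t, 2) = tris[3*t+2];
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}

// ---------------------------------------------------------------------------
// Voxelization by x-ray parity at voxel centres. Vertices in world mm,
// grid given by origin (centre of voxel [0,0,0]) and spacing.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_voxelize")]]
List cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                  NumericVector origin, NumericVector spacing,
                  IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nf = F.nrow();
  // tiny irrational ray offset avoids edge/vertex hits on gridded meshes
  double ey = spacing[1] * 1.2345678e-6, ez = spacing[2] * 2.3456789e-6;
  std::vector<std::vector<double>> cross((size_t)ny * nz);

  for (int t = 0; t < nf; ++t) {
    int i0 = F(t, 0), i1 = F(t, 1), i2 = F(t, 2);
    double y0 = V(i0,1), y1 = V(i1,1), y2 = V(i2,1);
    double z0 = V(i0,2), z1 = V(i1,2), z2 = V(i2,2);
    double x0 = V(i0,0), x1 = V(i1,0), x2 = V(i2,0);
    double det = (y1 - y0) * (z2 - z0) - (z1 - z0) * (y2 - y0);
    if (std::fabs(det) < 1e-14) continue; // parallel to x-rays
    double ymin = std::min({y0, y1, y2}), ymax = std::max({y0, y1, y2});
    double zmin = std::min({z0, z1, z2}), zmax = std::max({z0, z1, z2});
    int jlo = std::max(0, (int)std::ceil((ymin - ey - origin[1]) / spacing[1]));
    int jhi = std::min(ny - 1, (int)std::floor((ymax - ey - origin[1]) / spacing[1]));
    int klo = std::max(0, (int)std::ceil((zmin - ez - origin[2]) / spacing[2]));
    int khi = std::min(nz - 1, (int)std::floor((zmax - ez - origin[2]) / spacing[2]));
    for (int k = klo; k <= khi; ++k) {
      double zc = origin[2] + k * spacing[2] + ez;
      for (int j = jlo; j <= jhi; ++j) {
        double yc = origin[1] + j * spacing[1] + ey;
        double u = ((yc - y0) * (z2 - z0) - (zc - z0) * (y2 - y0)) / det;
        double v = ((y1 - y0) * (zc - z0) - (z1 - z0) * (yc - y0)) / det;
        if (u < 0 || v < 0 || u + v > 1) continue;
        double x = x0 + u * (x1 - x0) + v * (x2 - x0);
        cross[(size_t)j + (size_t)ny * k].push_back(x);
      }
    }
  }

  IntegerVector lab((R_xlen_t)nx * ny * nz, 0);
  lab.attr("dim") = dims;
  bool odd_warn = false;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      auto& cs = cross[(size_t)j + (size_t)ny * k];
      if (cs.empty()) continue;
      std::sort(cs.begin(), cs.end());
      if (cs.size() % 2 == 1) { odd_warn = true; cs.pop_back(); }
      for (size_t p = 0; p + 1 < cs.size(); p += 2) {
        int ilo = std::max(0, (int)std::ceil((cs[p] - origin[0]) / spacing[0]));
        int ihi = std::min(nx - 1, (int)std::floor((cs[p + 1] - origin[0]) / spacing[0]));
        for (int i = ilo; i <= ihi; ++i)
          lab[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = 1;
      }
    }
  return List::create(_["labels"] = lab, _["odd_parity"] = odd_warn);
}

// ---------------------------------------------------------------------------
// Exact point-to-triangle distance (Ericson), min over mesh per query point,
// with triangle bounding-box pruning against the current best.
// ---------------------------------------------------------------------------

static double point_tri_dist2(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = v3sub(b, a), ac = v3sub(c, a), ap = v3sub(p, a);
  double d1 = v3dot(ab, ap), d2 = v3dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { V3 d = ap; return v3dot(d, d); }
  V3 bp = v3sub(p, b);
  double d3 = v3dot(ab, bp), d4 = v3dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { V3 d = bp; return v3dot(d, d); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    V3 q = {a.x + t * ab.x - p.x, a.y + t * ab.y - p.y, a.z + t * ab.z - p.z};
    return v3dot(q, q);
  }
  V3 cp = v3sub(p, c);
  double d5 = v3dot(ab, cp), d6 = v3dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { V3 d = cp; return v3dot(d, d); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    V3 q = {a.x + t * ac.x - p.x, a.y + t * ac.y - p.y, a.z + t * ac.z - p.z};
    return v3dot(q, q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    V3 q = {b.x + t * (c.x - b.x) - p.x, b.y + t * (c.y - b.y) - p.y, b.z + t * (c.z - b.z) - p.z};
    return v3dot(q, q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  V3 q = {a.x + ab.x * v + ac.x * w - p.x, a.y + ab.y * v + ac.y * w - p.y,
          a.z + ab.z * v + ac.z * w - p.z};
  return v3dot(q, q);
}

// [[Rcpp::export(name = ".cpp_point_mesh_distance")]]
NumericVector cpp_point_mesh_distance(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  std::vector<double> bx0(nf), bx1(nf), by0(nf), by1(nf), bz0(nf), bz1(nf);
  std::vector<V3> ta(nf), tb(nf), tc(nf);
  for (int t = 0; t < nf; ++t) {
    int i0 = F(t,0), i1 = F(t,1), i2 = F(t,2);
    ta[t] = {V(i0,0), V(i0,1), V(i0,2)};
    tb[t] = {V(i1,0), V(i1,1), V(i1,2)};
    tc[t] = {V(i2,0), V(i2,1), V(i2,2)};
    bx0[t] = std::min({ta[t].x, tb[t].x, tc[t].x}); bx1[t] = std::max({ta[t].x, tb[t].x, tc[t].x});
    by0[t] = std::min({ta[t].y, tb[t].y, tc[t].y}); by1[t] = std::max({ta[t].y, tb[t].y, tc[t].y});
    bz0[t] = std::min({ta[t].z, tb[t].z, tc[t].z}); bz1[t] = std::max({ta[t].z, tb[t].z, tc[t].z});
  }
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    V3 q = {P(p,0), P(p,1), P(p,2)};
    double best = R_PosInf;
    for (int t = 0; t < nf; ++t) {
      double dx = std::max({bx0[t] - q.x, 0.0, q.x - bx1[t]});
      double dy = std::max({by0[t] - q.y, 0.0, q.y - by1[t]});
      double dz = std::max({bz0[t] - q.z, 0.0, q.z - bz1[t]});
      if (dx * dx + dy * dy + dz * dz >= best) continue;
      double d2 = point_tri_dist2(q, ta[t], tb[t], tc[t]);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
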