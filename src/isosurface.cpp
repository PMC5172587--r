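// Isosurface extraction by marching tetrahedra on the Freudenthal (Kuhn)
// 6-tetrahedron cube decomposition. The decomposition tiles the grid
// consistently, and surface vertices are deduplicated by the grid edge
// they lie on, so the output is a shared-vertex mesh that is watertight
// away from the volume boundary. Triangle winding is fixed so normals
// point toward the low-intensity (outside) region.
//
// Volume: integer array dim (nz, ny, nx), column-major. World coordinates:
// voxel (k, j, i) -> (x, y, z) = (i*sx, j*sy, k*sz) micrometres.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {
struct V3 { double x, y, z; };
V3 operator-(const V3& a, const V3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
}

// [[Rcpp::export]]
List cpp_marching_tetra(IntegerVector vol, int nz, int ny, int nx,
                        double iso, double sz, double sy, double sx) {
  const int* v = INTEGER(vol);
  auto val = [&](int k, int j, int i) -> double {
    return (double)v[k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i)];
  };
  auto gid = [&](int k, int j, int i) -> uint64_t {
    return (uint64_t)k + (uint64_t)nz * ((uint64_t)j + (uint64_t)ny * i);
  };
  // cube corner c = bx + 2*by + 4*bz ; Freudenthal path tets
  static const int TETS[6][4] = {
      {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
      {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> VX, VY, VZ;
  std::vector<int> F0, F1, F2;
  edge_vert.reserve(1 << 16);

  double cval[8]; uint64_t cid[8]; V3 cpos[8];
  for (int i = 0; i + 1 < nx; ++i)
    for (int j = 0; j + 1 < ny; ++j)
      for (int k = 0; k + 1 < nz; ++k) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int bi = c & 1, bj = (c >> 1) & 1, bk = (c >> 2) & 1;
          cval[c] = val(k + bk, j + bj, i + bi);
          cid[c] = gid(k + bk, j + bj, i + bi);
          cpos[c] = {(i + bi) * sx, (j + bj) * sy, (k + bk) * sz};
          if (cval[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int in_idx[4], out_idx[4], nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cval[T[c]] > iso) in_idx[nin++] = T[c];
            else out_idx[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          auto edge_vertex = [&](int a, int b) -> int {
            uint64_t ia = cid[a], ib = cid[b];
            if (ia > ib) std::swap(ia, ib);
            // nz*ny*nx <= 2^31 here, so pairing two ids fits in 64 bits
            uint64_t key = ia * (uint64_t)((R_xlen_t)nz * ny * nx) + ib;
            auto it = edge_vert.find(key);
            if (it != edge_vert.end()) return it->second;
            double va = cval[a], vb = cval[b];
            double tt = (iso - va) / (vb - va);
            if (tt < 0) tt = 0; if (tt > 1) tt = 1;
            V3 p = {cpos[a].x + tt * (cpos[b].x - cpos[a].x),
                    cpos[a].y + tt * (cpos[b].y - cpos[a].y),
                    cpos[a].z + tt * (cpos[b].z - cpos[a].z)};
            int id = (int)VX.size();
            VX.push_back(p.x); VY.push_back(p.y); VZ.push_back(p.z);
            edge_vert.emplace(key, id);
            return id;
          };
          auto emit = [&](int e0, int e1, int e2, const V3& out_ref) {
            if (e0 == e1 || e1 == e2 || e0 == e2) return;
            V3 p0 = {VX[e0], VY[e0], VZ[e0]};
            V3 p1 = {VX[e1], VY[e1], VZ[e1]};
            V3 p2 = {VX[e2], VY[e2], VZ[e2]};
            V3 n = cross(p1 - p0, p2 - p0);
            V3 cen = {(p0.x + p1.x + p2.x) / 3, (p0.y + p1.y + p2.y) / 3,
                      (p0.z + p1.z + p2.z) / 3};
            // orient normal toward the outside (low-intensity) reference
            if (dot(n, out_ref - cen) < 0) std::swap(e1, e2);
            F0.push_back(e0); F1.push_back(e1); F2.push_back(e2);
          };
          if (nin == 1) {
            int a = in_idx[0];
            int e0 = edge_vertex(a, out_idx[0]);
            int e1 = edge_vertex(a, out_idx[1]);
            int e2 = edge_vertex(a, out_idx[2]);
            V3 oc = {(cpos[out_idx[0]].x + cpos[out_idx[1]].x + cpos[out_idx[2]].x) / 3,
                     (cpos[out_idx[0]].y + cpos[out_idx[1]].y + cpos[out_idx[2]].y) / 3,
                     (cpos[out_idx[0]].z + cpos[out_idx[1]].z + cpos[out_idx[2]].z) / 3};
            emit(e0, e1, e2, oc);
          } else if (nin == 3) {
            int a = out_idx[0];
            int e0 = edge_vertex(a, in_idx[0]);
            int e1 = edge_vertex(a, in_idx[1]);
            int e2 = edge_vertex(a, in_idx[2]);
            emit(e0, e1, e2, cpos[a]);
          } else {  // 2 in, 2 out -> quad
            int a = in_idx[0], b = in_idx[1], c = out_idx[0], d = out_idx[1];
            int e0 = edge_vertex(a, c);
            int e1 = edge_vertex(a, d);
            int e2 = edge_vertex(b, d);
            int e3 = edge_vertex(b, c);
            V3 oc = {(cpos[c].x + cpos[d].x) / 2, (cpos[c].y + cpos[d].y) / 2,
                     (cpos[c].z + cpos[d].z) / 2};
            emit(e0, e1, e2, oc);
            emit(e0, e2, e3, oc);
          }
        }
      }
  const int nvert = (int)VX.size(), nface = (int)F0.size();
  NumericMatrix verts(nvert, 3);
  IntegerMatrix faces(nface, 3);
  for (int i = 0; i < nvert; ++i) {
    verts(i, 0) = VX[i]; verts(i, 1) = VY[i]; verts(i, 2) = VZ[i];
  }
  for (int i = 0; i < nface; ++i) {
    faces(i, 0) = F0[i] + 1; faces(i, 1) = F1[i] + 1; faces(i, 2) = F2[i] + 1;
  }
  return List::create(Named("vertices") = verts, Named("faces") = faces);
}
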