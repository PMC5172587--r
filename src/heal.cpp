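// Mesh healing: weld duplicate vertices, drop degenerate faces, make
// face windings consistent by breadth-first propagation over edge
// adjacency (dropping faces at non-orientable contacts), triangulate
// every boundary loop shut with a centroid fan, and flip components with
// negative signed volume so normals point outward.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <functional>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_heal_mesh(NumericMatrix verts, IntegerMatrix faces,
                   double merge_tol) {
  const int nv0 = verts.nrow(), nf0 = faces.nrow();
  // --- weld duplicates on a tolerance grid
  struct Key { long long a, b, c; int id; };
  std::unordered_map<uint64_t, std::vector<Key>> grid;
  grid.reserve(nv0 * 2);
  std::vector<int> remap(nv0);
  std::vector<double> VX, VY, VZ;
  auto h64 = [](long long a, long long b, long long c) {
    uint64_t h = 1469598103934665603ull;
    for (long long v : {a, b, c}) {
      h ^= (uint64_t)v;
      h *= 1099511628211ull;
    }
    return h;
  };
  for (int i = 0; i < nv0; ++i) {
    long long a = llround(verts(i, 0) / merge_tol);
    long long b = llround(verts(i, 1) / merge_tol);
    long long c = llround(verts(i, 2) / merge_tol);
    auto& bucket = grid[h64(a, b, c)];
    int hit = -1;
    for (const Key& k : bucket)
      if (k.a == a && k.b == b && k.c == c) { hit = k.id; break; }
    if (hit < 0) {
      hit = (int)VX.size();
      bucket.push_back({a, b, c, hit});
      VX.push_back(verts(i, 0));
      VY.push_back(verts(i, 1));
      VZ.push_back(verts(i, 2));
    }
    remap[i] = hit;
  }
  std::vector<int> F0, F1, F2;
  F0.reserve(nf0); F1.reserve(nf0); F2.reserve(nf0);
  for (int f = 0; f < nf0; ++f) {
    int a = remap[faces(f, 0) - 1], b = remap[faces(f, 1) - 1],
        c = remap[faces(f, 2) - 1];
    if (a == b || b == c || a == c) continue;
    F0.push_back(a); F1.push_back(b); F2.push_back(c);
  }
  int nf = (int)F0.size();
  int nv = (int)VX.size();

  // --- undirected edge map: edge id -> (face0, face1, extra?)
  std::unordered_map<uint64_t, std::pair<int, int>> emap;
  emap.reserve(nf * 2);
  std::vector<bool> nonmanifold_face(nf, false);
  auto ekey = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    return (uint64_t)a * (uint64_t)nv + (uint64_t)b;
  };
  for (int f = 0; f < nf; ++f) {
    int v[3] = {F0[f], F1[f], F2[f]};
    for (int e = 0; e < 3; ++e) {
      uint64_t k = ekey(v[e], v[(e + 1) % 3]);
      auto it = emap.find(k);
      if (it == emap.end()) emap.emplace(k, std::make_pair(f, -1));
      else if (it->second.second < 0) it->second.second = f;
      else nonmanifold_face[f] = true;  // third face on this edge
    }
  }

  // --- orient by BFS; flipped faces have reversed winding
  std::vector<char> visited(nf, 0), flip(nf, 0), keep(nf, 1);
  auto dir_has = [&](int f, int a, int b) {
    int v0 = F0[f], v1 = F1[f], v2 = F2[f];
    if (flip[f]) std::swap(v1, v2);
    return (v0 == a && v1 == b) || (v1 == a && v2 == b) || (v2 == a && v0 == b);
  };
  std::queue<int> bfs;
  for (int seed = 0; seed < nf; ++seed) {
    if (visited[seed]) continue;
    visited[seed] = 1;
    bfs.push(seed);
    while (!bfs.empty()) {
      int f = bfs.front(); bfs.pop();
      int v[3] = {F0[f], F1[f], F2[f]};
      for (int e = 0; e < 3; ++e) {
        int a = v[e], b = v[(e + 1) % 3];
        auto& pr = emap[ekey(a, b)];
        int g = (pr.first == f) ? pr.second : pr.first;
        if (g < 0) continue;
        bool f_ab = dir_has(f, a, b);
        if (!visited[g]) {
          // consistent neighbours traverse the shared edge oppositely
          bool g_ab = dir_has(g, a, b);
          flip[g] = (f_ab == g_ab) ? 1 : 0;
          visited[g] = 1;
          bfs.push(g);
        } else {
          if (dir_has(g, a, b) == f_ab) keep[g] = 0;  // orientation conflict
        }
      }
    }
  }
  // apply flips, drop conflicting faces
  {
    std::vector<int> G0, G1, G2;
    G0.reserve(nf); G1.reserve(nf); G2.reserve(nf);
    for (int f = 0; f < nf; ++f) {
      if (!keep[f]) continue;
      int a = F0[f], b = F1[f], c = F2[f];
      if (flip[f]) std::swap(b, c);
      G0.push_back(a); G1.push_back(b); G2.push_back(c);
    }
    F0.swap(G0); F1.swap(G1); F2.swap(G2);
    nf = (int)F0.size();
  }

  // --- boundary loops: directed edges whose undirected edge has 1 face
  emap.clear();
  std::unordered_map<uint64_t, int> ecount;
  ecount.reserve(nf * 2);
  for (int f = 0; f < nf; ++f) {
    int v[3] = {F0[f], F1[f], F2[f]};
    for (int e = 0; e < 3; ++e) ecount[ekey(v[e], v[(e + 1) % 3])]++;
  }
  std::unordered_map<int, int> nxt;  // boundary successor per vertex
  for (int f = 0; f < nf; ++f) {
    int v[3] = {F0[f], F1[f], F2[f]};
    for (int e = 0; e < 3; ++e) {
      int a = v[e], b = v[(e + 1) % 3];
      if (ecount[ekey(a, b)] == 1) nxt[a] = b;
    }
  }
  int n_loops = 0;
  std::unordered_map<int, char> consumed;
  for (auto& kv : nxt) {
    int start = kv.first;
    if (consumed.count(start)) continue;
    std::vector<int> loop;
    int cur = start;
    bool ok = true;
    while (true) {
      loop.push_back(cur);
      consumed[cur] = 1;
      auto it = nxt.find(cur);
      if (it == nxt.end()) { ok = false; break; }
      cur = it->second;
      if (cur == start) break;
      if (consumed.count(cur)) { ok = false; break; }
    }
    if (!ok || loop.size() < 3) continue;
    double cx = 0, cy = 0, cz = 0;
    for (int v : loop) { cx += VX[v]; cy += VY[v]; cz += VZ[v]; }
    double inv = 1.0 / loop.size();
    VX.push_back(cx * inv); VY.push_back(cy * inv); VZ.push_back(cz * inv);
    int cid = (int)VX.size() - 1;
    // boundary directed edge (a -> b) is unmatched: new face (b, a, cen)
    for (size_t i = 0; i < loop.size(); ++i) {
      int a = loop[i], b = loop[(i + 1) % loop.size()];
      F0.push_back(b); F1.push_back(a); F2.push_back(cid);
    }
    ++n_loops;
  }
  nf = (int)F0.size();
  nv = (int)VX.size();

  // --- union-find components, signed volume, flip inward components
  std::vector<int> uf(nv);
  for (int i = 0; i < nv; ++i) uf[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
    return x;
  };
  for (int f = 0; f < nf; ++f) {
    int a = find(F0[f]), b = find(F1[f]), c = find(F2[f]);
    uf[b] = a; uf[c] = find(a);
  }
  std::unordered_map<int, double> vol6;
  for (int f = 0; f < nf; ++f) {
    int r = find(F0[f]);
    double ax = VX[F0[f]], ay = VY[F0[f]], az = VZ[F0[f]];
    double bx = VX[F1[f]], by = VY[F1[f]], bz = VZ[F1[f]];
    double cx = VX[F2[f]], cy = VY[F2[f]], cz = VZ[F2[f]];
    vol6[r] += ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
               az * (bx * cy - by * cx);
  }
  for (int f = 0; f < nf; ++f)
    if (vol6[find(F0[f])] < 0) std::swap(F1[f], F2[f]);

  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = VX[i]; V(i, 1) = VY[i]; V(i, 2) = VZ[i];
  }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = F0[f] + 1; F(f, 1) = F1[f] + 1; F(f, 2) = F2[f] + 1;
  }
  int n_dropped = 0;
  for (int f = 0; f < (int)keep.size(); ++f) if (!keep[f]) ++n_dropped;
  return List::create(Named("vertices") = V, Named("faces") = F,
                      Named("n_loops_closed") = n_loops,
                      Named("n_faces_dropped") = n_dropped);
}
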