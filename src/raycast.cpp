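// Triangle-mesh geometry kernels: a uniform-grid acceleration structure
// shared by ray casting (volumetric obscurance, shape diameter function)
// and exact point-to-triangle nearest distances (surface distance / QC),
// plus vertex normals, Taubin smoothing and pairwise diameters.
// All coordinates are micrometres. Faces are 1-based on the R side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };
V3 operator+(const V3& a, const V3& b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
V3 operator-(const V3& a, const V3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
V3 operator*(double s, const V3& a) { return {s * a.x, s * a.y, s * a.z}; }
double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
double norm(const V3& a) { return std::sqrt(dot(a, a)); }

struct TriGrid {
  std::vector<V3> P;
  std::vector<int> fa, fb, fc;
  std::vector<V3> TA, TE1, TE2;  // precomputed triangle origin + edges
  double x0, y0, z0, cx, cy, cz;
  int nx, ny, nz;
  // CSR cell -> triangle list
  std::vector<int> cell_start, cell_items;
  std::vector<int> mark;  // query-stamp per triangle
  int stamp = 0;

  void build(const NumericMatrix& verts, const IntegerMatrix& faces) {
    const int nv = verts.nrow(), nf = faces.nrow();
    P.resize(nv);
    for (int i = 0; i < nv; ++i) P[i] = {verts(i, 0), verts(i, 1), verts(i, 2)};
    fa.resize(nf); fb.resize(nf); fc.resize(nf);
    TA.resize(nf); TE1.resize(nf); TE2.resize(nf);
    for (int i = 0; i < nf; ++i) {
      fa[i] = faces(i, 0) - 1; fb[i] = faces(i, 1) - 1; fc[i] = faces(i, 2) - 1;
      TA[i] = P[fa[i]];
      TE1[i] = P[fb[i]] - P[fa[i]];
      TE2[i] = P[fc[i]] - P[fa[i]];
    }
    double xmin = 1e300, ymin = 1e300, zmin = 1e300;
    double xmax = -1e300, ymax = -1e300, zmax = -1e300;
    for (const V3& p : P) {
      xmin = std::min(xmin, p.x); xmax = std::max(xmax, p.x);
      ymin = std::min(ymin, p.y); ymax = std::max(ymax, p.y);
      zmin = std::min(zmin, p.z); zmax = std::max(zmax, p.z);
    }
    const double pad = 1e-6 + 1e-6 * std::max({xmax - xmin, ymax - ymin, zmax - zmin});
    xmin -= pad; ymin -= pad; zmin -= pad;
    xmax += pad; ymax += pad; zmax += pad;
    const double target = std::cbrt(std::max(1.0, 2.0 * nf));
    const double ex = xmax - xmin, ey = ymax - ymin, ez = zmax - zmin;
    const double emean = std::cbrt(std::max(ex * ey * ez, 1e-18));
    auto ncell = [&](double e) {
      int n = (int)std::ceil(target * e / emean);
      return std::max(1, std::min(n, 320));
    };
    nx = ncell(ex); ny = ncell(ey); nz = ncell(ez);
    x0 = xmin; y0 = ymin; z0 = zmin;
    cx = ex / nx; cy = ey / ny; cz = ez / nz;
    const size_t ncells = (size_t)nx * ny * nz;
    std::vector<int> counts(ncells + 1, 0);
    auto tri_range = [&](int f, int& ix0, int& ix1, int& iy0, int& iy1,
                         int& iz0, int& iz1) {
      const V3& A = P[fa[f]]; const V3& B = P[fb[f]]; const V3& C = P[fc[f]];
      ix0 = idx(std::min({A.x, B.x, C.x}), x0, cx, nx);
      ix1 = idx(std::max({A.x, B.x, C.x}), x0, cx, nx);
      iy0 = idx(std::min({A.y, B.y, C.y}), y0, cy, ny);
      iy1 = idx(std::max({A.y, B.y, C.y}), y0, cy, ny);
      iz0 = idx(std::min({A.z, B.z, C.z}), z0, cz, nz);
      iz1 = idx(std::max({A.z, B.z, C.z}), z0, cz, nz);
    };
    for (int f = 0; f < nf; ++f) {
      int ix0, ix1, iy0, iy1, iz0, iz1;
      tri_range(f, ix0, ix1, iy0, iy1, iz0, iz1);
      for (int i = ix0; i <= ix1; ++i)
        for (int j = iy0; j <= iy1; ++j)
          for (int k = iz0; k <= iz1; ++k) ++counts[cell(i, j, k) + 1];
    }
    for (size_t c = 1; c <= ncells; ++c) counts[c] += counts[c - 1];
    cell_start = counts;
    cell_items.resize(cell_start[ncells]);
    std::vector<int> fill(cell_start.begin(), cell_start.end() - 1);
    for (int f = 0; f < nf; ++f) {
      int ix0, ix1, iy0, iy1, iz0, iz1;
      tri_range(f, ix0, ix1, iy0, iy1, iz0, iz1);
      for (int i = ix0; i <= ix1; ++i)
        for (int j = iy0; j <= iy1; ++j)
          for (int k = iz0; k <= iz1; ++k)
            cell_items[fill[cell(i, j, k)]++] = f;
    }
    mark.assign(nf, -1);
  }
  static int idx(double v, double o, double c, int n) {
    int i = (int)std::floor((v - o) / c);
    return std::max(0, std::min(i, n - 1));
  }
  size_t cell(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  }

  bool ray_tri(const V3& o, const V3& d, int f, double tmin, double& t) const {
    const V3& A = TA[f]; const V3& e1 = TE1[f]; const V3& e2 = TE2[f];
    V3 pv = cross(d, e2);
    double det = dot(e1, pv);
    if (std::fabs(det) < 1e-14) return false;
    double inv = 1.0 / det;
    V3 tv = o - A;
    double u = dot(tv, pv) * inv;
    if (u < -1e-9 || u > 1 + 1e-9) return false;
    V3 qv = cross(tv, e1);
    double vv = dot(d, qv) * inv;
    if (vv < -1e-9 || u + vv > 1 + 1e-9) return false;
    double tt = dot(e2, qv) * inv;
    if (tt < tmin) return false;
    t = tt;
    return true;
  }

  // nearest hit along ray; triangles incident to exclude_vert are skipped
  double ray_cast(const V3& o, const V3& d, int exclude_vert, double tmin) {
    ++stamp;
    double best = std::numeric_limits<double>::infinity();
    int i = idx(o.x, x0, cx, nx), j = idx(o.y, y0, cy, ny), k = idx(o.z, z0, cz, nz);
    if (o.x < x0 || o.x > x0 + cx * nx || o.y < y0 || o.y > y0 + cy * ny ||
        o.z < z0 || o.z > z0 + cz * nz)
      return best;  // origins are mesh vertices: always inside the grid
    int sx = d.x > 0 ? 1 : -1, sy = d.y > 0 ? 1 : -1, sz = d.z > 0 ? 1 : -1;
    const double inf = std::numeric_limits<double>::infinity();
    auto tmax0 = [&](double o1, double g0, double c, int i1, double dd, int s) {
      if (dd == 0) return inf;
      double edge = g0 + (i1 + (s > 0 ? 1 : 0)) * c;
      return (edge - o1) / dd;
    };
    double tmx = tmax0(o.x, x0, cx, i, d.x, sx);
    double tmy = tmax0(o.y, y0, cy, j, d.y, sy);
    double tmz = tmax0(o.z, z0, cz, k, d.z, sz);
    double tdx = d.x != 0 ? std::fabs(cx / d.x) : inf;
    double tdy = d.y != 0 ? std::fabs(cy / d.y) : inf;
    double tdz = d.z != 0 ? std::fabs(cz / d.z) : inf;
    while (true) {
      const size_t c = cell(i, j, k);
      for (int ii = cell_start[c]; ii < cell_start[c + 1]; ++ii) {
        const int f = cell_items[ii];
        if (mark[f] == stamp) continue;
        mark[f] = stamp;
        if (exclude_vert >= 0 &&
            (fa[f] == exclude_vert || fb[f] == exclude_vert || fc[f] == exclude_vert))
          continue;
        double t;
        if (ray_tri(o, d, f, tmin, t) && t < best) best = t;
      }
      double exit_t = std::min({tmx, tmy, tmz});
      if (best <= exit_t) break;
      if (tmx <= tmy && tmx <= tmz) { i += sx; tmx += tdx; if (i < 0 || i >= nx) break; }
      else if (tmy <= tmz) { j += sy; tmy += tdy; if (j < 0 || j >= ny) break; }
      else { k += sz; tmz += tdz; if (k < 0 || k >= nz) break; }
    }
    return best;
  }

  // does the ray hit anything at all? (no nearest-ordering; used by
  // obscurance where only escape/no-escape matters)
  bool ray_any_hit(const V3& o, const V3& d, int exclude_vert, double tmin) {
    ++stamp;
    int i = idx(o.x, x0, cx, nx), j = idx(o.y, y0, cy, ny), k = idx(o.z, z0, cz, nz);
    if (o.x < x0 || o.x > x0 + cx * nx || o.y < y0 || o.y > y0 + cy * ny ||
        o.z < z0 || o.z > z0 + cz * nz)
      return false;
    int sx = d.x > 0 ? 1 : -1, sy = d.y > 0 ? 1 : -1, sz = d.z > 0 ? 1 : -1;
    const double inf = std::numeric_limits<double>::infinity();
    auto tmax0 = [&](double o1, double g0, double c, int i1, double dd, int s) {
      if (dd == 0) return inf;
      double edge = g0 + (i1 + (s > 0 ? 1 : 0)) * c;
      return (edge - o1) / dd;
    };
    double tmx = tmax0(o.x, x0, cx, i, d.x, sx);
    double tmy = tmax0(o.y, y0, cy, j, d.y, sy);
    double tmz = tmax0(o.z, z0, cz, k, d.z, sz);
    double tdx = d.x != 0 ? std::fabs(cx / d.x) : inf;
    double tdy = d.y != 0 ? std::fabs(cy / d.y) : inf;
    double tdz = d.z != 0 ? std::fabs(cz / d.z) : inf;
    while (true) {
      const size_t c = cell(i, j, k);
      for (int ii = cell_start[c]; ii < cell_start[c + 1]; ++ii) {
        const int f = cell_items[ii];
        if (mark[f] == stamp) continue;
        mark[f] = stamp;
        if (exclude_vert >= 0 &&
            (fa[f] == exclude_vert || fb[f] == exclude_vert || fc[f] == exclude_vert))
          continue;
        double t;
        if (ray_tri(o, d, f, tmin, t)) return true;
      }
      if (tmx <= tmy && tmx <= tmz) { i += sx; tmx += tdx; if (i < 0 || i >= nx) return false; }
      else if (tmy <= tmz) { j += sy; tmy += tdy; if (j < 0 || j >= ny) return false; }
      else { k += sz; tmz += tdz; if (k < 0 || k >= nz) return false; }
    }
  }

  static V3 closest_on_tri(const V3& p, const V3& a, const V3& b, const V3& c) {
    // Ericson, Real-Time Collision Detection
    V3 ab = b - a, ac = c - a, ap = p - a;
    double d1 = dot(ab, ap), d2 = dot(ac, ap);
    if (d1 <= 0 && d2 <= 0) return a;
    V3 bp = p - b;
    double d3 = dot(ab, bp), d4 = dot(ac, bp);
    if (d3 >= 0 && d4 <= d3) return b;
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) return a + (d1 / (d1 - d3)) * ab;
    V3 cp = p - c;
    double d5 = dot(ab, cp), d6 = dot(ac, cp);
    if (d6 >= 0 && d5 <= d6) return c;
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) return a + (d2 / (d2 - d6)) * ac;
    double va = d3 * d6 - d5 * d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
      return b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b);
    double denom = 1.0 / (va + vb + vc);
    return a + (vb * denom) * ab + (vc * denom) * ac;
  }

  double aabb_dist(const V3& p, int i, int j, int k) const {
    double lx = x0 + i * cx, hx = lx + cx;
    double ly = y0 + j * cy, hy = ly + cy;
    double lz = z0 + k * cz, hz = lz + cz;
    double dx = std::max({lx - p.x, 0.0, p.x - hx});
    double dy = std::max({ly - p.y, 0.0, p.y - hy});
    double dz = std::max({lz - p.z, 0.0, p.z - hz});
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  double closest_dist(const V3& p) {
    ++stamp;
    double best = std::numeric_limits<double>::infinity();
    int ci = idx(p.x, x0, cx, nx), cj = idx(p.y, y0, cy, ny), ck = idx(p.z, z0, cz, nz);
    const int rmax = std::max({nx, ny, nz});
    double ring_min;
    auto visit = [&](int i, int j, int k) {
      if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return;
      double lb = aabb_dist(p, i, j, k);
      ring_min = std::min(ring_min, lb);
      if (lb >= best) return;
      const size_t c = cell(i, j, k);
      for (int ii = cell_start[c]; ii < cell_start[c + 1]; ++ii) {
        const int f = cell_items[ii];
        if (mark[f] == stamp) continue;
        mark[f] = stamp;
        V3 q = closest_on_tri(p, P[fa[f]], P[fb[f]], P[fc[f]]);
        best = std::min(best, norm(p - q));
      }
    };
    for (int r = 0; r <= rmax; ++r) {
      ring_min = std::numeric_limits<double>::infinity();
      if (r == 0) {
        visit(ci, cj, ck);
      } else {
        // the six faces of the Chebyshev shell at radius r
        for (int j = cj - r; j <= cj + r; ++j)
          for (int k = ck - r; k <= ck + r; ++k) {
            visit(ci - r, j, k);
            visit(ci + r, j, k);
          }
        for (int i = ci - r + 1; i <= ci + r - 1; ++i)
          for (int k = ck - r; k <= ck + r; ++k) {
            visit(i, cj - r, k);
            visit(i, cj + r, k);
          }
        for (int i = ci - r + 1; i <= ci + r - 1; ++i)
          for (int j = cj - r + 1; j <= cj + r - 1; ++j) {
            visit(i, j, ck - r);
            visit(i, j, ck + r);
          }
      }
      if (ring_min >= best && std::isfinite(best)) break;
    }
    return best;
  }
};

std::vector<V3> fibonacci_sphere(int n) {
  std::vector<V3> d(n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - (2.0 * i + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * i;
    d[i] = {r * std::cos(phi), r * std::sin(phi), z};
  }
  return d;
}

void orthobasis(const V3& w, V3& u, V3& v) {
  V3 a = std::fabs(w.x) < 0.9 ? V3{1, 0, 0} : V3{0, 1, 0};
  u = cross(w, a);
  double n = norm(u);
  u = (1.0 / n) * u;
  v = cross(w, u);
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_obscurance(NumericMatrix verts, IntegerMatrix faces,
                             int n_samples) {
  TriGrid g;
  g.build(verts, faces);
  std::vector<V3> dirs = fibonacci_sphere(n_samples);
  const int nv = verts.nrow();
  NumericVector out(nv);
  const double tmin = 1e-6;
  for (int i = 0; i < nv; ++i) {
    V3 o = {verts(i, 0), verts(i, 1), verts(i, 2)};
    int escaped = 0;
    for (const V3& d : dirs)
      if (!g.ray_any_hit(o, d, i, tmin)) ++escaped;
    out[i] = (double)escaped / n_samples;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sdf(NumericMatrix verts, IntegerMatrix faces,
                      NumericMatrix normals, double cone_half_deg,
                      int n_rays, bool robust) {
  TriGrid g;
  g.build(verts, faces);
  const int nv = verts.nrow();
  NumericVector out(nv);
  const double cone = cone_half_deg * M_PI / 180.0;
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  const double tmin = 1e-6;
  std::vector<double> hits;
  for (int i = 0; i < nv; ++i) {
    V3 nrm = {normals(i, 0), normals(i, 1), normals(i, 2)};
    double nn = norm(nrm);
    if (nn < 1e-12) { out[i] = NA_REAL; continue; }
    V3 w = (-1.0 / nn) * nrm;  // inward
    V3 u, v;
    orthobasis(w, u, v);
    V3 o = {verts(i, 0), verts(i, 1), verts(i, 2)};
    hits.clear();
    for (int m = 0; m < n_rays; ++m) {
      double th = cone * std::sqrt((m + 0.5) / n_rays);
      double ph = ga * m;
      V3 d = std::cos(th) * w +
             std::sin(th) * (std::cos(ph) * u + std::sin(ph) * v);
      double t = g.ray_cast(o, d, i, tmin);
      if (std::isfinite(t)) hits.push_back(t);
    }
    if (hits.empty()) { out[i] = NA_REAL; continue; }
    if (!robust) {
      out[i] = *std::min_element(hits.begin(), hits.end());
    } else {
      std::sort(hits.begin(), hits.end());
      double med = hits[hits.size() / 2];
      double mean = 0, sd = 0;
      for (double h : hits) mean += h;
      mean /= hits.size();
      for (double h : hits) sd += (h - mean) * (h - mean);
      sd = std::sqrt(sd / std::max<size_t>(1, hits.size() - 1));
      std::vector<double> keep;
      for (double h : hits)
        if (std::fabs(h - med) <= sd) keep.push_back(h);
      if (keep.empty()) keep = hits;
      out[i] = keep[keep.size() / 2];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_closest_dist(NumericMatrix points, NumericMatrix verts,
                               IntegerMatrix faces) {
  TriGrid g;
  g.build(verts, faces);
  const int np = points.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i)
    out[i] = g.closest_dist({points(i, 0), points(i, 1), points(i, 2)});
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_vertex_normals(NumericMatrix verts, IntegerMatrix faces) {
  const int nv = verts.nrow(), nf = faces.nrow();
  NumericMatrix out(nv, 3);
  for (int f = 0; f < nf; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    V3 A = {verts(a, 0), verts(a, 1), verts(a, 2)};
    V3 B = {verts(b, 0), verts(b, 1), verts(b, 2)};
    V3 C = {verts(c, 0), verts(c, 1), verts(c, 2)};
    V3 n = cross(B - A, C - A);  // area-weighted
    for (int k : {a, b, c}) {
      out(k, 0) += n.x; out(k, 1) += n.y; out(k, 2) += n.z;
    }
  }
  for (int i = 0; i < nv; ++i) {
    double n = std::sqrt(out(i, 0) * out(i, 0) + out(i, 1) * out(i, 1) +
                         out(i, 2) * out(i, 2));
    if (n > 1e-14) {
      out(i, 0) /= n; out(i, 1) /= n; out(i, 2) /= n;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_taubin(NumericMatrix verts, IntegerMatrix faces, int iters,
                         double lambda, double mu) {
  const int nv = verts.nrow(), nf = faces.nrow();
  std::vector<std::vector<int>> nb(nv);
  for (int f = 0; f < nf; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    nb[a].push_back(b); nb[a].push_back(c);
    nb[b].push_back(a); nb[b].push_back(c);
    nb[c].push_back(a); nb[c].push_back(b);
  }
  for (auto& v : nb) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }
  std::vector<double> X(nv), Y(nv), Z(nv), X2(nv), Y2(nv), Z2(nv);
  for (int i = 0; i < nv; ++i) {
    X[i] = verts(i, 0); Y[i] = verts(i, 1); Z[i] = verts(i, 2);
  }
  auto step = [&](double fac) {
    for (int i = 0; i < nv; ++i) {
      if (nb[i].empty()) { X2[i] = X[i]; Y2[i] = Y[i]; Z2[i] = Z[i]; continue; }
      double mx = 0, my = 0, mz = 0;
      for (int j : nb[i]) { mx += X[j]; my += Y[j]; mz += Z[j]; }
      double n = (double)nb[i].size();
      X2[i] = X[i] + fac * (mx / n - X[i]);
      Y2[i] = Y[i] + fac * (my / n - Y[i]);
      Z2[i] = Z[i] + fac * (mz / n - Z[i]);
    }
    X.swap(X2); Y.swap(Y2); Z.swap(Z2);
  };
  for (int it = 0; it < iters; ++it) { step(lambda); step(mu); }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i) {
    out(i, 0) = X[i]; out(i, 1) = Y[i]; out(i, 2) = Z[i];
  }
  return out;
}

// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d > best) best = d;
    }
  return std::sqrt(best);
}

// Index (1-based) of the extreme vertex along each direction, plus the
// antipodal extreme; used to prune diameter searches without
// materialising the n x K projection matrix.
// [[Rcpp::export]]
IntegerVector cpp_extreme_points(NumericMatrix pts, NumericMatrix dirs) {
  const int n = pts.nrow(), k = dirs.nrow();
  IntegerVector out(2 * k);
  for (int d = 0; d < k; ++d) {
    const double dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    double lo = R_PosInf, hi = R_NegInf;
    int ilo = 0, ihi = 0;
    for (int i = 0; i < n; ++i) {
      const double p = pts(i, 0) * dx + pts(i, 1) * dy + pts(i, 2) * dz;
      if (p > hi) { hi = p; ihi = i; }
      if (p < lo) { lo = p; ilo = i; }
    }
    out[2 * d] = ihi + 1;
    out[2 * d + 1] = ilo + 1;
  }
  return out;
}
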