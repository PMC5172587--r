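// 3D grayscale morphology on 8-bit scalar volumes stored as R integer
// arrays with dim (nz, ny, nx) (column-major: idx = k + nz*(j + ny*i)).
// Structuring elements are digital spheres in voxel units; boundary
// handling pads dilation with -Inf and erosion with +Inf (out-of-bounds
// neighbours are ignored), the convention under which closing stays
// idempotent and extensive on the volume interior.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
using namespace Rcpp;

struct Off { int dz, dy, dx; };

static std::vector<Off> sphere_offsets(int r) {
  std::vector<Off> out;
  const int r2 = r * r;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dz * dz + dy * dy + dx * dx <= r2) out.push_back({dz, dy, dx});
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_grey_dilate(IntegerVector vol, int nz, int ny, int nx, int r) {
  std::vector<Off> off = sphere_offsets(r);
  IntegerVector out(clone(vol));
  const int* v = INTEGER(vol);
  int* o = INTEGER(out);
  // scatter from nonzero voxels: cheap on sparse stain masks
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        const int val = v[k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i)];
        if (val <= 0) continue;
        for (const Off& d : off) {
          const int kk = k + d.dz, jj = j + d.dy, ii = i + d.dx;
          if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
            continue;
          int* t = o + (kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii));
          if (*t < val) *t = val;
        }
      }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_grey_erode(IntegerVector vol, int nz, int ny, int nx, int r) {
  std::vector<Off> off = sphere_offsets(r);
  IntegerVector out(vol.size());
  const int* v = INTEGER(vol);
  int* o = INTEGER(out);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        const R_xlen_t idx = k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i);
        int m = v[idx];
        if (m == 0) { o[idx] = 0; continue; }
        for (const Off& d : off) {
          const int kk = k + d.dz, jj = j + d.dy, ii = i + d.dx;
          if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
            continue;
          const int val = v[kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii)];
          if (val < m) { m = val; if (m == 0) break; }
        }
        o[idx] = m;
      }
  return out;
}

// Fill enclosed background cavities: zero voxels not 6-connected to the
// volume border take the minimum positive intensity of their enclosing
// shell (the nonzero voxels 6-adjacent to the cavity).
// [[Rcpp::export]]
IntegerVector cpp_fill_holes(IntegerVector vol, int nz, int ny, int nx) {
  IntegerVector out(clone(vol));
  int* v = INTEGER(out);
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> visited(n, 0);
  auto at = [&](int k, int j, int i) { return k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i); };
  std::queue<R_xlen_t> q;
  // seed exterior flood from border zero voxels; singleton axes (e.g. a
  // single z-plane in per-slice mode) contribute no border of their own
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        const bool zb = nz > 1 && (k == 0 || k == nz - 1);
        const bool yb = ny > 1 && (j == 0 || j == ny - 1);
        const bool xb = nx > 1 && (i == 0 || i == nx - 1);
        if (!zb && !yb && !xb) continue;
        R_xlen_t idx = at(k, j, i);
        if (v[idx] == 0 && !visited[idx]) { visited[idx] = 1; q.push(idx); }
      }
  const int DZ[6] = {1, -1, 0, 0, 0, 0};
  const int DY[6] = {0, 0, 1, -1, 0, 0};
  const int DX[6] = {0, 0, 0, 0, 1, -1};
  auto flood = [&](std::queue<R_xlen_t>& qq, std::vector<R_xlen_t>* comp,
                   int* shell_min) {
    while (!qq.empty()) {
      R_xlen_t idx = qq.front(); qq.pop();
      if (comp) comp->push_back(idx);
      int i = (int)(idx / ((R_xlen_t)nz * ny));
      int rem = (int)(idx - (R_xlen_t)nz * ny * i);
      int j = rem / nz, k = rem % nz;
      for (int d = 0; d < 6; ++d) {
        int kk = k + DZ[d], jj = j + DY[d], ii = i + DX[d];
        if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
          continue;
        R_xlen_t nb = at(kk, jj, ii);
        if (v[nb] == 0) {
          if (!visited[nb]) { visited[nb] = 1; qq.push(nb); }
        } else if (shell_min && v[nb] < *shell_min) {
          *shell_min = v[nb];
        }
      }
    }
  };
  flood(q, nullptr, nullptr);
  // remaining unvisited zero voxels are cavities
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (v[idx] != 0 || visited[idx]) continue;
    std::vector<R_xlen_t> comp;
    int shell_min = 256;
    std::queue<R_xlen_t> qq;
    visited[idx] = 1; qq.push(idx);
    flood(qq, &comp, &shell_min);
    if (shell_min > 255) shell_min = 255;  // degenerate: cavity with no shell
    for (R_xlen_t c : comp) v[c] = shell_min;
  }
  return out;
}

// Separable 3D Gaussian blur, sigma in voxels, reflect boundary
// (scipy-style "reflect": [.. b a | a b ..]), kernel truncated at 4 sigma
// and renormalised so flat regions are preserved.
// [[Rcpp::export]]
IntegerVector cpp_gaussian_blur(IntegerVector vol, int nz, int ny, int nx,
                                double sigma) {
  const int rad = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + rad];
  }
  for (double& w : ker) w /= s;
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(n), b(n);
  for (R_xlen_t idx = 0; idx < n; ++idx) a[idx] = INTEGER(vol)[idx];
  auto reflect = [](int p, int len) {
    while (p < 0 || p >= len) {
      if (p < 0) p = -p - 1;
      if (p >= len) p = 2 * len - p - 1;
    }
    return p;
  };
  auto pass = [&](std::vector<double>& src, std::vector<double>& dst,
                  int axis) {
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j)
        for (int k = 0; k < nz; ++k) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int kk = k, jj = j, ii = i;
            if (axis == 0) kk = reflect(k + t, nz);
            else if (axis == 1) jj = reflect(j + t, ny);
            else ii = reflect(i + t, nx);
            acc += ker[t + rad] *
                   src[kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii)];
          }
          dst[k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i)] = acc;
        }
  };
  pass(a, b, 0); pass(b, a, 1); pass(a, b, 2);
  IntegerVector out(n);
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    double r = std::round(b[idx]);
    out[idx] = (int)std::min(255.0, std::max(0.0, r));
  }
  out.attr("dim") = IntegerVector::create(nz, ny, nx);
  return out;
}
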