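// Dense optical flow by polynomial expansion (Farneback-style):
// each image is locally approximated by a quadratic polynomial under a
// Gaussian applicability window; displacement is solved from the change of
// the linear term, aggregated over a box window, iterated over an image
// pyramid coarse-to-fine. Used to synthesize intermediate planes between
// consecutive serial sections.
//
// Images are ny x nx matrices (rows = y). Flow (u, v) maps content of the
// first image to the second: I1(x, y) ~ I2(x + u, y + v).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Field {
  int ny, nx;
  std::vector<double> d;
  Field(int ny_, int nx_) : ny(ny_), nx(nx_), d((size_t)ny_ * nx_, 0.0) {}
  double& at(int y, int x) { return d[(size_t)y * nx + x]; }
  double at(int y, int x) const { return d[(size_t)y * nx + x]; }
};

int reflect(int p, int len) {
  while (p < 0 || p >= len) {
    if (p < 0) p = -p - 1;
    if (p >= len) p = 2 * len - p - 1;
  }
  return p;
}

double bilin(const Field& f, double x, double y) {
  if (x < 0) x = 0; if (x > f.nx - 1) x = f.nx - 1;
  if (y < 0) y = 0; if (y > f.ny - 1) y = f.ny - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, f.nx - 1), y1 = std::min(y0 + 1, f.ny - 1);
  double fx = x - x0, fy = y - y0;
  return (1 - fy) * ((1 - fx) * f.at(y0, x0) + fx * f.at(y0, x1)) +
         fy * ((1 - fx) * f.at(y1, x0) + fx * f.at(y1, x1));
}

// Per-pixel quadratic fit I(dx,dy) ~ c + b.(dx,dy) + (dx,dy)' A (dx,dy)
// via separable Gaussian-weighted moment correlations.
struct PolyExp {
  Field a11, a12, a22, b1, b2;
  PolyExp(int ny, int nx)
      : a11(ny, nx), a12(ny, nx), a22(ny, nx), b1(ny, nx), b2(ny, nx) {}
};

void poly_exp(const Field& img, double sigma, PolyExp& out) {
  const int ny = img.ny, nx = img.nx;
  const int rad = std::max(2, (int)std::ceil(2.5 * sigma));
  std::vector<double> g(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; ++t) {
    g[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += g[t + rad];
  }
  for (double& w : g) w /= s;
  double S2 = 0, S4 = 0;
  for (int t = -rad; t <= rad; ++t) {
    S2 += g[t + rad] * t * t;
    S4 += g[t + rad] * t * t * t * t;
  }
  const double denom = S4 - S2 * S2;
  // row pass: R_p(y,x) = sum_t t^p g(t) I(y, x+t)
  Field R0(ny, nx), R1(ny, nx), R2(ny, nx);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double m0 = 0, m1 = 0, m2 = 0;
      for (int t = -rad; t <= rad; ++t) {
        double v = img.at(y, reflect(x + t, nx));
        double w = g[t + rad];
        m0 += w * v; m1 += w * t * v; m2 += w * t * t * v;
      }
      R0.at(y, x) = m0; R1.at(y, x) = m1; R2.at(y, x) = m2;
    }
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double m00 = 0, m10 = 0, m01 = 0, m20 = 0, m02 = 0, m11 = 0;
      for (int t = -rad; t <= rad; ++t) {
        int yy = reflect(y + t, ny);
        double w = g[t + rad];
        m00 += w * R0.at(yy, x);
        m10 += w * R1.at(yy, x);
        m01 += w * t * R0.at(yy, x);
        m20 += w * R2.at(yy, x);
        m02 += w * t * t * R0.at(yy, x);
        m11 += w * t * R1.at(yy, x);
      }
      out.b1.at(y, x) = m10 / S2;             // d/dx
      out.b2.at(y, x) = m01 / S2;             // d/dy
      out.a11.at(y, x) = (m20 - S2 * m00) / denom;
      out.a22.at(y, x) = (m02 - S2 * m00) / denom;
      out.a12.at(y, x) = 0.5 * m11 / (S2 * S2);
    }
}

// box blur with clamped window, normalised by actual count
void box_blur(Field& f, int win) {
  const int r = win / 2;
  if (r < 1) return;
  Field tmp(f.ny, f.nx);
  for (int y = 0; y < f.ny; ++y) {
    double acc = 0; int cnt = 0;
    for (int x = 0; x <= std::min(r, f.nx - 1); ++x) { acc += f.at(y, x); ++cnt; }
    for (int x = 0; x < f.nx; ++x) {
      tmp.at(y, x) = acc / cnt;
      int add = x + r + 1, rem = x - r;
      if (add < f.nx) { acc += f.at(y, add); ++cnt; }
      if (rem >= 0) { acc -= f.at(y, rem); --cnt; }
    }
  }
  for (int x = 0; x < f.nx; ++x) {
    double acc = 0; int cnt = 0;
    for (int y = 0; y <= std::min(r, f.ny - 1); ++y) { acc += tmp.at(y, x); ++cnt; }
    for (int y = 0; y < f.ny; ++y) {
      f.at(y, x) = acc / cnt;
      int add = y + r + 1, rem = y - r;
      if (add < f.ny) { acc += tmp.at(add, x); ++cnt; }
      if (rem >= 0) { acc -= tmp.at(rem, x); --cnt; }
    }
  }
}

Field downsample(const Field& f) {
  // Gaussian presmooth sigma 1, then take every second pixel
  const int rad = 2;
  const double kern[5] = {0.0545, 0.2442, 0.4026, 0.2442, 0.0545};
  Field sm(f.ny, f.nx), sm2(f.ny, f.nx);
  for (int y = 0; y < f.ny; ++y)
    for (int x = 0; x < f.nx; ++x) {
      double acc = 0;
      for (int t = -rad; t <= rad; ++t)
        acc += kern[t + rad] * f.at(y, reflect(x + t, f.nx));
      sm.at(y, x) = acc;
    }
  for (int y = 0; y < f.ny; ++y)
    for (int x = 0; x < f.nx; ++x) {
      double acc = 0;
      for (int t = -rad; t <= rad; ++t)
        acc += kern[t + rad] * sm.at(reflect(y + t, f.ny), x);
      sm2.at(y, x) = acc;
    }
  Field out((f.ny + 1) / 2, (f.nx + 1) / 2);
  for (int y = 0; y < out.ny; ++y)
    for (int x = 0; x < out.nx; ++x) out.at(y, x) = sm2.at(2 * y, 2 * x);
  return out;
}

Field resize_flow(const Field& f, int ny, int nx, double scale) {
  Field out(ny, nx);
  const double sy = (double)f.ny / ny, sx = (double)f.nx / nx;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      out.at(y, x) = scale * bilin(f, (x + 0.5) * sx - 0.5, (y + 0.5) * sy - 0.5);
  return out;
}

void flow_level(const PolyExp& p1, const PolyExp& p2, Field& u, Field& v,
                int winsize, int iters) {
  const int ny = u.ny, nx = u.nx;
  for (int it = 0; it < iters; ++it) {
    Field g11(ny, nx), g12(ny, nx), g22(ny, nx), h1(ny, nx), h2(ny, nx);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double du = u.at(y, x), dv = v.at(y, x);
        int x2 = (int)std::lround(x + du), y2 = (int)std::lround(y + dv);
        if (x2 < 0) x2 = 0; if (x2 > nx - 1) x2 = nx - 1;
        if (y2 < 0) y2 = 0; if (y2 > ny - 1) y2 = ny - 1;
        double a11 = 0.5 * (p1.a11.at(y, x) + p2.a11.at(y2, x2));
        double a12 = 0.5 * (p1.a12.at(y, x) + p2.a12.at(y2, x2));
        double a22 = 0.5 * (p1.a22.at(y, x) + p2.a22.at(y2, x2));
        double db1 = -0.5 * (p2.b1.at(y2, x2) - p1.b1.at(y, x)) +
                     a11 * du + a12 * dv;
        double db2 = -0.5 * (p2.b2.at(y2, x2) - p1.b2.at(y, x)) +
                     a12 * du + a22 * dv;
        g11.at(y, x) = a11 * a11 + a12 * a12;
        g12.at(y, x) = a11 * a12 + a12 * a22;
        g22.at(y, x) = a12 * a12 + a22 * a22;
        h1.at(y, x) = a11 * db1 + a12 * db2;
        h2.at(y, x) = a12 * db1 + a22 * db2;
      }
    box_blur(g11, winsize); box_blur(g12, winsize); box_blur(g22, winsize);
    box_blur(h1, winsize); box_blur(h2, winsize);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double det = g11.at(y, x) * g22.at(y, x) - g12.at(y, x) * g12.at(y, x);
        if (std::fabs(det) > 1e-9) {
          u.at(y, x) = (g22.at(y, x) * h1.at(y, x) - g12.at(y, x) * h2.at(y, x)) / det;
          v.at(y, x) = (g11.at(y, x) * h2.at(y, x) - g12.at(y, x) * h1.at(y, x)) / det;
        }
      }
  }
}

Field from_matrix(const NumericMatrix& m) {
  Field f(m.nrow(), m.ncol());
  for (int y = 0; y < f.ny; ++y)
    for (int x = 0; x < f.nx; ++x) f.at(y, x) = m(y, x);
  return f;
}

}  // namespace

// [[Rcpp::export]]
List cpp_farneback(NumericMatrix img1, NumericMatrix img2, int levels,
                   int winsize, int iters, double poly_sigma) {
  std::vector<Field> pyr1, pyr2;
  pyr1.push_back(from_matrix(img1));
  pyr2.push_back(from_matrix(img2));
  for (int l = 1; l < levels; ++l) {
    if (std::min(pyr1.back().ny, pyr1.back().nx) < 24) break;
    pyr1.push_back(downsample(pyr1.back()));
    pyr2.push_back(downsample(pyr2.back()));
  }
  const int top = (int)pyr1.size() - 1;
  Field u(pyr1[top].ny, pyr1[top].nx), v(pyr1[top].ny, pyr1[top].nx);
  for (int l = top; l >= 0; --l) {
    if (l != top) {
      u = resize_flow(u, pyr1[l].ny, pyr1[l].nx, 2.0);
      v = resize_flow(v, pyr1[l].ny, pyr1[l].nx, 2.0);
    }
    PolyExp p1(pyr1[l].ny, pyr1[l].nx), p2(pyr1[l].ny, pyr1[l].nx);
    poly_exp(pyr1[l], poly_sigma, p1);
    poly_exp(pyr2[l], poly_sigma, p2);
    flow_level(p1, p2, u, v, winsize, iters);
  }
  NumericMatrix U(img1.nrow(), img1.ncol()), V(img1.nrow(), img1.ncol());
  for (int y = 0; y < img1.nrow(); ++y)
    for (int x = 0; x < img1.ncol(); ++x) {
      U(y, x) = u.at(y, x);
      V(y, x) = v.at(y, x);
    }
  return List::create(Named("u") = U, Named("v") = V);
}

// Symmetric flow-warped blend at fraction t of the gap between img1 and
// img2, using forward flow (uf, vf: 1->2) and backward flow (ub, vb: 2->1).
// [[Rcpp::export]]
NumericMatrix cpp_flow_interp(NumericMatrix img1, NumericMatrix img2,
                              NumericMatrix uf, NumericMatrix vf,
                              NumericMatrix ub, NumericMatrix vb, double t) {
  const int ny = img1.nrow(), nx = img1.ncol();
  Field f1 = from_matrix(img1), f2 = from_matrix(img2);
  NumericMatrix out(ny, nx);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double s1 = bilin(f1, x - t * uf(y, x), y - t * vf(y, x));
      double s2 = bilin(f2, x - (1 - t) * ub(y, x), y - (1 - t) * vb(y, x));
      out(y, x) = (1 - t) * s1 + t * s2;
    }
  return out;
}
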