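#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Siddon ray tracing through a square pixel grid centred at the origin.
// Coordinates in mm; returned intersection lengths in cm (so that
// mu [cm^-1] * length [cm] gives a dimensionless line integral).
// Pixel (ix, iy), 0-based, has x-range [xmin + ix*h, xmin + (ix+1)*h],
// column index j = ix + iy*n (matches as.vector() of an R matrix [x, y]).

namespace {

struct Hit {
  std::vector<int> pix;
  std::vector<double> len_cm;
};

void trace_one(double p0x, double p0y, double p1x, double p1y,
               int n, double h, Hit &out) {
  out.pix.clear();
  out.len_cm.clear();
  const double xmin = -0.5 * n * h;
  const double xmax = 0.5 * n * h;
  const double dx = p1x - p0x;
  const double dy = p1y - p0y;
  const double raylen = std::sqrt(dx * dx + dy * dy);
  if (raylen <= 0.0) stop("degenerate (zero-length) ray");

  double amin = 0.0, amax = 1.0;
  const double eps = 1e-12;

  // slab clipping against x and y extents
  if (std::fabs(dx) > eps) {
    double a1 = (xmin - p0x) / dx, a2 = (xmax - p0x) / dx;
    if (a1 > a2) std::swap(a1, a2);
    amin = std::max(amin, a1);
    amax = std::min(amax, a2);
  } else if (p0x <= xmin || p0x >= xmax) {
    return;  // parallel to y-planes and outside the slab
  }
  if (std::fabs(dy) > eps) {
    double a1 = (xmin - p0y) / dy, a2 = (xmax - p0y) / dy;
    if (a1 > a2) std::swap(a1, a2);
    amin = std::max(amin, a1);
    amax = std::min(amax, a2);
  } else if (p0y <= xmin || p0y >= xmax) {
    return;
  }
  if (amin >= amax - eps) return;  // misses the grid

  // parametric crossings of interior grid lines
  std::vector<double> alphas;
  alphas.reserve(2 * n + 4);
  alphas.push_back(amin);
  alphas.push_back(amax);
  if (std::fabs(dx) > eps) {
    for (int i = 0; i <= n; ++i) {
      double a = (xmin + i * h - p0x) / dx;
      if (a > amin + eps && a < amax - eps) alphas.push_back(a);
    }
  }
  if (std::fabs(dy) > eps) {
    for (int i = 0; i <= n; ++i) {
      double a = (xmin + i * h - p0y) / dy;
      if (a > amin + eps && a < amax - eps) alphas.push_back(a);
    }
  }
  std::sort(alphas.begin(), alphas.end());

  for (size_t k = 0; k + 1 < alphas.size(); ++k) {
    double a0 = alphas[k], a1 = alphas[k + 1];
    double seg = (a1 - a0) * raylen;
    if (seg <= eps * raylen) continue;
    double am = 0.5 * (a0 + a1);
    double px = p0x + am * dx, py = p0y + am * dy;
    int ix = (int)std::floor((px - xmin) / h);
    int iy = (int)std::floor((py - xmin) / h);
    if (ix < 0 || ix >= n || iy < 0 || iy >= n) continue;
    out.pix.push_back(ix + iy * n);
    out.len_cm.push_back(seg / 10.0);  // mm -> cm
  }
}

}  // namespace

// [[Rcpp::export]]
List siddon_trace_cpp(NumericVector p0, NumericVector p1, int n, double h) {
  Hit hit;
  trace_one(p0[0], p0[1], p1[0], p1[1], n, h, hit);
  return List::create(_["pixel"] = wrap(hit.pix),
                      _["length_cm"] = wrap(hit.len_cm));
}

// Trace every (view, detector) ray of a fan-beam geometry and return
// triplets for a sparse system matrix (rows = rays, cols = pixels).
// [[Rcpp::export]]
List siddon_system_cpp(NumericVector src_x, NumericVector src_y,
                       NumericMatrix det_x, NumericMatrix det_y,
                       int n, double h) {
  const int n_views = src_x.size();
  const int n_det = det_x.nrow();
  std::vector<int> ri, ci;
  std::vector<double> vv;
  ri.reserve((size_t)n_views * n_det * 2 * n);
  ci.reserve((size_t)n_views * n_det * 2 * n);
  vv.reserve((size_t)n_views * n_det * 2 * n);
  Hit hit;
  for (int v = 0; v < n_views; ++v) {
    for (int d = 0; d < n_det; ++d) {
      trace_one(src_x[v], src_y[v], det_x(d, v), det_y(d, v), n, h, hit);
      int row = d + v * n_det;  // detector fastest, matches R vectorisation
      for (size_t k = 0; k < hit.pix.size(); ++k) {
        ri.push_back(row);
        ci.push_back(hit.pix[k]);
        vv.push_back(hit.len_cm[k]);
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci),
                      _["x"] = wrap(vv));
}

// Distance-weighted fan-beam backprojection of one filtered sinogram
// frame. qf: n_det x n_views filtered projections; gamma grid is
// equiangular with spacing dgamma centred on gamma = 0; beta: view
// angles (rad); pixel coords in cm relative to isocentre; source at
// radius sid_cm. Linear interpolation in the detector coordinate.
// [[Rcpp::export]]
NumericVector fan_backproject_cpp(NumericMatrix qf, NumericVector beta,
                                  NumericVector px, NumericVector py,
                                  double sid_cm, double dgamma,
                                  double dbeta) {
  const int n_det = qf.nrow();
  const int n_views = qf.ncol();
  const int n_pix = px.size();
  const double g0 = -0.5 * (n_det - 1) * dgamma;
  NumericVector img(n_pix);
  for (int v = 0; v < n_views; ++v) {
    const double cb = std::cos(beta[v]), sb = std::sin(beta[v]);
    const double sx = sid_cm * cb, sy = sid_cm * sb;
    for (int p = 0; p < n_pix; ++p) {
      const double rx = px[p] - sx, ry = py[p] - sy;
      const double L2 = rx * rx + ry * ry;
      // angle of the ray through this pixel relative to the central ray
      // central direction is -(cb, sb); positive gamma matches the
      // detector ordering used in scan_geometry()
      const double dot = -(rx * cb + ry * sb);
      const double crs = -(ry * cb - rx * sb);
      const double gamma = std::atan2(crs, dot);
      const double t = (gamma - g0) / dgamma;
      const int k = (int)std::floor(t);
      if (k < 0 || k >= n_det - 1) continue;
      const double w = t - k;
      const double q = (1.0 - w) * qf(k, v) + w * qf(k + 1, v);
      img[p] += dbeta * q / L2;
    }
  }
  return img;
}
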