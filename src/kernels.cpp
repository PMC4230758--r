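// Core numerical kernels: exact voxel-boundary (Siddon-style) ray
// integration of water-equivalent path length, pencil-beam dose
// superposition, trilinear sampling and fixed-point inversion of
// deformation fields.  Grids are R arrays in column-major order
// (x fastest), voxel centers at origin + index * spacing (mm).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Grid {
  const double* val;
  int nx, ny, nz;
  double sp[3];
  double org[3];   // world coordinate of voxel (0,0,0) center
  double lo[3], hi[3]; // outer box faces

  Grid(const NumericVector& v, const IntegerVector& dim,
       const NumericVector& spacing, const NumericVector& origin) {
    val = v.begin();
    nx = dim[0]; ny = dim[1]; nz = dim[2];
    int n[3] = {nx, ny, nz};
    for (int a = 0; a < 3; ++a) {
      sp[a] = spacing[a];
      org[a] = origin[a];
      lo[a] = org[a] - 0.5 * sp[a];
      hi[a] = org[a] + (n[a] - 0.5) * sp[a];
    }
  }
  inline double at(int i, int j, int k) const {
    return val[i + (size_t)nx * (j + (size_t)ny * k)];
  }
  inline int clampi(int i, int n) const {
    return i < 0 ? 0 : (i >= n ? n - 1 : i);
  }
  // trilinear sample at world point, edge-clamped
  double tri(const double* p) const {
    double g[3];
    int n[3] = {nx, ny, nz};
    int i0[3]; double f[3];
    for (int a = 0; a < 3; ++a) {
      g[a] = (p[a] - org[a]) / sp[a];
      if (g[a] < 0) g[a] = 0;
      if (g[a] > n[a] - 1) g[a] = n[a] - 1;
      i0[a] = (int)std::floor(g[a]);
      if (i0[a] > n[a] - 2) i0[a] = n[a] >= 2 ? n[a] - 2 : 0;
      f[a] = g[a] - i0[a];
      if (n[a] == 1) { i0[a] = 0; f[a] = 0.0; }
    }
    double acc = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? f[0] : 1 - f[0]) * (dj ? f[1] : 1 - f[1]) *
                     (dk ? f[2] : 1 - f[2]);
          if (w == 0.0) continue;
          acc += w * at(clampi(i0[0] + di, nx), clampi(i0[1] + dj, ny),
                        clampi(i0[2] + dk, nz));
        }
    return acc;
  }
};

// Clip parametric segment p = a + t*d, t in [t0,t1], against the grid box.
// Returns false when the segment misses the box.
inline bool clip_box(const Grid& g, const double* a, const double* d,
                     double& t0, double& t1) {
  for (int ax = 0; ax < 3; ++ax) {
    if (std::fabs(d[ax]) < 1e-14) {
      if (a[ax] < g.lo[ax] || a[ax] > g.hi[ax]) return false;
    } else {
      double ta = (g.lo[ax] - a[ax]) / d[ax];
      double tb = (g.hi[ax] - a[ax]) / d[ax];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 >= t1) return false;
    }
  }
  return t0 < t1;
}

// Amanatides-Woo voxel walk along a + t*d (d unit length), t in [t0,t1].
// Calls visit(i, j, k, seg_len, t_seg_start, t_seg_end) per traversed voxel.
template <typename F>
inline void walk(const Grid& g, const double* a, const double* d,
                 double t0, double t1, F visit) {
  const double eps = 1e-9;
  double t = t0;
  double p[3];
  for (int ax = 0; ax < 3; ++ax) p[ax] = a[ax] + (t0 + eps) * d[ax];
  int idx[3];
  int n[3] = {g.nx, g.ny, g.nz};
  for (int ax = 0; ax < 3; ++ax) {
    int i = (int)std::floor((p[ax] - g.lo[ax]) / g.sp[ax]);
    idx[ax] = i < 0 ? 0 : (i >= n[ax] ? n[ax] - 1 : i);
  }
  double tmax[3], tdelta[3];
  int step[3];
  for (int ax = 0; ax < 3; ++ax) {
    if (d[ax] > 1e-14) {
      step[ax] = 1;
      tdelta[ax] = g.sp[ax] / d[ax];
      tmax[ax] = ((g.lo[ax] + (idx[ax] + 1) * g.sp[ax]) - a[ax]) / d[ax];
    } else if (d[ax] < -1e-14) {
      step[ax] = -1;
      tdelta[ax] = -g.sp[ax] / d[ax];
      tmax[ax] = ((g.lo[ax] + idx[ax] * g.sp[ax]) - a[ax]) / d[ax];
    } else {
      step[ax] = 0;
      tdelta[ax] = 0;
      tmax[ax] = std::numeric_limits<double>::infinity();
    }
  }
  while (t < t1 - eps) {
    int ax = 0;
    if (tmax[1] < tmax[ax]) ax = 1;
    if (tmax[2] < tmax[ax]) ax = 2;
    double tn = std::min(tmax[ax], t1);
    if (tn > t) visit(idx[0], idx[1], idx[2], tn - t, t, tn);
    t = tn;
    if (tmax[ax] >= t1) break;
    idx[ax] += step[ax];
    if (idx[ax] < 0 || idx[ax] >= n[ax]) break;
    tmax[ax] += tdelta[ax];
  }
}

// WEPL of the segment from world point A to B (exact Siddon sum).
inline double integrate_segment(const Grid& g, const double* A,
                                const double* B) {
  double d[3], L2 = 0.0;
  for (int ax = 0; ax < 3; ++ax) { d[ax] = B[ax] - A[ax]; L2 += d[ax] * d[ax]; }
  double L = std::sqrt(L2);
  if (L < 1e-12) return 0.0;
  double u[3];
  for (int ax = 0; ax < 3; ++ax) u[ax] = d[ax] / L;
  double t0 = 0.0, t1 = L;
  if (!clip_box(g, A, u, t0, t1)) return 0.0;
  double acc = 0.0;
  walk(g, A, u, t0, t1,
       [&](int i, int j, int k, double len, double, double) {
         acc += g.at(i, j, k) * len;
       });
  return acc;
}

inline double backoff_distance(const Grid& g) {
  double dx = g.hi[0] - g.lo[0], dy = g.hi[1] - g.lo[1], dz = g.hi[2] - g.lo[2];
  return 2.0 * std::sqrt(dx * dx + dy * dy + dz * dz) + 10.0;
}

}  // namespace

// Cumulative WEPL profile along one ray.  The ray passes through
// `point` with unit direction `dir`; depth 0 is the entry into the grid.
// Returns a matrix with columns (depth_mm, wepl_mm) at every voxel
// boundary crossing (first row 0,0).
// [[Rcpp::export]]
NumericMatrix cpp_trace_profile(NumericVector density, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericVector point, NumericVector dir) {
  Grid g(density, dim, spacing, origin);
  double big = backoff_distance(g);
  double a[3], d[3] = {dir[0], dir[1], dir[2]};
  for (int ax = 0; ax < 3; ++ax) a[ax] = point[ax] - big * d[ax];
  double t0 = 0.0, t1 = 2.0 * big;
  if (!clip_box(g, a, d, t0, t1)) return NumericMatrix(0, 2);
  std::vector<double> depth, wepl;
  depth.push_back(0.0); wepl.push_back(0.0);
  double acc = 0.0;
  walk(g, a, d, t0, t1,
       [&](int i, int j, int k, double len, double, double te) {
         acc += g.at(i, j, k) * len;
         depth.push_back(te - t0);
         wepl.push_back(acc);
       });
  NumericMatrix out(depth.size(), 2);
  for (size_t r = 0; r < depth.size(); ++r) {
    out(r, 0) = depth[r];
    out(r, 1) = wepl[r];
  }
  colnames(out) = CharacterVector::create("depth_mm", "wepl_mm");
  return out;
}

// WEPL from the grid entry along `dir` up to each query point.
// [[Rcpp::export]]
NumericVector cpp_wepl_points(NumericVector density, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              NumericVector dir, NumericMatrix pts) {
  Grid g(density, dim, spacing, origin);
  double big = backoff_distance(g);
  int n = pts.nrow();
  NumericVector out(n);
  double d[3] = {dir[0], dir[1], dir[2]};
  for (int r = 0; r < n; ++r) {
    double B[3] = {pts(r, 0), pts(r, 1), pts(r, 2)};
    double A[3];
    for (int ax = 0; ax < 3; ++ax) A[ax] = B[ax] - big * d[ax];
    out[r] = integrate_segment(g, A, B);
  }
  return out;
}

// Per-ray WEPL at the proximal entry into and distal exit from a mask.
// starts: N x 3 world points on each ray (any point; the ray is the full
// line through it along dir).  Returns N x 3: hit flag, wepl at first
// mask-voxel entry face, wepl at last mask-voxel exit face.
// [[Rcpp::export]]
NumericMatrix cpp_ray_mask_wepl(NumericVector density, IntegerVector mask,
                                IntegerVector dim, NumericVector spacing,
                                NumericVector origin, NumericMatrix starts,
                                NumericVector dir) {
  Grid g(density, dim, spacing, origin);
  const int* m = mask.begin();
  double big = backoff_distance(g);
  int n = starts.nrow();
  NumericMatrix out(n, 3);
  double d[3] = {dir[0], dir[1], dir[2]};
  for (int r = 0; r < n; ++r) {
    double a[3];
    for (int ax = 0; ax < 3; ++ax) a[ax] = starts(r, ax) - big * d[ax];
    double t0 = 0.0, t1 = 2.0 * big;
    out(r, 0) = 0.0; out(r, 1) = NA_REAL; out(r, 2) = NA_REAL;
    if (!clip_box(g, a, d, t0, t1)) continue;
    double acc = 0.0;
    bool seen = false;
    double win = NA_REAL, wout = NA_REAL;
    walk(g, a, d, t0, t1,
         [&](int i, int j, int k, double len, double, double) {
           bool in = m[i + (size_t)g.nx * (j + (size_t)g.ny * k)] != 0;
           if (in && !seen) { win = acc; seen = true; }
           acc += g.at(i, j, k) * len;
           if (in) wout = acc;
         });
    if (seen) { out(r, 0) = 1.0; out(r, 1) = win; out(r, 2) = wout; }
  }
  colnames(out) = CharacterVector::create("hit", "wepl_in", "wepl_out");
  return out;
}

namespace {
inline double depth_dose(double x, double p_tail, double s_rise,
                         double s_fall) {
  if (x <= 0.0) {
    return p_tail + (1.0 - p_tail) * std::exp(-x * x / (2.0 * s_rise * s_rise));
  }
  if (x > 6.0 * s_fall) return 0.0;
  return std::exp(-x * x / (2.0 * s_fall * s_fall));
}
}  // namespace

// Pristine-peak relative depth-dose vs (WEPL - layer range), peak 1 at 0:
// proximal plateau p_tail rising over ~s_rise mm, distal Gaussian falloff
// with sigma s_fall mm.
// [[Rcpp::export]]
NumericVector cpp_depth_profile(NumericVector x, double p_tail, double s_rise,
                                double s_fall) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = depth_dose(x[i], p_tail, s_rise, s_fall);
  return out;
}

// Superpose pencil-beam spots onto voxels described in beam's-eye-view
// coordinates.  wepl/u/v: per-voxel WEPL and lateral coordinates.
// spots: M x 4 (u_mm, v_mm, range_wepl_mm, weight).  Lateral kernel is an
// unnormalized Gaussian exp(-r^2/(2 sigma^2)) cut at cutoff*sigma per axis.
// [[Rcpp::export]]
NumericVector cpp_spot_dose(NumericVector wepl, NumericVector u,
                            NumericVector v, NumericMatrix spots,
                            double sigma, double p_tail, double s_rise,
                            double s_fall, double cutoff) {
  int n = wepl.size(), m = spots.nrow();
  NumericVector dose(n);
  if (m == 0 || n == 0) return dose;
  // sort voxels by u for windowed lookup
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return u[a] < u[b]; });
  std::vector<double> us(n);
  for (int i = 0; i < n; ++i) us[i] = u[ord[i]];
  double cut = cutoff * sigma;
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int s = 0; s < m; ++s) {
    double su = spots(s, 0), sv = spots(s, 1), rng = spots(s, 2),
           w = spots(s, 3);
    if (w == 0.0) continue;
    int a = std::lower_bound(us.begin(), us.end(), su - cut) - us.begin();
    int b = std::upper_bound(us.begin(), us.end(), su + cut) - us.begin();
    for (int q = a; q < b; ++q) {
      int i = ord[q];
      double dv = v[i] - sv;
      if (dv > cut || dv < -cut) continue;
      double du = us[q] - su;
      double x = wepl[i] - rng;
      double dp = depth_dose(x, p_tail, s_rise, s_fall);
      if (dp == 0.0) continue;
      dose[i] += w * std::exp(-(du * du + dv * dv) * inv2s2) * dp;
    }
  }
  return dose;
}

// Sparse dose-influence triplets (voxel i, spot j, unit-weight dose).
// [[Rcpp::export]]
List cpp_influence(NumericVector wepl, NumericVector u, NumericVector v,
                   NumericMatrix spots, double sigma, double p_tail,
                   double s_rise, double s_fall, double cutoff,
                   double thresh) {
  int n = wepl.size(), m = spots.nrow();
  std::vector<int> ii, jj;
  std::vector<double> xx;
  double cut = cutoff * sigma;
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return u[a] < u[b]; });
  std::vector<double> us(n);
  for (int i = 0; i < n; ++i) us[i] = u[ord[i]];
  for (int s = 0; s < m; ++s) {
    double su = spots(s, 0), sv = spots(s, 1), rng = spots(s, 2);
    int a = std::lower_bound(us.begin(), us.end(), su - cut) - us.begin();
    int b = std::upper_bound(us.begin(), us.end(), su + cut) - us.begin();
    for (int q = a; q < b; ++q) {
      int i = ord[q];
      double dv = v[i] - sv;
      if (dv > cut || dv < -cut) continue;
      double du = us[q] - su;
      double val = std::exp(-(du * du + dv * dv) * inv2s2) *
                   depth_dose(wepl[i] - rng, p_tail, s_rise, s_fall);
      if (val > thresh) {
        ii.push_back(i + 1);
        jj.push_back(s + 1);
        xx.push_back(val);
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["x"] = wrap(xx));
}

// Trilinear sampling of a grid at world points (edge-clamped).
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts) {
  Grid g(vol, dim, spacing, origin);
  int n = pts.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    double p[3] = {pts(r, 0), pts(r, 1), pts(r, 2)};
    out[r] = g.tri(p);
  }
  return out;
}

// Pull a phase volume back to reference voxel centers through a
// phase-to-reference displacement field d (mm, sampled on the phase grid):
// for each reference center r solve x + d(x) = r by fixed-point iteration,
// then sample the phase volume at x trilinearly.
// [[Rcpp::export]]
NumericVector cpp_pullback(NumericVector vol, NumericVector defx,
                           NumericVector defy, NumericVector defz,
                           IntegerVector dim, NumericVector spacing,
                           NumericVector origin, double tol_mm, int maxit) {
  Grid g(vol, dim, spacing, origin);
  Grid gx(defx, dim, spacing, origin);
  Grid gy(defy, dim, spacing, origin);
  Grid gz(defz, dim, spacing, origin);
  size_t n = (size_t)g.nx * g.ny * g.nz;
  NumericVector out(n);
  double tol2 = tol_mm * tol_mm;
  size_t q = 0;
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i, ++q) {
        double r[3] = {g.org[0] + i * g.sp[0], g.org[1] + j * g.sp[1],
                       g.org[2] + k * g.sp[2]};
        double x[3] = {r[0], r[1], r[2]};
        for (int it = 0; it < maxit; ++it) {
          double nx0 = r[0] - gx.tri(x);
          double ny0 = r[1] - gy.tri(x);
          double nz0 = r[2] - gz.tri(x);
          double dd = (nx0 - x[0]) * (nx0 - x[0]) +
                      (ny0 - x[1]) * (ny0 - x[1]) +
                      (nz0 - x[2]) * (nz0 - x[2]);
          x[0] = nx0; x[1] = ny0; x[2] = nz0;
          if (dd < tol2) break;
        }
        out[q] = g.tri(x);
      }
  return out;
}

// Coordinate-descent NNLS on a sparse column-compressed matrix:
// minimize ||A w - p||^2 subject to w >= 0.  Monotone in the objective;
// stops when the residual norm improves by less than tol (relative)
// over a 10-sweep window.
// [[Rcpp::export]]
List cpp_nnls_cd(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                 int nrow, NumericVector p, int max_sweeps, double tol) {
  int m = Ap.size() - 1;
  std::vector<double> w(m, 0.0), r(nrow);
  for (int i = 0; i < nrow; ++i) r[i] = -p[i];
  std::vector<double> cnorm(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int q = Ap[j]; q < Ap[j + 1]; ++q) s += Ax[q] * Ax[q];
    cnorm[j] = s;
  }
  const int window = 10;
  std::vector<double> hist;
  hist.reserve(max_sweeps);
  bool converged = false;
  int sweeps = max_sweeps;
  for (int it = 0; it < max_sweeps; ++it) {
    for (int j = 0; j < m; ++j) {
      if (cnorm[j] <= 0.0) continue;
      double g = 0.0;
      for (int q = Ap[j]; q < Ap[j + 1]; ++q) g += Ax[q] * r[Ai[q]];
      double wn = w[j] - g / cnorm[j];
      if (wn < 0.0) wn = 0.0;
      double d = wn - w[j];
      if (d != 0.0) {
        w[j] = wn;
        for (int q = Ap[j]; q < Ap[j + 1]; ++q) r[Ai[q]] += d * Ax[q];
      }
    }
    double rn = 0.0;
    for (int i = 0; i < nrow; ++i) rn += r[i] * r[i];
    rn = std::sqrt(rn);
    hist.push_back(rn);
    if (it >= window &&
        (hist[it - window] - rn) <= tol * std::max(rn, 1e-12)) {
      converged = true;
      sweeps = it + 1;
      break;
    }
  }
  return List::create(_["w"] = wrap(w), _["residual"] = hist.back(),
                      _["sweeps"] = sweeps, _["converged"] = converged);
}
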