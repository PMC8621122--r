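// Low-level numerical kernels: trilinear interpolation, volume resampling,
// cubic B-spline free-form deformation evaluation, separable Gaussian
// smoothing, exact Euclidean distance transforms, top-r weighted label
// fusion, and the stochastic-gradient-descent registration loop.
//
// Geometry convention: a voxel's world position is
//   w = origin + D %*% (spacing * index),  index 0-based continuous,
// with D the 3x3 orthonormal direction matrix (column-major from R).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------- geometry

struct Geom {
  int n0, n1, n2;
  double spc[3];
  double org[3];
  double dir[9];    // row-major D
  double idir[9];   // D^T (orthonormal inverse), row-major
};

static Geom makeGeom(const IntegerVector& dim, const NumericVector& spc,
                     const NumericVector& org, const NumericMatrix& dir) {
  Geom g;
  g.n0 = dim[0]; g.n1 = dim[1]; g.n2 = dim[2];
  for (int i = 0; i < 3; ++i) { g.spc[i] = spc[i]; g.org[i] = org[i]; }
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) {
      g.dir[3 * r + c]  = dir(r, c);
      g.idir[3 * r + c] = dir(c, r);
    }
  return g;
}

static inline void idx2world(const Geom& g, double i0, double i1, double i2,
                             double* w) {
  double s0 = g.spc[0] * i0, s1 = g.spc[1] * i1, s2 = g.spc[2] * i2;
  for (int r = 0; r < 3; ++r)
    w[r] = g.org[r] + g.dir[3 * r] * s0 + g.dir[3 * r + 1] * s1 +
           g.dir[3 * r + 2] * s2;
}

static inline void world2idx(const Geom& g, const double* w, double* i) {
  double d0 = w[0] - g.org[0], d1 = w[1] - g.org[1], d2 = w[2] - g.org[2];
  for (int r = 0; r < 3; ++r) {
    double v = g.idir[3 * r] * d0 + g.idir[3 * r + 1] * d1 +
               g.idir[3 * r + 2] * d2;
    i[r] = v / g.spc[r];
  }
}

static inline int64_t lin(const Geom& g, int i, int j, int k) {
  return (int64_t)i + (int64_t)g.n0 * ((int64_t)j + (int64_t)g.n1 * k);
}

// Trilinear interpolation; optionally also the gradient with respect to the
// continuous index. Returns false when the point lies outside the grid.
static bool trilinear(const double* v, const Geom& g, const double* ci,
                      double* val, double* grad_idx) {
  double x = ci[0], y = ci[1], z = ci[2];
  if (x < 0 || y < 0 || z < 0 || x > g.n0 - 1 || y > g.n1 - 1 || z > g.n2 - 1)
    return false;
  int i = (int)std::floor(x); if (i > g.n0 - 2) i = g.n0 - 2; if (i < 0) i = 0;
  int j = (int)std::floor(y); if (j > g.n1 - 2) j = g.n1 - 2; if (j < 0) j = 0;
  int k = (int)std::floor(z); if (k > g.n2 - 2) k = g.n2 - 2; if (k < 0) k = 0;
  if (g.n0 == 1) i = 0; if (g.n1 == 1) j = 0; if (g.n2 == 1) k = 0;
  double fx = x - i, fy = y - j, fz = z - k;
  int i1 = std::min(i + 1, g.n0 - 1), j1 = std::min(j + 1, g.n1 - 1),
      k1 = std::min(k + 1, g.n2 - 1);
  double c000 = v[lin(g, i, j, k)],   c100 = v[lin(g, i1, j, k)];
  double c010 = v[lin(g, i, j1, k)],  c110 = v[lin(g, i1, j1, k)];
  double c001 = v[lin(g, i, j, k1)],  c101 = v[lin(g, i1, j, k1)];
  double c011 = v[lin(g, i, j1, k1)], c111 = v[lin(g, i1, j1, k1)];
  double c00 = c000 + fx * (c100 - c000), c10 = c010 + fx * (c110 - c010);
  double c01 = c001 + fx * (c101 - c001), c11 = c011 + fx * (c111 - c011);
  double c0 = c00 + fy * (c10 - c00), c1 = c01 + fy * (c11 - c01);
  *val = c0 + fz * (c1 - c0);
  if (grad_idx) {
    double d00 = c100 - c000, d10 = c110 - c010, d01 = c101 - c001,
           d11 = c111 - c011;
    grad_idx[0] = (d00 + fy * (d10 - d00)) * (1 - fz) +
                  (d01 + fy * (d11 - d01)) * fz;
    double e0 = c10 - c00, e1 = c11 - c01;
    grad_idx[1] = e0 + fz * (e1 - e0);
    grad_idx[2] = c1 - c0;
  }
  return true;
}

// Catmull-Rom cubic interpolation (interpolating, no prefilter) with
// optional gradient; falls back to trilinear within one voxel of the
// border. Used at the finest registration level, where trilinear
// interpolation error would bias the metric optimum.
static bool cubicInterp(const double* v, const Geom& g, const double* ci,
                        double* val, double* grad_idx) {
  double x = ci[0], y = ci[1], z = ci[2];
  if (x < 0 || y < 0 || z < 0 || x > g.n0 - 1 || y > g.n1 - 1 || z > g.n2 - 1)
    return false;
  int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
  if (i < 1 || j < 1 || k < 1 || i > g.n0 - 3 || j > g.n1 - 3 || k > g.n2 - 3)
    return trilinear(v, g, ci, val, grad_idx);
  double t[3] = {x - i, y - j, z - k};
  double w[3][4], dw[3][4];
  for (int a = 0; a < 3; ++a) {
    double u = t[a], u2 = u * u, u3 = u2 * u;
    w[a][0] = -0.5 * u3 + u2 - 0.5 * u;
    w[a][1] = 1.5 * u3 - 2.5 * u2 + 1.0;
    w[a][2] = -1.5 * u3 + 2.0 * u2 + 0.5 * u;
    w[a][3] = 0.5 * u3 - 0.5 * u2;
    if (grad_idx) {
      dw[a][0] = -1.5 * u2 + 2.0 * u - 0.5;
      dw[a][1] = 4.5 * u2 - 5.0 * u;
      dw[a][2] = -4.5 * u2 + 4.0 * u + 0.5;
      dw[a][3] = 1.5 * u2 - u;
    }
  }
  double s = 0, gx = 0, gy = 0, gz = 0;
  for (int ck = 0; ck < 4; ++ck)
    for (int cj = 0; cj < 4; ++cj) {
      double wyz = w[1][cj] * w[2][ck];
      double row = 0;
      const double* base = v + lin(g, i - 1, j - 1 + cj, k - 1 + ck);
      double r0 = base[0], r1 = base[1], r2 = base[2], r3 = base[3];
      row = w[0][0] * r0 + w[0][1] * r1 + w[0][2] * r2 + w[0][3] * r3;
      s += row * wyz;
      if (grad_idx) {
        double drow = dw[0][0] * r0 + dw[0][1] * r1 + dw[0][2] * r2 +
                      dw[0][3] * r3;
        gx += drow * wyz;
        gy += row * dw[1][cj] * w[2][ck];
        gz += row * w[1][cj] * dw[2][ck];
      }
    }
  *val = s;
  if (grad_idx) { grad_idx[0] = gx; grad_idx[1] = gy; grad_idx[2] = gz; }
  return true;
}

static bool nearestVal(const double* v, const Geom& g, const double* ci,
                       double* val) {
  int i = (int)std::lround(ci[0]);
  int j = (int)std::lround(ci[1]);
  int k = (int)std::lround(ci[2]);
  if (i < 0 || j < 0 || k < 0 || i >= g.n0 || j >= g.n1 || k >= g.n2)
    return false;
  *val = v[lin(g, i, j, k)];
  return true;
}

// ----------------------------------------------------- cubic B-spline FFD

struct BsplineGrid {
  int n0, n1, n2;       // control points per axis
  double org[3], spc[3];
  const double* coef;   // [n0*n1*n2] x 3, column-major over components
};

static inline void bsplW(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}
static inline void bsplW2(double t, double* w) {  // second derivative wrt t
  w[0] = 1 - t;
  w[1] = 3 * t - 2;
  w[2] = 1 - 3 * t;
  w[3] = t;
}

// Evaluate displacement d(x); optionally record the 64 support weights and
// linear coefficient indices (for the optimizer), and the 6 second-derivative
// stencils (for bending energy).  Points outside full support get d = 0 and
// inside=false.
static bool bsplDisp(const BsplineGrid& b, const double* x, double* d,
                     int* sup_idx, double* sup_w, double* sup_w2 /*6x64*/) {
  double u[3]; int base[3]; double wt[3][4], wt1[3][4], wt2[3][4];
  for (int a = 0; a < 3; ++a) {
    u[a] = (x[a] - b.org[a]) / b.spc[a];
    double fl = std::floor(u[a]);
    base[a] = (int)fl - 1;
    double t = u[a] - fl;
    bsplW(t, wt[a]);
    if (sup_w2) {
      bsplW2(t, wt2[a]);
      double t2 = t * t;  // first derivative of the 1D basis
      wt1[a][0] = (-3 + 6 * t - 3 * t2) / 6.0;
      wt1[a][1] = (-12 * t + 9 * t2) / 6.0;
      wt1[a][2] = (3 + 6 * t - 9 * t2) / 6.0;
      wt1[a][3] = (3 * t2) / 6.0;
    }
  }
  int nc[3] = {b.n0, b.n1, b.n2};
  for (int a = 0; a < 3; ++a)
    if (base[a] < 0 || base[a] + 3 > nc[a] - 1) { d[0] = d[1] = d[2] = 0; return false; }
  int64_t ncp = (int64_t)b.n0 * b.n1 * b.n2;
  d[0] = d[1] = d[2] = 0;
  int q = 0;
  for (int kk = 0; kk < 4; ++kk)
    for (int jj = 0; jj < 4; ++jj)
      for (int ii = 0; ii < 4; ++ii, ++q) {
        int64_t ci = (base[0] + ii) +
                     (int64_t)b.n0 * ((base[1] + jj) +
                     (int64_t)b.n1 * (base[2] + kk));
        double w = wt[0][ii] * wt[1][jj] * wt[2][kk];
        d[0] += w * b.coef[ci];
        d[1] += w * b.coef[ci + ncp];
        d[2] += w * b.coef[ci + 2 * ncp];
        if (sup_idx) { sup_idx[q] = (int)ci; sup_w[q] = w; }
        if (sup_w2) {
          double h0 = b.spc[0], h1 = b.spc[1], h2 = b.spc[2];
          sup_w2[q]           = wt2[0][ii] * wt[1][jj] * wt[2][kk] / (h0 * h0);
          sup_w2[64 + q]      = wt[0][ii] * wt2[1][jj] * wt[2][kk] / (h1 * h1);
          sup_w2[128 + q]     = wt[0][ii] * wt[1][jj] * wt2[2][kk] / (h2 * h2);
          sup_w2[192 + q]     = wt1[0][ii] * wt1[1][jj] * wt[2][kk] / (h0 * h1);
          sup_w2[256 + q]     = wt1[0][ii] * wt[1][jj] * wt1[2][kk] / (h0 * h2);
          sup_w2[320 + q]     = wt[0][ii] * wt1[1][jj] * wt1[2][kk] / (h1 * h2);
        }
      }
  return true;
}

// ------------------------------------------------------- transform stages

// A transform spec is a list of stages applied in declared order; each stage
// is either list(kind="affine", matrix=4x4) or
// list(kind="bspline", coef=, grid_dim=, grid_origin=, grid_spacing=).
struct Stage {
  bool affine;
  double M[12];        // 3x4
  BsplineGrid grid;
};

static std::vector<Stage> parseStages(const List& tf) {
  std::vector<Stage> st;
  for (int s = 0; s < tf.size(); ++s) {
    List e = tf[s];
    std::string kind = as<std::string>(e["kind"]);
    Stage S;
    if (kind == "affine") {
      S.affine = true;
      NumericMatrix M = e["matrix"];
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 4; ++c) S.M[4 * r + c] = M(r, c);
    } else if (kind == "bspline") {
      S.affine = false;
      NumericVector coef = e["coef"];
      IntegerVector gd = e["grid_dim"];
      NumericVector go = e["grid_origin"], gs = e["grid_spacing"];
      S.grid.n0 = gd[0]; S.grid.n1 = gd[1]; S.grid.n2 = gd[2];
      for (int a = 0; a < 3; ++a) { S.grid.org[a] = go[a]; S.grid.spc[a] = gs[a]; }
      S.grid.coef = REAL(coef);
    } else {
      stop("unknown transform stage kind");
    }
    st.push_back(S);
  }
  return st;
}

static inline void applyStage(const Stage& S, const double* x, double* y) {
  if (S.affine) {
    for (int r = 0; r < 3; ++r)
      y[r] = S.M[4 * r] * x[0] + S.M[4 * r + 1] * x[1] +
             S.M[4 * r + 2] * x[2] + S.M[4 * r + 3];
  } else {
    double d[3];
    bsplDisp(S.grid, x, d, nullptr, nullptr, nullptr);
    y[0] = x[0] + d[0]; y[1] = x[1] + d[1]; y[2] = x[2] + d[2];
  }
}

static inline void applyStages(const std::vector<Stage>& st, const double* x,
                               double* y) {
  double p[3] = {x[0], x[1], x[2]}, q[3];
  for (size_t s = 0; s < st.size(); ++s) {
    applyStage(st[s], p, q);
    p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
  }
  y[0] = p[0]; y[1] = p[1]; y[2] = p[2];
}

// [[Rcpp::export]]
NumericMatrix cpp_transform_points(NumericMatrix pts, List tf) {
  std::vector<Stage> st = parseStages(tf);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double x[3] = {pts(i, 0), pts(i, 1), pts(i, 2)}, y[3];
    applyStages(st, x, y);
    out(i, 0) = y[0]; out(i, 1) = y[1]; out(i, 2) = y[2];
  }
  return out;
}

// Interpolate a volume at world points (after applying tf, possibly empty).
// [[Rcpp::export]]
List cpp_sample_volume(NumericVector vox, IntegerVector dim, NumericVector spc,
                       NumericVector org, NumericMatrix dirm,
                       NumericMatrix pts, List tf, int interp) {
  Geom g = makeGeom(dim, spc, org, dirm);
  std::vector<Stage> st = parseStages(tf);
  int n = pts.nrow();
  NumericVector val(n);
  LogicalVector ok(n);
  const double* v = REAL(vox);
  for (int i = 0; i < n; ++i) {
    double x[3] = {pts(i, 0), pts(i, 1), pts(i, 2)}, y[3], ci[3], vv = NA_REAL;
    applyStages(st, x, y);
    world2idx(g, y, ci);
    bool valid = interp == 0 ? nearestVal(v, g, ci, &vv)
                             : trilinear(v, g, ci, &vv, nullptr);
    val[i] = valid ? vv : NA_REAL;
    ok[i] = valid;
  }
  return List::create(_["value"] = val, _["valid"] = ok);
}

// Resample a source volume onto a target grid. tf maps target world points
// into source world space. interp: 0 nearest, 1 linear.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdim,
                           NumericVector sspc, NumericVector sorg,
                           NumericMatrix sdir, IntegerVector tdim,
                           NumericVector tspc, NumericVector torg,
                           NumericMatrix tdir, List tf, int interp,
                           double default_value) {
  Geom gs = makeGeom(sdim, sspc, sorg, sdir);
  Geom gt = makeGeom(tdim, tspc, torg, tdir);
  std::vector<Stage> st = parseStages(tf);
  int64_t n = (int64_t)gt.n0 * gt.n1 * gt.n2;
  NumericVector out((R_xlen_t)n);
  const double* v = REAL(src);
  int64_t q = 0;
  for (int k = 0; k < gt.n2; ++k)
    for (int j = 0; j < gt.n1; ++j)
      for (int i = 0; i < gt.n0; ++i, ++q) {
        double w[3], y[3], ci[3], vv;
        idx2world(gt, i, j, k, w);
        applyStages(st, w, y);
        world2idx(gs, y, ci);
        bool valid = interp == 0 ? nearestVal(v, gs, ci, &vv)
                                 : trilinear(v, gs, ci, &vv, nullptr);
        out[q] = valid ? vv : default_value;
      }
  return out;
}

// ----------------------------------------------------- gaussian smoothing

static void smooth1d(std::vector<double>& buf, double* data, int64_t n,
                     int64_t stride, int len, double sigma,
                     const std::vector<double>& kern) {
  int r = (int)kern.size() - 1;  // kern holds centre..edge
  for (int p = 0; p < len; ++p) {
    double acc = data[(int64_t)p * stride] * kern[0], wsum = kern[0];
    for (int t = 1; t <= r; ++t) {
      int lo = p - t, hi = p + t;
      // mirror (whole-sample symmetric) reflection, folded as often as
      // needed so kernels wider than the axis stay correct
      int m = len > 1 ? 2 * (len - 1) : 1;
      lo %= m; if (lo < 0) lo += m; if (lo > len - 1) lo = m - lo;
      hi %= m; if (hi < 0) hi += m; if (hi > len - 1) hi = m - hi;
      acc += kern[t] * (data[(int64_t)lo * stride] + data[(int64_t)hi * stride]);
      wsum += 2 * kern[t];
    }
    buf[p] = acc / wsum;
  }
  for (int p = 0; p < len; ++p) data[(int64_t)p * stride] = buf[p];
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vox, IntegerVector dim,
                         NumericVector sigma_voxels) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  NumericVector out = clone(vox);
  double* v = REAL(out);
  int maxlen = std::max(n0, std::max(n1, n2));
  std::vector<double> buf(maxlen);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_voxels[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(r + 1);
    for (int t = 0; t <= r; ++t) kern[t] = std::exp(-0.5 * t * t / (s * s));
    if (axis == 0) {
      for (int k = 0; k < n2; ++k)
        for (int j = 0; j < n1; ++j)
          smooth1d(buf, v + (int64_t)n0 * (j + (int64_t)n1 * k), n0, 1, n0, s, kern);
    } else if (axis == 1) {
      for (int k = 0; k < n2; ++k)
        for (int i = 0; i < n0; ++i)
          smooth1d(buf, v + i + (int64_t)n0 * (int64_t)n1 * k, n1, n0, n1, s, kern);
    } else {
      for (int j = 0; j < n1; ++j)
        for (int i = 0; i < n0; ++i)
          smooth1d(buf, v + i + (int64_t)n0 * j, n2, (int64_t)n0 * n1, n2, s, kern);
    }
  }
  return out;
}

// --------------------------------------------- Euclidean distance transform

// Felzenszwalb-Huttenlocher 1D squared distance transform with anisotropic
// sample spacing h (distance between adjacent samples along this axis).
// Infinite entries (no source yet on this line) are excluded from the lower
// envelope; an all-infinite line stays infinite.
static void dt1d(double* f, int n, double h, std::vector<double>& d,
                 std::vector<int>& vtx, std::vector<double>& zz) {
  const double INF = std::numeric_limits<double>::infinity();
  double h2 = h * h;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; vtx[0] = q;
      zz[0] = -INF; zz[1] = INF;
      continue;
    }
    double s;
    while (true) {
      int p = vtx[k];
      s = ((f[q] + h2 * (double)q * q) - (f[p] + h2 * (double)p * p)) /
          (2.0 * h2 * (q - p));
      if (s <= zz[k] && k > 0) { --k; continue; }
      if (s <= zz[k] && k == 0) { vtx[0] = q; break; }
      break;
    }
    if (vtx[k] != q) { ++k; vtx[k] = q; zz[k] = s; }
    zz[k + 1] = INF;
  }
  if (k < 0) return;  // all infinite
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[kk + 1] < q) ++kk;
    int p = vtx[kk];
    d[q] = f[p] + h2 * (double)(q - p) * (q - p);
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (in the units of `spacing`) from every voxel to
// the nearest foreground voxel centre.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  int64_t n = (int64_t)n0 * n1 * n2;
  NumericVector out((R_xlen_t)n);
  double* v = REAL(out);
  const double INF = std::numeric_limits<double>::infinity();
  for (int64_t q = 0; q < n; ++q) v[q] = mask[(R_xlen_t)q] ? 0.0 : INF;
  int maxlen = std::max(n0, std::max(n1, n2));
  std::vector<double> line(maxlen), d(maxlen), zz(maxlen + 1);
  std::vector<int> vtx(maxlen);
  // axis 0
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j) {
      double* p = v + (int64_t)n0 * (j + (int64_t)n1 * k);
      dt1d(p, n0, spacing[0], d, vtx, zz);
    }
  // axis 1
  for (int k = 0; k < n2; ++k)
    for (int i = 0; i < n0; ++i) {
      double* base = v + i + (int64_t)n0 * (int64_t)n1 * k;
      for (int j = 0; j < n1; ++j) line[j] = base[(int64_t)j * n0];
      dt1d(line.data(), n1, spacing[1], d, vtx, zz);
      for (int j = 0; j < n1; ++j) base[(int64_t)j * n0] = line[j];
    }
  // axis 2
  int64_t plane = (int64_t)n0 * n1;
  for (int j = 0; j < n1; ++j)
    for (int i = 0; i < n0; ++i) {
      double* base = v + i + (int64_t)n0 * j;
      for (int k = 0; k < n2; ++k) line[k] = base[(int64_t)k * plane];
      dt1d(line.data(), n2, spacing[2], d, vtx, zz);
      for (int k = 0; k < n2; ++k) base[(int64_t)k * plane] = line[k];
    }
  return out;
}

// ------------------------------------------------------------ label fusion

// Per-voxel majority vote over the r atlases with the highest weight at that
// voxel (all atlases when weights is empty). Weight ties -> lower atlas
// index; vote ties -> smallest label value. Labels matrix: nvox x natlas.
// [[Rcpp::export]]
IntegerVector cpp_fuse_topr(IntegerMatrix labels, NumericMatrix weights,
                            int r) {
  int64_t nvox = labels.nrow();
  int na = labels.ncol();
  bool usew = weights.nrow() == labels.nrow();
  if (r < 1 || r > na) stop("r must be in [1, n_atlases]");
  IntegerVector out((R_xlen_t)nvox);
  std::vector<int> order(na), sel(na);
  std::vector<double> wrow(na);
  for (int64_t q = 0; q < nvox; ++q) {
    int nsel = na;
    if (usew && r < na) {
      for (int a = 0; a < na; ++a) { order[a] = a; wrow[a] = weights(q, a); }
      std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
        if (wrow[a] != wrow[b]) return wrow[a] > wrow[b];
        return a < b;
      });
      nsel = r;
      for (int a = 0; a < r; ++a) sel[a] = order[a];
    } else {
      int lim = usew ? r : (r < na ? r : na);
      if (!usew) lim = r;  // unweighted: first r atlases == all when r == na
      nsel = lim;
      for (int a = 0; a < lim; ++a) sel[a] = a;
    }
    // count votes
    int best_label = 0, best_count = -1;
    // labels are small nonnegative ints; count with a small map
    std::vector<std::pair<int, int> > cnt;
    for (int a = 0; a < nsel; ++a) {
      int lb = labels(q, sel[a]);
      bool found = false;
      for (auto& pr : cnt)
        if (pr.first == lb) { pr.second++; found = true; break; }
      if (!found) cnt.push_back(std::make_pair(lb, 1));
    }
    for (auto& pr : cnt)
      if (pr.second > best_count ||
          (pr.second == best_count && pr.first < best_label)) {
        best_label = pr.first; best_count = pr.second;
      }
    out[(R_xlen_t)q] = best_label;
  }
  return out;
}

// ------------------------------------------------------------- SGD engine

struct Rng {  // xorshift64*
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n) % n; }
};

static void expmapTimes(const double* w, double* R) {
  // R <- exp([w]x) %*% R  (in place), Rodrigues
  double th = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  double E[9];
  if (th < 1e-14) return;
  double kx = w[0] / th, ky = w[1] / th, kz = w[2] / th;
  double c = std::cos(th), s = std::sin(th), v = 1 - c;
  E[0] = c + kx * kx * v;      E[1] = kx * ky * v - kz * s; E[2] = kx * kz * v + ky * s;
  E[3] = ky * kx * v + kz * s; E[4] = c + ky * ky * v;      E[5] = ky * kz * v - kx * s;
  E[6] = kz * kx * v - ky * s; E[7] = kz * ky * v + kx * s; E[8] = c + kz * kz * v;
  double out[9];
  for (int r = 0; r < 3; ++r)
    for (int cc = 0; cc < 3; ++cc)
      out[3 * r + cc] = E[3 * r] * R[cc] + E[3 * r + 1] * R[3 + cc] +
                        E[3 * r + 2] * R[6 + cc];
  std::copy(out, out + 9, R);
}

static void reorthonormalize(double* R) {
  // Gram-Schmidt on rows, then fix handedness via cross product
  double n0 = std::sqrt(R[0] * R[0] + R[1] * R[1] + R[2] * R[2]);
  for (int c = 0; c < 3; ++c) R[c] /= n0;
  double dp = R[3] * R[0] + R[4] * R[1] + R[5] * R[2];
  for (int c = 0; c < 3; ++c) R[3 + c] -= dp * R[c];
  double n1 = std::sqrt(R[3] * R[3] + R[4] * R[4] + R[5] * R[5]);
  for (int c = 0; c < 3; ++c) R[3 + c] /= n1;
  R[6] = R[1] * R[5] - R[2] * R[4];
  R[7] = R[2] * R[3] - R[0] * R[5];
  R[8] = R[0] * R[4] - R[1] * R[3];
}

struct SampleBuf {
  std::vector<double> x;      // n x 3 fixed world points
  std::vector<double> f;      // fixed values
  std::vector<double> m;      // moving values
  std::vector<double> g;      // n x 3 world gradient of moving at y
  std::vector<char> valid;
  std::vector<int> supIdx;    // bspline: n x 64
  std::vector<double> supW;   // bspline: n x 64
  std::vector<double> supW2;  // bspline bend subset: n x 384
};

// Metric codes: 0 MSD(normalized by fixed variance), 1 NCC (cost 1-rho), 2 MI (cost -MI)
// Kind codes:   0 rigid, 1 affine, 2 bspline
// [[Rcpp::export]]
List cpp_sgd_stage(NumericVector fixed, IntegerVector fdim, NumericVector fspc,
                   NumericVector forg, NumericMatrix fdir,
                   NumericVector moving, IntegerVector mdim, NumericVector mspc,
                   NumericVector morg, NumericMatrix mdir,
                   int kind, int metric, int mi_bins,
                   NumericMatrix init, NumericMatrix pre, NumericVector center,
                   IntegerVector mask_idx,
                   NumericVector coef0, IntegerVector gdim, NumericVector gorg,
                   NumericVector gspc, double bend_weight, int n_bend,
                   int n_samples, int max_iter, double alpha_decay, double Acap,
                   double delta0, int seed, double stop_tol, int stop_window,
                   int interp_order = 1) {
  Geom gf = makeGeom(fdim, fspc, forg, fdir);
  Geom gm = makeGeom(mdim, mspc, morg, mdir);
  const double* fv = REAL(fixed);
  const double* mv = REAL(moving);
  Rng rng((uint64_t)(uint32_t)seed * 2654435761ULL + 1013904223ULL);

  // --- state
  double R[9], tvec[3], A[9];  // rigid / affine
  double c0 = center[0], c1 = center[1], c2 = center[2];
  for (int r = 0; r < 3; ++r) {
    for (int c = 0; c < 3; ++c) { R[3 * r + c] = init(r, c); A[3 * r + c] = init(r, c); }
  }
  // y = M x + b  ==  R (x - c) + c + t  =>  t = b + M c - c
  for (int r = 0; r < 3; ++r)
    tvec[r] = init(r, 3) + init(r, 0) * c0 + init(r, 1) * c1 + init(r, 2) * c2 -
              center[r];
  double P[12];  // pre-affine for bspline stage (3x4)
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) P[4 * r + c] = pre(r, c);

  BsplineGrid grid;
  std::vector<double> coef;
  int64_t ncp = 0;
  if (kind == 2) {
    grid.n0 = gdim[0]; grid.n1 = gdim[1]; grid.n2 = gdim[2];
    for (int a = 0; a < 3; ++a) { grid.org[a] = gorg[a]; grid.spc[a] = gspc[a]; }
    ncp = (int64_t)grid.n0 * grid.n1 * grid.n2;
    coef.assign(REAL(coef0), REAL(coef0) + 3 * ncp);
    grid.coef = coef.data();
  }
  int npar = kind == 0 ? 6 : (kind == 1 ? 12 : (int)(3 * ncp));

  int64_t nfix = (int64_t)gf.n0 * gf.n1 * gf.n2;
  int nmask = mask_idx.size();
  bool usemask = nmask > 0;

  SampleBuf B;
  B.x.resize((size_t)n_samples * 3); B.f.resize(n_samples);
  B.m.resize(n_samples); B.g.resize((size_t)n_samples * 3);
  B.valid.resize(n_samples);
  if (kind == 2) {
    B.supIdx.resize((size_t)n_samples * 64);
    B.supW.resize((size_t)n_samples * 64);
    B.supW2.resize((size_t)std::min(n_bend, n_samples) * 384);
  }

  std::vector<double> grad(npar), upd(npar);
  std::vector<double> bendAcc;  // per-sample 18 second-derivs (3 comp x 6)
  if (kind == 2) bendAcc.resize((size_t)std::min(n_bend, n_samples) * 18);

  // characteristic radius for rotation/affine parameter scaling
  double r_char = 0;
  {
    int nprobe = 200;
    for (int s = 0; s < nprobe; ++s) {
      int64_t vi = usemask ? (int64_t)mask_idx[rng.below(nmask)]
                           : (int64_t)(rng.unif() * nfix);
      if (vi >= nfix) vi = nfix - 1;
      int i = (int)(vi % gf.n0), j = (int)((vi / gf.n0) % gf.n1),
          k = (int)(vi / ((int64_t)gf.n0 * gf.n1));
      double w[3];
      idx2world(gf, i, j, k, w);
      double dx = w[0] - c0, dy = w[1] - c1, dz = w[2] - c2;
      r_char += std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    r_char /= 200.0;
    if (r_char < 1.0) r_char = 1.0;
  }

  // draw samples + evaluate metric value, residual weights and gradient
  // returns cost, fills grad if wanted; nvalid out
  double hist[64 * 64];  // MI joint histogram (mi_bins <= 64)
  if (metric == 2 && mi_bins > 64) stop("mi_bins must be <= 64");

  // Random-coordinate sampling: a voxel (optionally mask-restricted) plus a
  // uniform jitter within its cell, with the fixed value interpolated. Both
  // images then see the same interpolation blur irrespective of the current
  // transform, which keeps the metric optimum unbiased; voxel-centre
  // sampling would favour lattice-aligned transforms.
  auto drawSamples = [&](void) {
    int s = 0;
    int guard = 0;
    while (s < n_samples) {
      int64_t vi = usemask ? (int64_t)mask_idx[rng.below(nmask)]
                           : (int64_t)(rng.unif() * nfix);
      if (vi >= nfix) vi = nfix - 1;
      int i = (int)(vi % gf.n0), j = (int)((vi / gf.n0) % gf.n1),
          k = (int)(vi / ((int64_t)gf.n0 * gf.n1));
      double ci[3];
      ci[0] = i + rng.unif() - 0.5;
      ci[1] = j + rng.unif() - 0.5;
      ci[2] = k + rng.unif() - 0.5;
      double fval;
      bool okf = interp_order >= 3 ? cubicInterp(fv, gf, ci, &fval, nullptr)
                                   : trilinear(fv, gf, ci, &fval, nullptr);
      if (!okf) {
        if (++guard < 8 * n_samples) continue;  // boundary voxel: redraw
        ci[0] = i; ci[1] = j; ci[2] = k; fval = fv[vi];
      }
      idx2world(gf, ci[0], ci[1], ci[2], &B.x[(size_t)s * 3]);
      B.f[s] = fval;
      ++s;
    }
  };

  int nBendUse = kind == 2 ? std::min(n_bend, n_samples) : 0;

  // evaluate moving values/gradients at current parameters for drawn samples
  auto evalPoints = [&](bool wantGrad) -> int {
    int nvalid = 0;
    for (int s = 0; s < n_samples; ++s) {
      const double* x = &B.x[(size_t)s * 3];
      double y[3];
      if (kind == 0 || kind == 1) {
        const double* M = kind == 0 ? R : A;
        double dx = x[0] - c0, dy = x[1] - c1, dz = x[2] - c2;
        for (int r = 0; r < 3; ++r)
          y[r] = M[3 * r] * dx + M[3 * r + 1] * dy + M[3 * r + 2] * dz +
                 center[r] + tvec[r];
      } else {
        double d[3];
        bool withBend = bend_weight > 0 && s < nBendUse;
        bool inside = bsplDisp(grid, x, d, &B.supIdx[(size_t)s * 64],
                               &B.supW[(size_t)s * 64],
                               withBend ? &B.supW2[(size_t)s * 384] : nullptr);
        if (!inside) {
          // outside control-grid support: zero displacement, no coef grad
          for (int q = 0; q < 64; ++q) B.supW[(size_t)s * 64 + q] = 0;
        }
        double z[3] = {x[0] + d[0], x[1] + d[1], x[2] + d[2]};
        for (int r = 0; r < 3; ++r)
          y[r] = P[4 * r] * z[0] + P[4 * r + 1] * z[1] + P[4 * r + 2] * z[2] +
                 P[4 * r + 3];
        if (withBend) {
          // accumulate second derivatives of each displacement component
          double* ba = &bendAcc[(size_t)s * 18];
          std::fill(ba, ba + 18, 0.0);
          const int* si = &B.supIdx[(size_t)s * 64];
          const double* w2 = &B.supW2[(size_t)s * 384];
          if (inside)
            for (int q = 0; q < 64; ++q) {
              int ci = si[q];
              for (int comp = 0; comp < 3; ++comp) {
                double cc = coef[ci + (int64_t)comp * ncp];
                for (int dd = 0; dd < 6; ++dd)
                  ba[6 * comp + dd] += w2[64 * dd + q] * cc;
              }
            }
        }
      }
      double ci[3], val, gi[3];
      world2idx(gm, y, ci);
      bool okv = interp_order >= 3
                     ? cubicInterp(mv, gm, ci, &val, wantGrad ? gi : nullptr)
                     : trilinear(mv, gm, ci, &val, wantGrad ? gi : nullptr);
      B.valid[s] = okv ? 1 : 0;
      if (!okv) continue;
      ++nvalid;
      B.m[s] = val;
      if (wantGrad) {
        // world gradient: D * (g_idx / spc)
        double gw[3];
        double a0 = gi[0] / gm.spc[0], a1 = gi[1] / gm.spc[1],
               a2 = gi[2] / gm.spc[2];
        for (int r = 0; r < 3; ++r)
          gw[r] = gm.dir[3 * r] * a0 + gm.dir[3 * r + 1] * a1 +
                  gm.dir[3 * r + 2] * a2;
        B.g[(size_t)s * 3] = gw[0];
        B.g[(size_t)s * 3 + 1] = gw[1];
        B.g[(size_t)s * 3 + 2] = gw[2];
      }
    }
    return nvalid;
  };

  // cost + dC/dm_s weights for valid samples
  std::vector<double> wres(n_samples);
  auto costAndResiduals = [&](int nvalid, bool wantGrad) -> double {
    if (metric == 0) {  // MSD normalized by fixed-sample variance
      double sf = 0, sff = 0;
      for (int s = 0; s < n_samples; ++s)
        if (B.valid[s]) { sf += B.f[s]; sff += B.f[s] * B.f[s]; }
      double varf = sff / nvalid - (sf / nvalid) * (sf / nvalid);
      if (varf < 1e-12) varf = 1e-12;
      double c = 0;
      for (int s = 0; s < n_samples; ++s)
        if (B.valid[s]) {
          double rr = B.m[s] - B.f[s];
          c += rr * rr;
          if (wantGrad) wres[s] = 2.0 * rr / (nvalid * varf);
        }
      return c / (nvalid * varf);
    } else if (metric == 1) {  // 1 - NCC
      double sf = 0, sm = 0;
      for (int s = 0; s < n_samples; ++s)
        if (B.valid[s]) { sf += B.f[s]; sm += B.m[s]; }
      double mf = sf / nvalid, mm = sm / nvalid;
      double sab = 0, saa = 0, sbb = 0;
      for (int s = 0; s < n_samples; ++s)
        if (B.valid[s]) {
          double a = B.m[s] - mm, b = B.f[s] - mf;
          sab += a * b; saa += a * a; sbb += b * b;
        }
      if (saa < 1e-12 || sbb < 1e-12) {
        if (wantGrad) std::fill(wres.begin(), wres.end(), 0.0);
        return 1.0;
      }
      double den = std::sqrt(saa * sbb);
      double rho = sab / den;
      if (wantGrad)
        for (int s = 0; s < n_samples; ++s)
          if (B.valid[s]) {
            double a = B.m[s] - mm, b = B.f[s] - mf;
            wres[s] = -(b - a * sab / saa) / den;
          }
      return 1.0 - rho;
    } else {  // -MI, hard-binned joint histogram (no analytic gradient)
      double fmin = 1e300, fmax = -1e300, mmin = 1e300, mmax = -1e300;
      for (int s = 0; s < n_samples; ++s)
        if (B.valid[s]) {
          fmin = std::min(fmin, B.f[s]); fmax = std::max(fmax, B.f[s]);
          mmin = std::min(mmin, B.m[s]); mmax = std::max(mmax, B.m[s]);
        }
      if (fmax <= fmin || mmax <= mmin) return 0.0;
      int nb = mi_bins;
      std::fill(hist, hist + nb * nb, 0.0);
      for (int s = 0; s < n_samples; ++s)
        if (B.valid[s]) {
          int bi = (int)((B.f[s] - fmin) / (fmax - fmin) * nb);
          int bj = (int)((B.m[s] - mmin) / (mmax - mmin) * nb);
          if (bi >= nb) bi = nb - 1;
          if (bj >= nb) bj = nb - 1;
          hist[bi * nb + bj] += 1.0;
        }
      std::vector<double> pi(nb, 0.0), pj(nb, 0.0);
      for (int a = 0; a < nb; ++a)
        for (int b = 0; b < nb; ++b) {
          hist[a * nb + b] /= nvalid;
          pi[a] += hist[a * nb + b];
          pj[b] += hist[a * nb + b];
        }
      double mi = 0;
      for (int a = 0; a < nb; ++a)
        for (int b = 0; b < nb; ++b) {
          double p = hist[a * nb + b];
          if (p > 1e-15) mi += p * std::log(p / (pi[a] * pj[b]));
        }
      return -mi;
    }
  };

  // accumulate parameter gradient from residual weights
  auto paramGrad = [&](int nvalid) {
    std::fill(grad.begin(), grad.end(), 0.0);
    for (int s = 0; s < n_samples; ++s) {
      if (!B.valid[s]) continue;
      double w = wres[s];
      const double* g = &B.g[(size_t)s * 3];
      const double* x = &B.x[(size_t)s * 3];
      if (kind == 0) {
        double dx = x[0] - c0, dy = x[1] - c1, dz = x[2] - c2;
        double v0 = R[0] * dx + R[1] * dy + R[2] * dz;
        double v1 = R[3] * dx + R[4] * dy + R[5] * dz;
        double v2 = R[6] * dx + R[7] * dy + R[8] * dz;
        // d y / d delta_j = e_j x v  =>  grad_delta = w * (v x g)
        grad[0] += w * (v1 * g[2] - v2 * g[1]);
        grad[1] += w * (v2 * g[0] - v0 * g[2]);
        grad[2] += w * (v0 * g[1] - v1 * g[0]);
        grad[3] += w * g[0]; grad[4] += w * g[1]; grad[5] += w * g[2];
      } else if (kind == 1) {
        double d[3] = {x[0] - c0, x[1] - c1, x[2] - c2};
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c) grad[3 * r + c] += w * g[r] * d[c];
        grad[9] += w * g[0]; grad[10] += w * g[1]; grad[11] += w * g[2];
      } else {
        // chain through pre-affine: gp = P_lin^T g
        double gp[3];
        for (int c = 0; c < 3; ++c)
          gp[c] = P[c] * g[0] + P[4 + c] * g[1] + P[8 + c] * g[2];
        const int* si = &B.supIdx[(size_t)s * 64];
        const double* sw = &B.supW[(size_t)s * 64];
        for (int q = 0; q < 64; ++q) {
          double ww = w * sw[q];
          if (ww == 0) continue;
          int ci = si[q];
          grad[ci] += ww * gp[0];
          grad[ci + ncp] += ww * gp[1];
          grad[ci + 2 * ncp] += ww * gp[2];
        }
      }
    }
    // bending energy gradient (bspline only): mean over bend subset of
    // sum_comp [dxx^2+dyy^2+dzz^2+2(dxy^2+dxz^2+dyz^2)]
    if (kind == 2 && bend_weight > 0 && nBendUse > 0) {
      double mult[6] = {1, 1, 1, 2, 2, 2};
      double scale = bend_weight / nBendUse;
      for (int s = 0; s < nBendUse; ++s) {
        const double* ba = &bendAcc[(size_t)s * 18];
        const int* si = &B.supIdx[(size_t)s * 64];
        const double* w2 = &B.supW2[(size_t)s * 384];
        for (int q = 0; q < 64; ++q) {
          int ci = si[q];
          for (int comp = 0; comp < 3; ++comp) {
            double acc = 0;
            for (int dd = 0; dd < 6; ++dd)
              acc += 2.0 * mult[dd] * ba[6 * comp + dd] * w2[64 * dd + q];
            grad[ci + (int64_t)comp * ncp] += scale * acc;
          }
        }
      }
    }
  };

  auto bendCost = [&]() -> double {
    if (kind != 2 || bend_weight <= 0 || nBendUse == 0) return 0.0;
    double mult[6] = {1, 1, 1, 2, 2, 2};
    double c = 0;
    for (int s = 0; s < nBendUse; ++s) {
      const double* ba = &bendAcc[(size_t)s * 18];
      for (int comp = 0; comp < 3; ++comp)
        for (int dd = 0; dd < 6; ++dd)
          c += mult[dd] * ba[6 * comp + dd] * ba[6 * comp + dd];
    }
    return bend_weight * c / nBendUse;
  };

  // scales (squared divisor per parameter)
  std::vector<double> s2(npar, 1.0);
  if (kind == 0) { s2[0] = s2[1] = s2[2] = r_char * r_char; }
  if (kind == 1) for (int p = 0; p < 9; ++p) s2[p] = r_char * r_char;

  // MI finite-difference gradient (rigid/affine only). The hard-binned
  // estimator is flat at sub-bin scales, so each parameter is perturbed by
  // the equivalent of ~0.3 mm of displacement at the characteristic radius.
  auto miGrad = [&](int nvalid) {
    double h_mm = 0.3;
    if (kind == 2) stop("MI metric is not supported for the B-spline stage");
    for (int p = 0; p < npar; ++p) {
      bool scaled = (kind == 0 && p < 3) || (kind == 1 && p < 9);
      double delta = scaled ? h_mm / r_char : h_mm;
      double cplus, cminus;
      if (kind == 0 && p < 3) {
        double w[3] = {0, 0, 0};
        double Rs[9];
        std::copy(R, R + 9, Rs);
        w[p] = delta;  // radians
        expmapTimes(w, R);
        int nv = evalPoints(false);
        cplus = costAndResiduals(nv > 0 ? nv : 1, false);
        std::copy(Rs, Rs + 9, R);
        w[p] = -delta;
        expmapTimes(w, R);
        nv = evalPoints(false);
        cminus = costAndResiduals(nv > 0 ? nv : 1, false);
        std::copy(Rs, Rs + 9, R);
      } else {
        double* tgt = kind == 0 ? &tvec[p - 3]
                                : (p < 9 ? &A[p] : &tvec[p - 9]);
        double save = *tgt;
        *tgt = save + delta;
        int nv = evalPoints(false);
        cplus = costAndResiduals(nv > 0 ? nv : 1, false);
        *tgt = save - delta;
        nv = evalPoints(false);
        cminus = costAndResiduals(nv > 0 ? nv : 1, false);
        *tgt = save;
      }
      grad[p] = (cplus - cminus) / (2 * delta);
    }
  };

  // ---- gain probe: average scaled gradient magnitude over a few draws
  double gmag = 0;
  int nprobe = 5, okprobe = 0;
  std::vector<int> probe_nv(nprobe, 0);
  for (int pr = 0; pr < nprobe; ++pr) {
    drawSamples();
    int nv = evalPoints(true);
    probe_nv[pr] = nv;
    if (nv < n_samples / 2) continue;
    costAndResiduals(nv, true);
    if (metric == 2) miGrad(nv); else paramGrad(nv);
    double mx = 0;
    for (int p = 0; p < npar; ++p)
      mx = std::max(mx, std::fabs(grad[p]) / s2[p]);
    gmag += mx;
    ++okprobe;
  }
  if (okprobe == 0)
    return List::create(_["status"] = "degenerate_overlap",
                        _["probe_nv"] = IntegerVector(probe_nv.begin(),
                                                      probe_nv.end()));
  gmag /= okprobe;
  double a_gain = gmag > 1e-14
                      ? delta0 * std::pow(Acap + 1.0, alpha_decay) / gmag
                      : 0.0;

  // ---- main loop
  int it = 0, still = 0, nvalid_last = 0;
  double cost_last = NA_REAL;
  bool degenerate = false;
  // Polyak tail averaging: accumulate the iterates over the last quarter of
  // the schedule to suppress stochastic jitter around the optimum
  int tail_start = (3 * max_iter) / 4;
  int n_avg = 0;
  double Ravg[9] = {0}, tavg[3] = {0}, Aavg[9] = {0};
  std::vector<double> coef_avg;
  if (kind == 2) coef_avg.assign(coef.size(), 0.0);
  for (it = 0; it < max_iter; ++it) {
    drawSamples();
    int nv = evalPoints(true);
    if (nv < n_samples / 2) { degenerate = true; break; }
    nvalid_last = nv;
    cost_last = costAndResiduals(nv, true) + bendCost();
    if (metric == 2) miGrad(nv); else paramGrad(nv);
    double at = a_gain / std::pow(Acap + it + 1.0, alpha_decay);
    // raw update and its largest step in mm-equivalent units
    double maxstep = 0;
    for (int p = 0; p < npar; ++p) {
      upd[p] = -at * grad[p] / s2[p];
      double nat = std::fabs(upd[p]);
      if ((kind == 0 && p < 3) || (kind == 1 && p < 9)) nat *= r_char;
      if (nat > maxstep) maxstep = nat;
    }
    // trust region: the probe gain can be arbitrarily large when starting
    // near an optimum (tiny gradients), so cap the step length; the cap
    // decays on the same schedule as the gain so late iterations settle
    double cap = delta0 * std::pow((Acap + 1.0) / (Acap + it + 1.0),
                                   alpha_decay);
    if (maxstep > cap) {
      double sc = cap / maxstep;
      for (int p = 0; p < npar; ++p) upd[p] *= sc;
      maxstep = cap;
    }
    if (kind == 0) {
      expmapTimes(upd.data(), R);
      if ((it & 63) == 0) reorthonormalize(R);
      for (int p = 0; p < 3; ++p) tvec[p] += upd[p + 3];
    } else if (kind == 1) {
      for (int p = 0; p < 9; ++p) A[p] += upd[p];
      for (int p = 0; p < 3; ++p) tvec[p] += upd[p + 9];
    } else {
      for (int p = 0; p < npar; ++p) coef[p] += upd[p];
    }
    if (it >= tail_start) {
      ++n_avg;
      if (kind == 0) {
        for (int p = 0; p < 9; ++p) Ravg[p] += R[p];
        for (int p = 0; p < 3; ++p) tavg[p] += tvec[p];
      } else if (kind == 1) {
        for (int p = 0; p < 9; ++p) Aavg[p] += A[p];
        for (int p = 0; p < 3; ++p) tavg[p] += tvec[p];
      } else {
        for (size_t p = 0; p < coef.size(); ++p) coef_avg[p] += coef[p];
      }
    }
    if (maxstep < stop_tol) { if (++still >= stop_window) { ++it; break; } }
    else still = 0;
  }
  if (!degenerate && n_avg > 0) {
    if (kind == 0) {
      for (int p = 0; p < 9; ++p) R[p] = Ravg[p] / n_avg;
      for (int p = 0; p < 3; ++p) tvec[p] = tavg[p] / n_avg;
    } else if (kind == 1) {
      for (int p = 0; p < 9; ++p) A[p] = Aavg[p] / n_avg;
      for (int p = 0; p < 3; ++p) tvec[p] = tavg[p] / n_avg;
    } else {
      for (size_t p = 0; p < coef.size(); ++p) coef[p] = coef_avg[p] / n_avg;
    }
  }
  reorthonormalize(R);

  // ---- pack result
  NumericMatrix out(4, 4);
  out(3, 3) = 1.0;
  if (kind == 0 || kind == 1) {
    const double* M = kind == 0 ? R : A;
    for (int r = 0; r < 3; ++r) {
      for (int c = 0; c < 3; ++c) out(r, c) = M[3 * r + c];
      out(r, 3) = tvec[r] + center[r] -
                  (M[3 * r] * c0 + M[3 * r + 1] * c1 + M[3 * r + 2] * c2);
    }
  }
  List res = List::create(
      _["status"] = degenerate ? "degenerate_overlap" : "ok",
      _["matrix"] = out, _["iterations"] = it, _["cost"] = cost_last,
      _["n_valid"] = nvalid_last, _["gain"] = a_gain);
  if (kind == 2) res["coef"] = NumericVector(coef.begin(), coef.end());
  return res;
}
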