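// Interpolation primitives on 3D scalar volumes.
// Points are continuous 0-based voxel coordinates (N x 3 matrix). Samples that
// fall outside the voxel-center bounding box [0, D-1] take the fill value
// (linear interpolation uses implicit zero padding only through the fill).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".sample_nearest")]]
NumericVector sample_nearest(NumericVector vol, IntegerVector dims,
                             NumericMatrix pts, double fill) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const size_t plane = (size_t)d1 * d2;
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    // round half away from zero would differ from R's round; use nearbyint-free
    // explicit floor(x+0.5) so ties at .5 go up, deterministically
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    // negated bounds so non-finite coordinates (NaN comparisons are false)
    // safely take the fill value instead of an undefined cast
    if (!(px >= -0.5 && px < d1 - 0.5 && py >= -0.5 && py < d2 - 0.5 &&
          pz >= -0.5 && pz < d3 - 0.5)) {
      out[i] = fill;
      continue;
    }
    const long ix = (long)std::floor(px + 0.5);
    const long iy = (long)std::floor(py + 0.5);
    const long iz = (long)std::floor(pz + 0.5);
    out[i] = vol[(size_t)ix + (size_t)d1 * iy + plane * iz];
  }
  return out;
}

// [[Rcpp::export(name = ".sample_linear")]]
NumericVector sample_linear(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts, double fill) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const size_t plane = (size_t)d1 * d2;
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    if (!(px >= 0 && px <= d1 - 1 && py >= 0 && py <= d2 - 1 &&
          pz >= 0 && pz <= d3 - 1)) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(px); if (x0 > d1 - 2) x0 = std::max(0, d1 - 2);
    int y0 = (int)std::floor(py); if (y0 > d2 - 2) y0 = std::max(0, d2 - 2);
    int z0 = (int)std::floor(pz); if (z0 > d3 - 2) z0 = std::max(0, d3 - 2);
    const double fx = px - x0, fy = py - y0, fz = pz - z0;
    const int x1 = std::min(x0 + 1, d1 - 1), y1 = std::min(y0 + 1, d2 - 1),
              z1 = std::min(z0 + 1, d3 - 1);
    double v = 0;
    const double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
    const int xs[2] = {x0, x1}, ys[2] = {y0, y1}, zs[2] = {z0, z1};
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c)
          v += wz[a] * wy[b] * wx[c] *
               vol[(size_t)xs[c] + (size_t)d1 * ys[b] + plane * zs[a]];
    out[i] = v;
  }
  return out;
}

// Gradient of the trilinear interpolant with respect to the sample point.
// Out-of-box points get zero gradient (the sample is the constant fill there).
// [[Rcpp::export(name = ".sample_linear_grad")]]
NumericMatrix sample_linear_grad(NumericVector vol, IntegerVector dims,
                                 NumericMatrix pts) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const size_t plane = (size_t)d1 * d2;
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    if (!(px >= 0 && px <= d1 - 1 && py >= 0 && py <= d2 - 1 &&
          pz >= 0 && pz <= d3 - 1))
      continue;
    int x0 = (int)std::floor(px); if (x0 > d1 - 2) x0 = std::max(0, d1 - 2);
    int y0 = (int)std::floor(py); if (y0 > d2 - 2) y0 = std::max(0, d2 - 2);
    int z0 = (int)std::floor(pz); if (z0 > d3 - 2) z0 = std::max(0, d3 - 2);
    const double fx = px - x0, fy = py - y0, fz = pz - z0;
    const int x1 = std::min(x0 + 1, d1 - 1), y1 = std::min(y0 + 1, d2 - 1),
              z1 = std::min(z0 + 1, d3 - 1);
    const double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
    const double dx[2] = {-1.0, 1.0};
    const int xs[2] = {x0, x1}, ys[2] = {y0, y1}, zs[2] = {z0, z1};
    double gx = 0, gy = 0, gz = 0;
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c) {
          const double v =
              vol[(size_t)xs[c] + (size_t)d1 * ys[b] + plane * zs[a]];
          gx += wz[a] * wy[b] * dx[c] * v;
          gy += wz[a] * dx[b] * wx[c] * v;
          gz += dx[a] * wy[b] * wx[c] * v;
        }
    out(i, 0) = gx; out(i, 1) = gy; out(i, 2) = gz;
  }
  return out;
}

namespace {

inline int mirror_index(int i, int n) {
  // reflect about the end samples (period 2n-2), standard spline boundary
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i = std::abs(i) % period;
  return (i < n) ? i : period - i;
}

// In-place cubic B-spline prefilter along one axis (Unser's recursive filter,
// mirror boundaries) so that spline evaluation interpolates the original data.
void prefilter_axis(std::vector<double>& c) {
  const int n = (int)c.size();
  if (n == 1) return;
  const double z1 = std::sqrt(3.0) - 2.0;
  const double lambda = 6.0;
  for (int i = 0; i < n; ++i) c[i] *= lambda;
  // causal initialization: c+(0) = sum z1^i c(i) over the mirrored signal,
  // truncated once the weights fall below 1e-12 (mirror indexing makes the
  // sum valid for any line length)
  double sum = c[0];
  double zn = z1;
  const int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::abs(z1)));
  for (int i = 1; i < horizon; ++i) {
    sum += zn * c[mirror_index(i, n)];
    zn *= z1;
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i] += z1 * c[i - 1];
  // anticausal
  c[n - 1] = (z1 / (z1 * z1 - 1.0)) * (c[n - 1] + z1 * c[n - 2]);
  for (int i = n - 2; i >= 0; --i) c[i] = z1 * (c[i + 1] - c[i]);
}

inline void cubic_weights(double f, double* w) {
  // cubic B-spline basis at fractional offset f in [0,1) for taps -1,0,1,2
  const double f2 = f * f, f3 = f2 * f;
  w[0] = (1.0 - 3.0 * f + 3.0 * f2 - f3) / 6.0;
  w[1] = (4.0 - 6.0 * f2 + 3.0 * f3) / 6.0;
  w[2] = (1.0 + 3.0 * f + 3.0 * f2 - 3.0 * f3) / 6.0;
  w[3] = f3 / 6.0;
}

} // namespace

// [[Rcpp::export(name = ".bspline_prefilter3d")]]
NumericVector bspline_prefilter3d(NumericVector vol, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const size_t plane = (size_t)d1 * d2;
  NumericVector out = clone(vol);
  std::vector<double> line;
  // x lines
  line.resize(d1);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y) {
      double* p = out.begin() + (size_t)d1 * y + plane * z;
      std::copy(p, p + d1, line.begin());
      prefilter_axis(line);
      std::copy(line.begin(), line.end(), p);
    }
  // y lines
  line.resize(d2);
  for (int z = 0; z < d3; ++z)
    for (int x = 0; x < d1; ++x) {
      for (int y = 0; y < d2; ++y) line[y] = out[(size_t)x + (size_t)d1 * y + plane * z];
      prefilter_axis(line);
      for (int y = 0; y < d2; ++y) out[(size_t)x + (size_t)d1 * y + plane * z] = line[y];
    }
  // z lines
  line.resize(d3);
  for (int y = 0; y < d2; ++y)
    for (int x = 0; x < d1; ++x) {
      for (int z = 0; z < d3; ++z) line[z] = out[(size_t)x + (size_t)d1 * y + plane * z];
      prefilter_axis(line);
      for (int z = 0; z < d3; ++z) out[(size_t)x + (size_t)d1 * y + plane * z] = line[z];
    }
  out.attr("dim") = IntegerVector::create(d1, d2, d3);
  return out;
}

// Sample a prefiltered coefficient volume with the cubic B-spline basis.
// [[Rcpp::export(name = ".sample_cubic")]]
NumericVector sample_cubic(NumericVector coef, IntegerVector dims,
                           NumericMatrix pts, double fill) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const size_t plane = (size_t)d1 * d2;
  const int n = pts.nrow();
  NumericVector out(n);
  double wx[4], wy[4], wz[4];
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    if (!(px >= 0 && px <= d1 - 1 && py >= 0 && py <= d2 - 1 &&
          pz >= 0 && pz <= d3 - 1)) {
      out[i] = fill;
      continue;
    }
    const int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
              z0 = (int)std::floor(pz);
    cubic_weights(px - x0, wx);
    cubic_weights(py - y0, wy);
    cubic_weights(pz - z0, wz);
    double v = 0;
    for (int a = 0; a < 4; ++a) {
      const int zz = mirror_index(z0 - 1 + a, d3);
      for (int b = 0; b < 4; ++b) {
        const int yy = mirror_index(y0 - 1 + b, d2);
        const double wzy = wz[a] * wy[b];
        for (int c = 0; c < 4; ++c) {
          const int xx = mirror_index(x0 - 1 + c, d1);
          v += wzy * wx[c] * coef[(size_t)xx + (size_t)d1 * yy + plane * zz];
        }
      }
    }
    out[i] = v;
  }
  return out;
}

// Cubic B-spline free-form deformation: control lattice of size (n1,n2,n3)
// with per-axis knot spacing h spanning [0, (n-1)*h]; coefficients outside the
// lattice are edge-replicated. Returns the displacement (N x 3) at the points.
// [[Rcpp::export(name = ".ffd_eval")]]
NumericMatrix ffd_eval(NumericVector coef, IntegerVector nctrl,
                       NumericVector h, NumericMatrix pts) {
  const int n1 = nctrl[0], n2 = nctrl[1], n3 = nctrl[2];
  const size_t lat = (size_t)n1 * n2 * n3;
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  double wx[4], wy[4], wz[4];
  for (int i = 0; i < n; ++i) {
    const double tx = pts(i, 0) / h[0], ty = pts(i, 1) / h[1],
                 tz = pts(i, 2) / h[2];
    if (!(std::isfinite(tx) && std::isfinite(ty) && std::isfinite(tz)))
      continue;
    const int x0 = (int)std::floor(tx), y0 = (int)std::floor(ty),
              z0 = (int)std::floor(tz);
    cubic_weights(tx - x0, wx);
    cubic_weights(ty - y0, wy);
    cubic_weights(tz - z0, wz);
    double u0 = 0, u1 = 0, u2 = 0;
    for (int a = 0; a < 4; ++a) {
      int zz = z0 - 1 + a; zz = std::min(std::max(zz, 0), n3 - 1);
      for (int b = 0; b < 4; ++b) {
        int yy = y0 - 1 + b; yy = std::min(std::max(yy, 0), n2 - 1);
        const double wzy = wz[a] * wy[b];
        for (int c = 0; c < 4; ++c) {
          int xx = x0 - 1 + c; xx = std::min(std::max(xx, 0), n1 - 1);
          const double w = wzy * wx[c];
          const size_t li = (size_t)xx + (size_t)n1 * yy + (size_t)n1 * n2 * zz;
          u0 += w * coef[li];
          u1 += w * coef[li + lat];
          u2 += w * coef[li + 2 * lat];
        }
      }
    }
    out(i, 0) = u0; out(i, 1) = u1; out(i, 2) = u2;
  }
  return out;
}

// For each row of A, the minimum Euclidean distance to any row of B (both in
// physical mm coordinates).
// [[Rcpp::export(name = ".min_dists")]]
NumericVector min_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
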