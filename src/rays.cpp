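// Per-azimuth profile scans shared by topographic openness, sky-view
// factor, wind exposure and horizon shading. Along the eight principal
// directions profiles step from cell to cell (exact, distance cs or
// cs*sqrt(2)); other azimuths advance in steps of one cell size and sample
// the surface bilinearly. NaN samples are skipped; rays stop at the grid
// boundary.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

struct Ray {
  bool grid_aligned;   // one of the 8 principal directions
  int ir, ic;          // integer step (grid-aligned path)
  double dr, dc;       // fractional step (bilinear path), in cells
  double step_len;     // metres per step
  int nstep;
};

static Ray make_ray(double az, double cs, double radius) {
  Ray ray;
  double dc = std::sin(az), dr = -std::cos(az);
  bool card = std::fabs(dc) < 1e-9 || std::fabs(dr) < 1e-9;
  bool diag = std::fabs(dc * dc - 0.5) < 1e-9 && std::fabs(dr * dr - 0.5) < 1e-9;
  if (card || diag) {
    ray.grid_aligned = true;
    ray.ir = (dr > 0.5) - (dr < -0.5);
    ray.ic = (dc > 0.5) - (dc < -0.5);
    ray.step_len = diag ? cs * std::sqrt(2.0) : cs;
  } else {
    ray.grid_aligned = false;
    ray.dr = dr;
    ray.dc = dc;
    ray.step_len = cs;
  }
  ray.nstep = (int) std::floor(radius / ray.step_len);
  return ray;
}

// bilinear sample at fractional (row, col); NaN outside or on nodata
static inline double sample_bilinear(const NumericMatrix& z, double r,
                                     double c) {
  const int nr = z.nrow(), nc = z.ncol();
  if (r < 0 || c < 0 || r > nr - 1 || c > nc - 1) return NA_REAL;
  int r0 = (int) std::floor(r), c0 = (int) std::floor(c);
  if (r0 == nr - 1) r0--;
  if (c0 == nc - 1) c0--;
  if (r0 < 0) r0 = 0;
  if (c0 < 0) c0 = 0;
  double fr = r - r0, fc = c - c0;
  double v00 = z(r0, c0), v01 = z(r0, c0 + 1);
  double v10 = z(r0 + 1, c0), v11 = z(r0 + 1, c0 + 1);
  if (!R_finite(v00) || !R_finite(v01) || !R_finite(v10) || !R_finite(v11))
    return NA_REAL;
  return (1 - fr) * ((1 - fc) * v00 + fc * v01) +
         fr * ((1 - fc) * v10 + fc * v11);
}

// max tangent of the elevation angle seen from (r0,c0) along the ray
static inline double max_tan_along(const NumericMatrix& z, int r0, int c0,
                                   const Ray& ray, double sgn) {
  const int nr = z.nrow(), nc = z.ncol();
  const double z0 = sgn * z(r0, c0);
  double best = -INFINITY;
  if (ray.grid_aligned) {
    int rr = r0, cc = c0;
    for (int t = 1; t <= ray.nstep; ++t) {
      rr += ray.ir; cc += ray.ic;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) break;
      double v = z(rr, cc);
      if (!R_finite(v)) continue;
      double tn = (sgn * v - z0) / (t * ray.step_len);
      if (tn > best) best = tn;
    }
  } else {
    for (int t = 1; t <= ray.nstep; ++t) {
      double rr = r0 + t * ray.dr, cc = c0 + t * ray.dc;
      if (rr < 0 || rr > nr - 1 || cc < 0 || cc > nc - 1) break;
      double v = sample_bilinear(z, rr, cc);
      if (!R_finite(v)) continue;
      double tn = (sgn * v - z0) / (t * ray.step_len);
      if (tn > best) best = tn;
    }
  }
  if (!R_finite(best)) best = 0.0;  // no valid sample: flat horizon
  return best;
}

static std::vector<Ray> make_rays(int n_azimuths, double cs, double radius) {
  std::vector<Ray> rays;
  rays.reserve(n_azimuths);
  for (int k = 0; k < n_azimuths; ++k)
    rays.push_back(make_ray(2.0 * PI_ * k / n_azimuths, cs, radius));
  return rays;
}

// [[Rcpp::export]]
NumericMatrix openness_cpp(NumericMatrix z, double cs, double radius,
                           int n_azimuths, bool negative) {
  const int nr = z.nrow(), nc = z.ncol();
  const double sgn = negative ? -1.0 : 1.0;
  std::vector<Ray> rays = make_rays(n_azimuths, cs, radius);
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!R_finite(z(r, c))) { out(r, c) = NA_REAL; continue; }
      double acc = 0.0;
      for (int k = 0; k < n_azimuths; ++k)
        acc += PI_ / 2.0 - std::atan(max_tan_along(z, r, c, rays[k], sgn));
      out(r, c) = acc / n_azimuths;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix svf_cpp(NumericMatrix z, double cs, double radius,
                      int n_azimuths) {
  const int nr = z.nrow(), nc = z.ncol();
  std::vector<Ray> rays = make_rays(n_azimuths, cs, radius);
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!R_finite(z(r, c))) { out(r, c) = NA_REAL; continue; }
      double acc = 0.0;
      for (int k = 0; k < n_azimuths; ++k) {
        double h = std::atan(max_tan_along(z, r, c, rays[k], 1.0));
        if (h < 0) h = 0;  // horizon cannot dip below horizontal for sky view
        double ch = std::cos(h);
        acc += ch * ch;
      }
      out(r, c) = acc / n_azimuths;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix wex_cpp(NumericMatrix z, double cs, double radius,
                      int n_azimuths, double decay) {
  const int nr = z.nrow(), nc = z.ncol();
  std::vector<Ray> rays = make_rays(n_azimuths, cs, radius);
  // per-ray, per-step weights decay^(distance in metres)
  std::vector<std::vector<double>> w(n_azimuths);
  for (int k = 0; k < n_azimuths; ++k) {
    w[k].resize(rays[k].nstep + 1);
    for (int t = 1; t <= rays[k].nstep; ++t)
      w[k][t] = std::pow(decay, t * rays[k].step_len);
  }
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double z0 = z(r, c);
      if (!R_finite(z0)) { out(r, c) = NA_REAL; continue; }
      double acc = 0.0;
      for (int k = 0; k < n_azimuths; ++k) {
        const Ray& ray = rays[k];
        double sw = 0.0, swphi = 0.0;
        if (ray.grid_aligned) {
          int rr = r, cc = c;
          for (int t = 1; t <= ray.nstep; ++t) {
            rr += ray.ir; cc += ray.ic;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) break;
            double v = z(rr, cc);
            if (!R_finite(v)) continue;
            double phi = std::atan((v - z0) / (t * ray.step_len));
            sw += w[k][t];
            swphi += w[k][t] * phi;
          }
        } else {
          for (int t = 1; t <= ray.nstep; ++t) {
            double rr = r + t * ray.dr, cc = c + t * ray.dc;
            if (rr < 0 || rr > nr - 1 || cc < 0 || cc > nc - 1) break;
            double v = sample_bilinear(z, rr, cc);
            if (!R_finite(v)) continue;
            double phi = std::atan((v - z0) / (t * ray.step_len));
            sw += w[k][t];
            swphi += w[k][t] * phi;
          }
        }
        if (sw > 0) acc += -(2.0 / PI_) * std::atan(swphi / sw);
      }
      out(r, c) = 1.0 + acc / n_azimuths;
    }
  return out;
}

// Horizon elevation angle (radians, >= 0) per azimuth sector, used for
// cast-shadow tests in the solar model. Returned as ncell x n_az with cells
// in R's column-major order.
// [[Rcpp::export]]
NumericMatrix horizon_cpp(NumericMatrix z, double cs, double radius,
                          int n_azimuths) {
  const int nr = z.nrow(), nc = z.ncol();
  std::vector<Ray> rays = make_rays(n_azimuths, cs, radius);
  NumericMatrix out(nr * nc, n_azimuths);
  for (int k = 0; k < n_azimuths; ++k) {
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        if (!R_finite(z(r, c))) { out(r + c * nr, k) = NA_REAL; continue; }
        double h = std::atan(max_tan_along(z, r, c, rays[k], 1.0));
        out(r + c * nr, k) = h > 0 ? h : 0.0;
      }
  }
  return out;
}
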