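// Clear-sky irradiation accumulator. Sun positions and atmospheric terms
// are precomputed per time step in R; this kernel accumulates direct-beam
// energy on the tilted surface (with DEM horizon shading) plus isotropic
// diffuse energy weighted by the sky-view factor.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector solar_accumulate_cpp(NumericVector sinS, NumericVector cosS,
                                   NumericVector sinA, NumericVector cosA,
                                   NumericVector svf, NumericMatrix horizon,
                                   IntegerVector sun_sector,
                                   NumericVector sun_h, NumericVector sun_sinh,
                                   NumericVector sun_cosh,
                                   NumericVector sun_sinaz,
                                   NumericVector sun_cosaz,
                                   NumericVector beam, NumericVector diffuse,
                                   double step_hours) {
  const int ncell = sinS.size(), nstep = sun_h.size();
  NumericVector out(ncell);
  for (int i = 0; i < ncell; ++i) {
    if (!R_finite(sinS[i])) { out[i] = NA_REAL; continue; }
    double e = 0.0;
    const double sS = sinS[i], cS = cosS[i], sA = sinA[i], cA = cosA[i];
    const double sv = svf[i];
    for (int t = 0; t < nstep; ++t) {
      e += diffuse[t] * sv;
      if (sun_h[t] <= horizon(i, sun_sector[t])) continue;  // shaded
      // incidence on the slope/aspect-tilted surface
      double cosrel = sun_cosaz[t] * cA + sun_sinaz[t] * sA;
      double cinc = cS * sun_sinh[t] + sS * sun_cosh[t] * cosrel;
      if (cinc > 0) e += beam[t] * cinc;
    }
    out[i] = e * step_hours;
  }
  return out;
}
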