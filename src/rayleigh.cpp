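#include <Rcpp.h>
using namespace Rcpp;

// Steady-state Rayleigh-Sommerfeld sum over a discretised radiating surface.
//
// The continuous integral for a uniform-velocity source with characteristic
// source pressure p_s = rho * c * u0 is
//   p(x) = -(i k p_s / 2 pi) \int exp(i k r) / r dS,
// so the modulus returned here is (k p_s / 2 pi) |sum exp(i k r)/r dS|.
// Element positions and areas are precomputed in R (midpoint rule on the
// spherical cap); this routine only evaluates the oscillatory sum.
// [[Rcpp::export]]
NumericVector rayleigh_modulus_cpp(NumericVector px, NumericVector py,
                                   NumericVector pz, NumericVector ex,
                                   NumericVector ey, NumericVector ez,
                                   NumericVector area, double k,
                                   double source_pressure) {
  const R_xlen_t np = px.size();
  const R_xlen_t ne = ex.size();
  if (ey.size() != ne || ez.size() != ne || area.size() != ne)
    stop("element arrays must have equal length");
  if (py.size() != np || pz.size() != np)
    stop("field point arrays must have equal length");
  NumericVector out(np);
  const double pref = k * source_pressure / (2.0 * M_PI);
  for (R_xlen_t i = 0; i < np; ++i) {
    double re = 0.0, im = 0.0;
    const double xi = px[i], yi = py[i], zi = pz[i];
    for (R_xlen_t j = 0; j < ne; ++j) {
      const double dx = xi - ex[j];
      const double dy = yi - ey[j];
      const double dz = zi - ez[j];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double w = area[j] / r;
      const double kr = k * r;
      re += w * std::cos(kr);
      im += w * std::sin(kr);
    }
    out[i] = pref * std::sqrt(re * re + im * im);
  }
  return out;
}
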