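#include <Rcpp.h>
using namespace Rcpp;

// Explicit (forward-Euler) stepper for the Pennes bioheat equation
//   rho C dT/dt = div(k grad T) + w_b C_b (T_a - T) + s(t) Q
// on a regular grid with harmonic-mean face conductivities (conservative
// flux form across material interfaces).
//
// Boundary conditions: `fixed` marks voxels held at their initial value
// (Dirichlet); all grid faces are otherwise zero-flux.  The drivers pass
// the water voxels of the two faces perpendicular to z as fixed.
//
// The relay (hysteresis) controller is consulted once per step with the
// sensor-voxel temperature: ON -> OFF strictly above `upper`, OFF -> ON
// strictly below `lower`.  With `control = false` the source flag is frozen
// at `state0` (always-on / always-off runs).
//
// CEM43 thermal dose is accumulated every `dose_stride` steps using the
// piecewise-constant-in-time convention: dose += (stride * dt / 60) *
// R^(43 - T), R = r_above for T >= 43, r_below otherwise.
// [[Rcpp::export]]
List bhte_run_cpp(NumericVector T0, NumericVector Q, NumericVector rho,
                  NumericVector cp, NumericVector kth, NumericVector wb,
                  IntegerVector dims, double dx, double dt, int nsteps,
                  double t_start, double Ta, double Cb, int sensor,
                  bool control, double upper, double lower, bool state0,
                  LogicalVector fixed, bool accumulate_dose, double r_above,
                  double r_below, int dose_stride, int snapshot_stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (T0.size() != n || Q.size() != n || rho.size() != n || cp.size() != n ||
      kth.size() != n || wb.size() != n)
    stop("field arrays do not match grid dims");
  if (sensor < 0 || sensor >= n) stop("sensor index outside grid");
  if (fixed.size() != n) stop("fixed mask does not match grid dims");
  if (dt <= 0) stop("dt must be positive");

  std::vector<double> T(T0.begin(), T0.end());
  std::vector<double> Tn(n);
  const double inv_dx2 = 1.0 / (dx * dx);

  // Precompute face conductivities (harmonic mean / dx^2) and per-voxel
  // dt/(rho C), w_b C_b.
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  std::vector<double> gx(n, 0.0), gy(n, 0.0), gz(n, 0.0);
  auto hmean = [](double a, double b) {
    return (a + b > 0.0) ? 2.0 * a * b / (a + b) : 0.0;
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t id = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (i + 1 < nx) gx[id] = hmean(kth[id], kth[id + sx]) * inv_dx2;
        if (j + 1 < ny) gy[id] = hmean(kth[id], kth[id + sy]) * inv_dx2;
        if (k + 1 < nz) gz[id] = hmean(kth[id], kth[id + sz]) * inv_dx2;
      }
  std::vector<double> dt_rC(n), perf(n);
  for (R_xlen_t id = 0; id < n; ++id) {
    dt_rC[id] = dt / (rho[id] * cp[id]);
    perf[id] = wb[id] * Cb;
  }

  NumericVector trace_t(nsteps), trace_T(nsteps);
  LogicalVector trace_on(nsteps);
  std::vector<double> dose;
  if (accumulate_dose) dose.assign(n, 0.0);
  List snapshots;
  const double ln_ra = std::log(r_above), ln_rb = std::log(r_below);

  bool on = state0;
  for (int step = 0; step < nsteps; ++step) {
    if (control) {
      const double Ts = T[sensor];
      if (on && Ts > upper) on = false;
      else if (!on && Ts < lower) on = true;
    }
    const double s = on ? 1.0 : 0.0;
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        R_xlen_t id = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = 0; i < nx; ++i, ++id) {
          if (fixed[id]) { Tn[id] = T[id]; continue; }
          const double Tc = T[id];
          double flux = 0.0;
          if (i + 1 < nx) flux += gx[id] * (T[id + sx] - Tc);
          if (i > 0) flux += gx[id - sx] * (T[id - sx] - Tc);
          if (j + 1 < ny) flux += gy[id] * (T[id + sy] - Tc);
          if (j > 0) flux += gy[id - sy] * (T[id - sy] - Tc);
          if (k + 1 < nz) flux += gz[id] * (T[id + sz] - Tc);
          if (k > 0) flux += gz[id - sz] * (T[id - sz] - Tc);
          Tn[id] = Tc + dt_rC[id] * (flux + perf[id] * (Ta - Tc) + s * Q[id]);
        }
      }
    }
    T.swap(Tn);
    trace_t[step] = t_start + (step + 1) * dt;
    trace_T[step] = T[sensor];
    trace_on[step] = on;
    if (accumulate_dose && ((step + 1) % dose_stride == 0)) {
      const double mins = dose_stride * dt / 60.0;
      for (R_xlen_t id = 0; id < n; ++id) {
        const double d43 = 43.0 - T[id];
        dose[id] += mins * std::exp(d43 * (T[id] >= 43.0 ? ln_ra : ln_rb));
      }
    }
    if (snapshot_stride > 0 && ((step + 1) % snapshot_stride == 0)) {
      NumericVector snap(T.begin(), T.end());
      snapshots.push_back(snap);
    }
  }

  List out = List::create(
      _["T"] = NumericVector(T.begin(), T.end()), _["trace_t"] = trace_t,
      _["trace_T"] = trace_T, _["trace_on"] = trace_on,
      _["final_on"] = on);
  if (accumulate_dose)
    out["dose"] = NumericVector(dose.begin(), dose.end());
  if (snapshot_stride > 0) out["snapshots"] = snapshots;
  return out;
}
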