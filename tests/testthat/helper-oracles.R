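# Independent closed-form oracles used across the suite.  These are written
# directly from the analytic solutions, not from the package's numerics.

# Axial pressure magnitude of a uniform spherical-cap source with an
# optional concentric opening (difference of two full caps); apex at z = 0,
# radius of curvature A, characteristic source pressure ps = rho c u0.
oracle_axial_bowl <- function(ps, frequency, outer_diameter, A, z,
                              opening = 0, sound_speed = 1482) {
  k <- 2 * pi * frequency / sound_speed
  ct1 <- cos(asin(outer_diameter / 2 / A))
  ct0 <- cos(asin(opening / 2 / A))
  r1 <- sqrt(A^2 + (z - A)^2 + 2 * A * (z - A) * ct1)
  r0 <- sqrt(A^2 + (z - A)^2 + 2 * A * (z - A) * ct0)
  near_focus <- abs(z - A) < 1e-9
  out <- ps * abs(A / (A - z)) * Mod(exp(1i * k * r1) - exp(1i * k * r0))
  out[near_focus] <- ps * k * A * (ct0 - ct1)
  out
}

# ON/OFF phase durations of an ideal relay oscillator whose temperature
# relaxes exponentially toward T_inf_on (source on) or T_inf_off (off) with
# rate gamma, switching at upper/lower thresholds.
oracle_relay_periods <- function(gamma, T_inf_on, T_inf_off, lower, upper) {
  stopifnot(T_inf_on > upper, T_inf_off < lower)
  t_on <- log((T_inf_on - lower) / (T_inf_on - upper)) / gamma
  t_off <- log((upper - T_inf_off) / (lower - T_inf_off)) / gamma
  c(on = t_on, off = t_off)
}

# Dense-grid 1-D FTCS reference solver for the source-free heat equation in
# a two-medium rod with harmonic-mean interface conductivity and insulated
# ends; written independently of the package kernel.
oracle_rod_1d <- function(T0_fun, rho, cp, kth, length_m, dx, dt, nsteps) {
  n <- round(length_m / dx)
  x <- (seq_len(n) - 0.5) * dx
  half <- x < length_m / 2
  rr <- ifelse(half, rho[1], rho[2])
  cc <- ifelse(half, cp[1], cp[2])
  kk <- ifelse(half, kth[1], kth[2])
  temp <- T0_fun(x)
  gface <- 2 * kk[-n] * kk[-1] / (kk[-n] + kk[-1]) / dx^2
  for (s in seq_len(nsteps)) {
    f <- gface * diff(temp)            # f[i] = flux between cell i and i+1
    div <- c(f, 0) - c(0, f)
    temp <- temp + dt / (rr * cc) * div
  }
  list(x = x, temperature = temp)
}

# Uniform-tissue material map with custom properties (single row table).
custom_uniform_map <- function(grid, density = 1000, sound_speed = 1500,
                               attenuation = 0, conductivity = 0.5,
                               specific_heat = 4000, perfusion = 0,
                               medium = "tissue") {
  tab <- data.frame(medium = medium, density = density,
                    sound_speed = sound_speed, attenuation = attenuation,
                    conductivity = conductivity,
                    specific_heat = specific_heat, perfusion = perfusion,
                    stringsAsFactors = FALSE)
  structure(list(grid = grid,
                 media = array(1L, dim = c(grid$nx, grid$ny, grid$nz)),
                 table = tab),
            class = "material_map")
}

# Wrap a bare amplitude array as a pressure_field for focal_metrics tests.
as_pressure_field <- function(amplitude, grid, frequency = 350e3) {
  structure(list(amplitude = amplitude, grid = grid, frequency = frequency,
                 transducer = NULL),
            class = "pressure_field")
}
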