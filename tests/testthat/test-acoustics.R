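test_that("transducer and grid constructors enforce their invariants", {
  expect_error(transducer_spec(aperture_diameter = 70e-3,
                               radius_of_curvature = 31.5e-3),
               "twice the radius")
  expect_error(transducer_spec(central_opening = 50e-3), "smaller")
  expect_error(simulation_grid(spacing = 0), "spacing")
  g <- simulation_grid(0.5e-3, c(0.02, 0.02, 0.03))
  expect_true(g$nx %% 2 == 1)           # beam axis is sampled
  expect_equal(g$x[(g$nx + 1) / 2], 0)
})

test_that("on-axis pressure matches the closed-form bowl solution within 1%", {
  z <- seq(5e-3, 48e-3, by = 3.1e-4)
  z <- z[abs(z - 31.5e-3) > 1e-6]
  for (opening in c(0, 12e-3)) {
    tr <- transducer_spec(surface_pressure = 1e5, active_diameter = 40e-3,
                          central_opening = opening)
    num <- rayleigh_at_points(tr, cbind(0, 0, z))
    ana <- oracle_axial_bowl(1e5, tr$frequency, tr$active_diameter,
                             tr$radius_of_curvature, z, opening)
    sel <- ana > 0.02 * max(ana)        # away from pressure nulls
    expect_lt(max(abs(num - ana)[sel] / ana[sel]), 0.01)
  }
})

test_that("the field is linear in surface pressure and zero drive gives zero field", {
  g <- simulation_grid(0.7e-3, c(0.02, 0.02, 0.04))
  mat <- uniform_materials(g, "water")
  tr1 <- transducer_spec(surface_pressure = 5e4)
  tr3 <- transducer_spec(surface_pressure = 1.5e5)
  f1 <- rayleigh_pressure_field(tr1, g, mat, n_theta = 48L, n_phi = 64L)
  f3 <- rayleigh_pressure_field(tr3, g, mat, n_theta = 48L, n_phi = 64L)
  expect_equal(f3$amplitude, 3 * f1$amplitude, tolerance = 1e-12)
  q1 <- heat_source(f1, uniform_materials(g, "tumor"))
  q3 <- heat_source(f3, uniform_materials(g, "tumor"))
  expect_equal(q3$q, 9 * q1$q, tolerance = 1e-12)
  tr0 <- transducer_spec(surface_pressure = 0)
  f0 <- rayleigh_pressure_field(tr0, g, mat, n_theta = 48L, n_phi = 64L)
  expect_true(all(f0$amplitude == 0))
})

test_that("cap quadrature is converged: doubling elements moves the focal value < 0.5%", {
  tr <- transducer_spec(surface_pressure = 1e5)
  focus <- cbind(0, 0, tr$radius_of_curvature - 2e-3)
  p1 <- rayleigh_at_points(tr, focus, n_theta = 96L, n_phi = 128L)
  p2 <- rayleigh_at_points(tr, focus, n_theta = 192L, n_phi = 256L)
  expect_lt(abs(p2 - p1) / p2, 0.005)
})

test_that("grid coarseness and focus placement are rejected", {
  tr <- transducer_spec()
  g_coarse <- simulation_grid(1e-3, c(0.02, 0.02, 0.04))
  expect_error(rayleigh_pressure_field(tr, g_coarse,
                                       uniform_materials(g_coarse, "water")),
               "points per wavelength")
  g_short <- simulation_grid(0.7e-3, c(0.02, 0.02, 0.02))
  expect_error(rayleigh_pressure_field(tr, g_short,
                                       uniform_materials(g_short, "water")),
               "focus")
})

test_that("attenuation only ever reduces amplitude beyond the skin", {
  g <- simulation_grid(0.7e-3, c(0.024, 0.024, 0.045))
  tr <- calibrate_transducer(transducer_spec(), 1e6)
  ph <- layered_phantom()
  mat <- build_phantom_fixture(ph, g)
  f_tissue <- rayleigh_pressure_field(tr, g, mat, n_theta = 48L,
                                      n_phi = 64L)
  f_water <- rayleigh_pressure_field(tr, g, uniform_materials(g, "water"),
                                     n_theta = 48L, n_phi = 64L)
  beyond <- rep(g$z >= ph$water_standoff, each = g$nx * g$ny)
  expect_true(all(f_tissue$amplitude[beyond] <=
                    f_water$amplitude[beyond] + 1e-9))
})

test_that("focal metrics recover the Gaussian half-intensity width", {
  g <- simulation_grid(0.1e-3, c(0.01, 0.01, 0.02))
  sigma <- 1e-3
  z0 <- g$z[g$nz %/% 2]                # peak on a voxel center
  r2 <- outer(outer(g$x^2, g$y^2, "+"), (g$z - z0)^2 / 25, "+")
  amp <- exp(-r2 / (2 * sigma^2))
  fm <- focal_metrics(as_pressure_field(amp, g))
  expect_equal(fm$lateral_width, 2 * sigma * sqrt(log(2)), tolerance = 1e-3)
  expect_equal(fm$axial_length, 5 * 2 * sigma * sqrt(log(2)),
               tolerance = 1e-3)
})

test_that("degenerate fields are rejected by focal_metrics", {
  g <- simulation_grid(0.5e-3, c(0.005, 0.005, 0.01))
  uniform <- array(1, dim = c(g$nx, g$ny, g$nz))
  expect_error(focal_metrics(as_pressure_field(uniform, g)), "unique")
  edge <- array(0, dim = c(g$nx, g$ny, g$nz))
  edge[1, 1, 1] <- 1
  expect_error(focal_metrics(as_pressure_field(edge, g)), "boundary")
})

test_that("plane-wave intensity follows p^2/(2 rho c)", {
  expect_equal(intensity_from_pressure(1e6, 1000, 1482),
               1e12 / (2 * 1000 * 1482))
  # 1 MPa in water is 33.7 W/cm^2, which reports rounded as 34
  expect_equal(round(intensity_from_pressure(1e6) * 1e-4), 34)
  expect_equal(intensity_from_pressure(0), 0)
  expect_equal(intensity_from_pressure(0.5e6),
               intensity_from_pressure(1e6) / 4)
  expect_error(intensity_from_pressure(1e6, density = 0), "density")
  expect_error(intensity_from_pressure(1e6, sound_speed = -1), "sound_speed")
})

test_that("heat source deposits alpha p^2 / (rho c), zero in water", {
  g <- simulation_grid(0.7e-3, c(0.005, 0.005, 0.01))
  amp <- array(1e6, dim = c(g$nx, g$ny, g$nz))
  fld <- as_pressure_field(amp, g)
  q_w <- heat_source(fld, uniform_materials(g, "water"))
  expect_true(all(q_w$q == 0))
  q_t <- heat_source(fld, uniform_materials(g, "tumor"))
  alpha <- 9.32 * 0.35
  expect_equal(q_t$q[1, 1, 1], alpha * 1e12 / (1060 * 1560))
  expect_equal(q_t$q[1, 1, 1], 1.97e6, tolerance = 0.01)
  # Q = 2 alpha I exactly
  I <- intensity_from_pressure(1e6, 1060, 1560)
  expect_equal(q_t$q[1, 1, 1], 2 * alpha * I, tolerance = 1e-12)
  g2 <- simulation_grid(0.5e-3, c(0.005, 0.005, 0.01))
  expect_error(heat_source(fld, uniform_materials(g2, "tumor")),
               "different grids")
})

test_that("source calibration hits the requested lossless focal peak", {
  tr <- calibrate_transducer(transducer_spec(), 1e6)
  z <- seq(20e-3, 40e-3, by = 1e-4)
  pk <- max(rayleigh_at_points(tr, cbind(0, 0, z)))
  expect_equal(pk, 1e6, tolerance = 1e-4)
})
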