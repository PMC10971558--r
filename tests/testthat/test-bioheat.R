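make_box <- function(n = 7L, dx = 1e-3, ...) {
  g <- simulation_grid(dx, c(n * dx, n * dx, n * dx))
  list(grid = g, map = custom_uniform_map(g, ...))
}

test_that("uniform insulated tissue at equilibrium stays exactly put", {
  b <- make_box()
  cfg <- bhte_config(boundary = "insulated", equilibration = 30,
                     initial_tissue = 37, initial_water = 37)
  Teq <- equilibrate(b$map, cfg)
  expect_true(all(Teq$temperature == 37))
})

test_that("insulated perfusion-free stepping conserves the discrete energy budget", {
  b <- make_box(specific_heat = 3700, density = 1060, conductivity = 0.5)
  g <- b$grid
  cfg <- bhte_config(boundary = "insulated")
  set.seed(11)
  temp <- structure(list(temperature = array(37 + runif(g$nx * g$ny * g$nz),
                                             dim = c(g$nx, g$ny, g$nz)),
                         grid = g, time = 0),
                    class = "temperature_field")
  qarr <- array(runif(g$nx * g$ny * g$nz, 0, 1e5),
                dim = c(g$nx, g$ny, g$nz))
  dt <- 0.5 * stability_dt(b$map, cfg)
  rc <- 1060 * 3700
  for (i in 1:10) {
    before <- sum(rc * temp$temperature)
    temp <- bhte_step(temp, qarr, dt, cfg, b$map)
    gained <- sum(temp$temperature * rc) - before
    expect_equal(gained, sum(qarr) * dt, tolerance = 1e-12)
  }
  # and over many source-free steps the total enthalpy is constant
  t2 <- temp
  e0 <- sum(t2$temperature)
  for (i in 1:1000) t2 <- bhte_step(t2, NULL, dt, cfg, b$map)
  expect_equal(sum(t2$temperature), e0, tolerance = 1e-12)
})

test_that("source-free fields obey the maximum principle", {
  b <- make_box(n = 9L)
  cfg <- bhte_config(boundary = "insulated")
  g <- b$grid
  set.seed(7)
  temp <- structure(list(temperature = array(runif(g$nx * g$ny * g$nz, 20, 40),
                                             dim = c(g$nx, g$ny, g$nz)),
                         grid = g, time = 0),
                    class = "temperature_field")
  lo <- min(temp$temperature); hi <- max(temp$temperature)
  dt <- 0.5 * stability_dt(b$map, cfg)
  for (i in 1:200) {
    temp <- bhte_step(temp, NULL, dt, cfg, b$map)
    expect_gte(min(temp$temperature), lo - 1e-12)
    expect_lte(max(temp$temperature), hi + 1e-12)
  }
})

test_that("lumped perfusion relaxation matches the closed-form exponential within 0.5%", {
  # conduction off: pure perfusion return toward arterial temperature
  b <- make_box(n = 3L, conductivity = 0, perfusion = 2,
                density = 1000, specific_heat = 4000)
  cb <- 3700
  tau <- 1000 * 4000 / (2 * cb)
  cfg <- bhte_config(dt = tau / 2000, boundary = "insulated",
                     blood_temperature = 37, blood_specific_heat = cb,
                     initial_tissue = 30, initial_water = 30,
                     equilibration = tau)
  Teq <- equilibrate(b$map, cfg)
  expected <- 37 - 7 * exp(-1)
  expect_equal(Teq$temperature[2, 2, 2], expected, tolerance = 0.005)
})

test_that("perfusion strictly removes enthalpy when tissue is hotter than blood", {
  b <- make_box(perfusion = 5)
  cfg <- bhte_config(boundary = "insulated", blood_temperature = 37)
  g <- b$grid
  temp <- structure(list(temperature = array(42, dim = c(g$nx, g$ny, g$nz)),
                         grid = g, time = 0),
                    class = "temperature_field")
  dt <- 0.5 * stability_dt(b$map, cfg)
  for (i in 1:20) {
    nxt <- bhte_step(temp, NULL, dt, cfg, b$map)
    expect_lt(sum(nxt$temperature), sum(temp$temperature))
    expect_gte(min(nxt$temperature), 37)
    temp <- nxt
  }
})

test_that("a coarse two-medium rod tracks a dense-grid reference within 1%", {
  len <- 0.02
  rho <- c(1000, 1060); cp <- c(4118, 3700); kth <- c(0.627, 0.5)
  T0_fun <- function(x) 30 + 10 * (x > len / 2)
  dx_c <- 5e-4
  g <- simulation_grid(dx_c, c(dx_c, dx_c, len))
  media <- array(1L, dim = c(1, 1, g$nz))
  media[1, 1, g$z > len / 2] <- 2L
  tab <- data.frame(medium = c("a", "b"), density = rho, sound_speed = 1500,
                    attenuation = 0, conductivity = kth, specific_heat = cp,
                    perfusion = 0)
  map <- structure(list(grid = g, media = media, table = tab),
                   class = "material_map")
  cfg <- bhte_config(boundary = "insulated")
  dt_c <- 0.5 * stability_dt(map, cfg)
  temp <- structure(list(temperature = array(T0_fun(g$z), dim = dim(media)),
                         grid = g, time = 0),
                    class = "temperature_field")
  for (i in 1:100) temp <- bhte_step(temp, NULL, dt_c, cfg, map)
  t_end <- 100 * dt_c
  dx_f <- 1e-4
  dt_f <- 0.4 * min(rho * cp) * dx_f^2 / (2 * max(kth))
  ref <- oracle_rod_1d(T0_fun, rho, cp, kth, len, dx_f, dt_f,
                       round(t_end / dt_f))
  ref_at <- approx(ref$x, ref$temperature, xout = g$z)$y
  expect_lt(max(abs(as.vector(temp$temperature) - ref_at)) / 10, 0.01)
})

test_that("time steps beyond the stability bound are refused", {
  b <- make_box()
  cfg <- bhte_config(dt = 10 * stability_dt(b$map, bhte_config()))
  expect_error(equilibrate(b$map, cfg), "stability")
})

test_that("halving the grid spacing leaves the sensor trace nearly unchanged", {
  # fixed (uncontrolled) source so switching-time jitter cannot enter
  run_at <- function(dx) {
    ext <- c(0.016, 0.016, 0.024)
    g <- simulation_grid(dx, ext)
    map <- custom_uniform_map(g, density = 1060, specific_heat = 3700,
                              conductivity = 0.5, perfusion = 2)
    r2 <- outer(outer(g$x^2, g$y^2, "+"), (g$z - 0.012)^2, "+")
    qarr <- 2e5 * exp(-r2 / (2 * (2e-3)^2))
    cfg <- bhte_config(boundary = "insulated", equilibration = 0)
    T0 <- initial_temperature(map, cfg)
    hist <- run_treatment(T0, qarr, controller = NULL, duration = 120,
                          config = cfg, materials = map,
                          accumulate_dose = FALSE)
    hist$trace
  }
  tr_c <- run_at(0.8e-3)
  tr_f <- run_at(0.4e-3)
  at <- seq(5, 115, by = 5)
  Tc <- approx(tr_c$time_s, tr_c$sensor_c, xout = at)$y
  Tf <- approx(tr_f$time_s, tr_f$sensor_c, xout = at)$y
  expect_lt(max(abs(Tc - Tf)), 0.2)
})

test_that("a zero source under control reduces to continued equilibration", {
  g <- simulation_grid(1e-3, c(0.01, 0.01, 0.02))
  ph <- layered_phantom(tumor_diameter = 4e-3, focal_length = 14e-3)
  map <- build_phantom_fixture(ph, g)
  cfg <- bhte_config(equilibration = 20)
  T0 <- equilibrate(map, cfg)
  treated <- run_treatment(T0, NULL, hysteresis_controller(), duration = 20,
                           config = cfg, materials = map,
                           accumulate_dose = FALSE)
  cfg2 <- bhte_config(equilibration = 40)
  T40 <- equilibrate(map, cfg2)
  expect_equal(treated$final$temperature, T40$temperature,
               tolerance = 1e-12)
  # the relay may ask for heat the whole time, but with Q = 0 nothing burns
  expect_true(all(treated$trace$source_on))
})

test_that("equilibration leaves skin-adjacent water cooler than the deep tissue", {
  g <- simulation_grid(0.8e-3, c(0.0208, 0.0208, 0.04))
  ph <- layered_phantom()
  map <- build_phantom_fixture(ph, g)
  Teq <- equilibrate(map, bhte_config())
  cx <- (g$nx + 1) / 2
  iz_water <- max(which(g$z < ph$water_standoff))
  ctr <- nearest_voxel(g, ph$tumor_center)
  expect_lt(Teq$temperature[cx, cx, iz_water],
            Teq$temperature[ctr[1], ctr[2], ctr[3]])
  # water boundary slices stay clamped at their initial temperature
  expect_true(all(Teq$temperature[, , 1] == 23))
})
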