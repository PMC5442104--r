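test_that("O2-profile fit recovers noise-free generating parameters", {
  x <- seq(0, 120, by = 5)
  d <- data.frame(distance_um = x,
                  o2_fraction = 0.05 * exp(-(x / 15)^2 / (2 * 2.4^2)))
  r <- fit_o2_profile(d)
  expect_equal(r$s, 0.05, tolerance = 1e-8)
  expect_equal(r$sigma, 2.4, tolerance = 1e-8)
})

test_that("O2-profile fit handles noise and mmHg conversion", {
  x <- seq(0, 150, by = 3)
  set.seed(33)
  y <- 0.05 * exp(-(x / 15)^2 / (2 * 2.4^2)) * (1 + 0.05 * rnorm(length(x)))
  r <- fit_o2_profile(data.frame(distance_um = x, o2_fraction = y))
  expect_equal(r$sigma, 2.4, tolerance = 0.05)
  expect_true(r$ci95_sigma[1] <= 2.4 && 2.4 <= r$ci95_sigma[2])

  # 40 mmHg at the wall converts to 40/760 of an atmosphere
  dm <- data.frame(distance_px = c(0, 2, 4, 6),
                   o2_mmhg = 40 * exp(-c(0, 2, 4, 6)^2 / (2 * 2.4^2)))
  rm_ <- fit_o2_profile(dm)
  expect_equal(rm_$s, 40 / 760, tolerance = 1e-6)

  expect_error(fit_o2_profile(data.frame(distance_um = c(0, 1),
                                         o2_fraction = c(0.05, 0.04))),
               "at least 3")
})

test_that("HRF fit recovers (m, K) from its own curve, from the standard start", {
  o2 <- c(0, 0.0005, 0.001, 0.002, 0.005, 0.01, 0.03, 0.05, 0.1, 0.21)
  d <- data.frame(o2_fraction = o2,
                  hrf = (2.804 * 0.001076 + o2) / (0.001076 + o2))
  r <- fit_hrf(d, init_m = 2.7, init_K = 0.002)
  expect_equal(r$m, 2.804, tolerance = 1e-7)
  expect_equal(r$K, 0.001076, tolerance = 1e-7)
  expect_error(fit_hrf(d[1, , drop = FALSE]), "at least 3")
})

test_that("amplitude calibration hits the mean-oxygen target", {
  geom <- geometry_params(grid_side = 300L, tumour_radius_px = 25L)
  ox <- oxygen_params(s = 1)
  expect_equal(calibrate_amplitude(geom, ox, target_mean = 0), 0)
  expect_error(calibrate_amplitude(geom, ox, target_mean = 0.06),
               "unreachable")
  s_cal <- calibrate_amplitude(geom, ox, target_mean = 0.03, seeds = 1:3)
  ox$s <- s_cal
  achieved <- mean(vapply(1:3, function(sd) {
    st <- init_tissue(geom, seed = sd)
    mean_tumour_oxygen(compute_oxygen_map(st, ox), st)
  }, numeric(1)))
  expect_equal(achieved, 0.03, tolerance = 1e-4)
  # denser vasculature needs a smaller amplitude (sub-linearly, via the cap)
  geom2 <- geometry_params(grid_side = 300L, tumour_radius_px = 25L,
                           vessel_density = 0.076)
  s2 <- calibrate_amplitude(geom2, oxygen_params(s = 1), 0.03, seeds = 1:3)
  expect_lt(abs(s2 - s_cal / 2) / (s_cal / 2), 0.15)
})

test_that("diffusion selection returns the feasible sigma and flags failure", {
  geom <- geometry_params(grid_side = 300L, tumour_radius_px = 25L)
  r <- calibrate_diffusion(geom, sigma_range = 2.4, seeds = 1:3)
  expect_equal(r$sigma, 2.4)
  expect_error(calibrate_diffusion(geom, sigma_range = 2.4,
                                   max_hypoxia = -1),
               "impossible")
  expect_error(calibrate_diffusion(geom, sigma_range = numeric(0)), "empty")
})

test_that("leak-factor sweep recovers the generating value round-trip", {
  geom <- scaled_geometry()
  ox <- oxygen_params()
  radio <- radiobiology_params()  # leak_factor 1.5
  prot <- protocol(2, 16, start_day = 8, horizon_days = 20)
  target <- run_simulation(geom, ox, radio, prot, seed = 14)
  series <- data.frame(day = target$day,
                       hypoxic_fraction = target$hypoxic_fraction)
  r <- calibrate_leak_factor(series, lf_range = c(1.0, 1.3, 1.5, 1.7),
                             geom = geom, ox = ox, radio = radio,
                             prot = prot, seed = 14)
  expect_equal(r$leak_factor, 1.5)
  expect_equal(r$sweep$sse[r$sweep$leak_factor == 1.5], 0)
  expect_error(calibrate_leak_factor(series, lf_range = numeric(0),
                                     geom = geom, ox = ox, radio = radio,
                                     prot = prot),
               "empty")
})

test_that("growth-layer sweep recovers n = 3 and grows monotonically in n", {
  geom <- scaled_geometry()
  ox <- oxygen_params()
  prot <- protocol(1, 0, start_day = 0, horizon_days = 12)
  radio <- radiobiology_params()
  target <- run_simulation(geom, ox, radio, prot, seed = 15)
  growth <- data.frame(day = target$day, volume_mm3 = target$volume_mm3)
  r <- calibrate_growth_layers(growth, n_range = 1:4, geom = geom, ox = ox,
                               seed = 15)
  expect_identical(r$n_layers, 3L)
  expect_equal(r$sweep$sse[r$sweep$n_layers == 3], 0)
  # final simulated volume rises with the number of dividing layers
  finals <- vapply(1:4, function(n) {
    g <- geom; g$n_layers <- n
    traj <- run_simulation(g, ox, radio, prot, seed = 15)
    traj$volume_mm3[nrow(traj)]
  }, numeric(1))
  expect_true(all(diff(finals) > 0))
})
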