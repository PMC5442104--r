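# scaled-down cohort settings used throughout this file
cohort_geom <- scaled_geometry()
cohort_ox <- oxygen_params()
cohort_radio <- radiobiology_params()

test_that("sigmoid fit recovers noise-free generating parameters", {
  dose <- seq(3, 90, by = 3)
  pts <- data.frame(cumulative_dose = dose,
                    tcp = 1 / (1 + exp(-0.2 * dose + 8)))
  ft <- fit_tcp(pts)
  expect_equal(ft$lambda, 0.2, tolerance = 1e-6)
  expect_equal(ft$delta, 8, tolerance = 1e-6)
  expect_equal(ft$tcp50, 40, tolerance = 1e-6)
})

test_that("sigmoid fit recovers parameters from binomial cohort noise", {
  dose <- seq(3, 90, by = 3)
  p <- 1 / (1 + exp(-0.15 * dose + 6.3))  # TCP50 = 42 Gy
  set.seed(77)
  pts <- data.frame(cumulative_dose = dose,
                    tcp = rbinom(length(dose), 100, p) / 100)
  ft <- fit_tcp(pts)
  expect_equal(ft$tcp50, 42, tolerance = 0.06)
  expect_true(ft$ci95[1] < 42 && 42 < ft$ci95[2] + 2)
})

test_that("degenerate TCP curves are rejected by the fit", {
  dose <- seq(3, 30, by = 3)
  expect_error(fit_tcp(data.frame(cumulative_dose = dose, tcp = 0)),
               "degenerate")
  expect_error(fit_tcp(data.frame(cumulative_dose = dose, tcp = 1)),
               "degenerate")
  expect_error(fit_tcp(data.frame(cumulative_dose = 1:2, tcp = c(0, 1))),
               "at least 3")
})

test_that("extreme fraction sizes give extreme cohort outcomes", {
  # one enormous fully oxygenated fraction: control at the first point
  prot <- protocol(100, 100, start_day = 8, horizon_days = 10)
  cu <- simulate_cohort(cohort_geom, cohort_ox, cohort_radio, prot,
                        n_mice = 5, base_seed = 1,
                        scenario = "full_oxygenation")
  expect_equal(cu$points$tcp[1], 1)
  # negligible fractions: no control anywhere
  prot0 <- protocol(0.01, 0.05, start_day = 8, horizon_days = 12)
  cu0 <- simulate_cohort(cohort_geom, cohort_ox, cohort_radio, prot0,
                         n_mice = 5, base_seed = 1)
  expect_true(all(cu0$points$tcp == 0))
})

test_that("TCP is monotone in dose and cohorts are seed-reproducible", {
  prot <- protocol(3, 36, start_day = 8, horizon_days = 30)
  cu <- simulate_cohort(cohort_geom, cohort_ox, cohort_radio, prot,
                        n_mice = 12, base_seed = 5)
  expect_true(all(diff(cu$points$tcp) >= 0))
  expect_true(all(apply(cu$controlled, 1, function(x) all(diff(x) >= 0))))
  cu2 <- simulate_cohort(cohort_geom, cohort_ox, cohort_radio, prot,
                         n_mice = 12, base_seed = 5)
  expect_identical(cu$points, cu2$points)
})

test_that("biology scenarios order TCP50 as hypoxia and perfusion dictate", {
  prot <- protocol(3, 60, start_day = 8, horizon_days = 40)
  tab <- compare_scenarios(list(p3 = prot),
                           c("full_oxygenation", "dlo", "dlo_vperf"),
                           cohort_geom, cohort_ox, cohort_radio,
                           n_mice = 24, base_seed = 3)
  t50 <- setNames(tab$tcp50, tab$scenario)
  # neglecting hypoxia underestimates the dose needed
  expect_lte(t50[["full_oxygenation"]], t50[["dlo"]] + 1e-9)
  # perfusion brings control back toward (but not past) full oxygenation
  expect_lte(t50[["dlo_vperf"]], t50[["dlo"]] + 1e-9)
  expect_error(compare_scenarios(list(prot), "warp_drive", cohort_geom,
                                 cohort_ox, cohort_radio, n_mice = 2),
               "arg")
})

test_that("vessel death is a no-op below its 6 Gy threshold", {
  prot <- protocol(2, 20, start_day = 8, horizon_days = 25)
  a <- simulate_cohort(cohort_geom, cohort_ox, cohort_radio, prot,
                       n_mice = 8, base_seed = 2, scenario = "dlo_vperf")
  b <- simulate_cohort(cohort_geom, cohort_ox, cohort_radio, prot,
                       n_mice = 8, base_seed = 2,
                       scenario = "dlo_vperf_vdeath")
  expect_identical(a$points, b$points)
  expect_identical(a$controlled, b$controlled)
})

test_that("bootstrap CI on TCP50 brackets the delta-method estimate", {
  dose <- seq(3, 60, by = 3)
  p <- 1 / (1 + exp(-0.2 * dose + 7))
  set.seed(42)
  controlled <- t(vapply(seq_len(40), function(i) {
    thr <- runif(1)
    as.logical(p >= thr)  # monotone per-mouse outcome
  }, logical(length(dose))))
  cu <- structure(list(points = data.frame(fraction = seq_along(dose),
                                           day = dose, cumulative_dose = dose,
                                           tcp = colMeans(controlled)),
                       controlled = controlled, n_mice = 40,
                       protocol = NULL, scenario = "dlo", base_seed = 1),
                  class = "tcp_curve")
  ft_d <- fit_tcp(cu)
  set.seed(9)
  ft_b <- fit_tcp(cu, ci = "bootstrap", n_boot = 100)
  expect_equal(ft_b$tcp50, ft_d$tcp50)
  expect_true(ft_b$ci95[1] <= ft_d$tcp50 && ft_d$tcp50 <= ft_b$ci95[2])
})
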