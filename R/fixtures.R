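#' Generate synthetic calibration fixtures
#'
#' Writes a bundle of small CSV tables generated from the model's own
#' equations/simulator with known parameters, for tests and demos:
#' `profile.csv` (single-vessel O2 vs distance), `hrf.csv`
#' (Howard-Flanders HRF vs O2), `growth.csv` (unirradiated volume curve)
#' and `hypoxia.csv` (hypoxic fraction under 2 Gy daily). The growth and
#' hypoxia series come from a scaled-down tissue (240 px grid, 20 px
#' tumour) so generation stays fast; the generating parameters are written
#' alongside in `fixture-params.json`. All tables are synthetic: they stand
#' in for literature measurements that are not distributed with the
#' package.
#'
#' @param dir Output directory.
#' @param seed Seed for the simulated series.
#' @param noise_sd Multiplicative noise (relative sd) applied to the
#'   profile and HRF tables; 0 (default) gives exact model values.
#' @return Named list of file paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1, noise_sd = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  pars <- list(profile = list(s = 0.05, sigma_px = 2.4,
                              pixel_size_um = 15),
               hrf = list(m = 2.804, K = 0.001076),
               series = list(grid_side = 240L, tumour_radius_px = 20L,
                             leak_factor = 1.5, n_layers = 3L,
                             seed = seed),
               noise_sd = noise_sd)

  noisy <- function(y) y * (1 + noise_sd * stats::rnorm(length(y)))

  x_um <- seq(0, 120, by = 5)
  profile <- data.frame(
    distance_um = x_um,
    o2_fraction = noisy(pars$profile$s *
      exp(-(x_um / pars$profile$pixel_size_um)^2 /
            (2 * pars$profile$sigma_px^2))))

  o2_grid <- c(0, 0.0005, 0.001, 0.002, 0.005, 0.01, 0.03, 0.05, 0.1, 0.21)
  hrf_tab <- data.frame(
    o2_fraction = o2_grid,
    hrf = noisy((pars$hrf$m * pars$hrf$K + o2_grid) /
                  (pars$hrf$K + o2_grid)))

  geom <- geometry_params(grid_side = pars$series$grid_side,
                          tumour_radius_px = pars$series$tumour_radius_px)
  ox <- oxygen_params()
  radio <- radiobiology_params(leak_factor = pars$series$leak_factor)

  growth_prot <- protocol(frac_dose = 1, total_dose = 0, start_day = 0L,
                          horizon_days = 15L)
  growth_traj <- run_simulation(geom, ox, radio, growth_prot, seed = seed)
  growth <- data.frame(day = growth_traj$day,
                       volume_mm3 = growth_traj$volume_mm3)

  hyp_prot <- protocol(frac_dose = 2, total_dose = 20, start_day = 5L,
                       horizon_days = 20L)
  hyp_traj <- run_simulation(geom, ox, radio, hyp_prot, seed = seed)
  hypoxia <- data.frame(day = hyp_traj$day,
                        hypoxic_fraction = hyp_traj$hypoxic_fraction)

  paths <- list(profile = file.path(dir, "profile.csv"),
                hrf = file.path(dir, "hrf.csv"),
                growth = file.path(dir, "growth.csv"),
                hypoxia = file.path(dir, "hypoxia.csv"),
                params = file.path(dir, "fixture-params.json"))
  utils::write.csv(profile, paths$profile, row.names = FALSE)
  utils::write.csv(hrf_tab, paths$hrf, row.names = FALSE)
  utils::write.csv(growth, paths$growth, row.names = FALSE)
  utils::write.csv(hypoxia, paths$hypoxia, row.names = FALSE)
  jsonlite::write_json(pars, paths$params, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
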