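#' Pixel state codes
#'
#' Integer codes used on the lattice. `EMPTY` (0) is free space,
#' `TUMOUR_NORMOXIC` (1) and `TUMOUR_HYPOXIC` (2) are viable tumour cells
#' (the split is a visual/metric reclassification by local oxygen, never an
#' input to the kill computation), `NORMAL` (3) is quiescent normal tissue,
#' `VESSEL` (4) a blood vessel crossing the plane perpendicularly, and
#' `LETHAL` (5) a tumour cell condemned to die at its next division
#' (mitotic catastrophe).
#'
#' @format Named integer vector of length 6.
#' @export
PIXEL_STATES <- c(
  EMPTY = 0L, TUMOUR_NORMOXIC = 1L, TUMOUR_HYPOXIC = 2L,
  NORMAL = 3L, VESSEL = 4L, LETHAL = 5L
)

# states counting as tumour for morphology (they occupy tumour space)
TUMOUR_MASK_STATES <- c(1L, 2L, 5L)
# states counting as viable for growth and control assessment
VIABLE_STATES <- c(1L, 2L)

#' Tissue geometry parameters
#'
#' @param grid_side Lattice side length in pixels.
#' @param pixel_size_um Side of one square cell in micrometres.
#' @param tumour_radius_px Radius of the initial tumour disk, pixels
#'   (50 px = 0.75 mm, i.e. a 1.5 mm diameter tumour at 15 um pixels).
#' @param normal_fraction Fraction of extratumoural space occupied by
#'   quiescent normal cells (permanent obstacles).
#' @param vessel_density Fraction of all lattice sites occupied by vessels.
#' @param n_layers Number of peripheral tumour cell layers allowed to divide
#'   per day.
#' @param cell_area_um2 Area of one cell, square micrometres.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(grid_side = 600L, pixel_size_um = 15,
                            tumour_radius_px = 50L, normal_fraction = 0.20,
                            vessel_density = 0.038, n_layers = 3L,
                            cell_area_um2 = 225) {
  grid_side <- as.integer(grid_side)
  tumour_radius_px <- as.integer(tumour_radius_px)
  n_layers <- as.integer(n_layers)
  stopifnot(grid_side > 0, pixel_size_um > 0, cell_area_um2 > 0,
            n_layers >= 1)
  if (normal_fraction < 0 || normal_fraction > 1)
    stop("normal_fraction must be in [0, 1]")
  if (vessel_density < 0 || vessel_density > 1)
    stop("vessel_density must be in [0, 1]")
  if (tumour_radius_px < 0 ||
      tumour_radius_px + n_layers >= grid_side / 2)
    stop("tumour (plus its growth layers) does not fit inside the grid")
  structure(list(grid_side = grid_side, pixel_size_um = pixel_size_um,
                 tumour_radius_px = tumour_radius_px,
                 normal_fraction = normal_fraction,
                 vessel_density = vessel_density, n_layers = n_layers,
                 cell_area_um2 = cell_area_um2),
            class = "geometry_params")
}

#' Oxygen field parameters
#'
#' The steady-state oxygen field is a Gaussian-filtered image of the vessel
#' map: an isolated vessel produces the radial profile
#' `O2(x) = s * exp(-x^2 / (2 sigma^2))`, peak-normalized so `s` is the O2
#' fraction at the vessel wall. Overlapping vessels sum; the summed field is
#' capped at `cap` (full saturation).
#'
#' @param sigma Gaussian sigma in pixels. The diffusion coefficient of the
#'   kernel is `D = sigma^2` (5.76 px^2 at the default 2.4).
#' @param s Peak O2 fraction contributed by one unhit vessel. The default is
#'   the amplitude calibrated by [calibrate_amplitude()] so that mean tumour
#'   O2 at initialization is 3% under the default geometry.
#' @param cap Saturation O2 fraction (0.05 = 5%).
#' @param hypoxia_threshold O2 fraction below which a pixel is counted as
#'   hypoxic (0.002 = 0.2%).
#' @return An object of class `oxygen_params`.
#' @export
oxygen_params <- function(sigma = 2.4, s = 0.02356, cap = 0.05,
                          hypoxia_threshold = 0.002) {
  stopifnot(sigma > 0, s >= 0, cap > 0)
  if (hypoxia_threshold <= 0 || hypoxia_threshold >= cap)
    stop("hypoxia_threshold must lie strictly between 0 and cap")
  structure(list(sigma = sigma, s = s, cap = cap,
                 hypoxia_threshold = hypoxia_threshold),
            class = "oxygen_params")
}

#' Radiobiology parameters
#'
#' Linear-quadratic coefficients for tumour cells at full oxygenation
#' (21% O2), the Howard-Flanders hypoxia reduction factor (HRF) describing
#' how low oxygen protects cells, endothelial LQ coefficients governing the
#' per-fraction probability that a vessel is "hit" and becomes leaky, the
#' leak factor applied to hit vessels, the linear dose ramp for outright
#' vessel death, and the dose-proportional growth-arrest slope.
#'
#' @param alpha,beta Tumour LQ coefficients (1/Gy, 1/Gy^2) at 21% O2.
#' @param hrf_m Maximum HRF (anoxic limit), dimensionless.
#' @param hrf_K O2 fraction at which HRF is half-maximal.
#' @param alpha_ec,beta_ec Endothelial LQ coefficients for the vessel hit
#'   probability. Not measured in this package; the defaults are surrogate
#'   values typical of endothelial clonogenic survival and should be
#'   replaced by fitted values when data are available.
#' @param leak_factor Multiplicative O2 increase for a hit vessel
#'   (plausible range 1.3-1.7).
#' @param vessel_death_threshold,vessel_death_max Dose (Gy) at which the
#'   linear vessel-death ramp starts (probability 0) and saturates
#'   (probability 1).
#' @param arrest_slope Growth-arrest hours per Gy (9 h/Gy reproduces 36 h
#'   after a single 4 Gy fraction).
#' @return An object of class `radiobiology_params`.
#' @export
radiobiology_params <- function(alpha = 0.0441, beta = 0.0898,
                                hrf_m = 2.804, hrf_K = 0.001076,
                                alpha_ec = 0.28, beta_ec = 0.045,
                                leak_factor = 1.5,
                                vessel_death_threshold = 6,
                                vessel_death_max = 35,
                                arrest_slope = 9) {
  stopifnot(alpha >= 0, beta >= 0, hrf_m > 1, hrf_K > 0,
            alpha_ec >= 0, beta_ec >= 0, leak_factor >= 1,
            vessel_death_threshold >= 0, arrest_slope >= 0)
  if (vessel_death_threshold >= vessel_death_max)
    stop("vessel_death_threshold must be below vessel_death_max")
  structure(list(alpha = alpha, beta = beta, hrf_m = hrf_m, hrf_K = hrf_K,
                 alpha_ec = alpha_ec, beta_ec = beta_ec,
                 leak_factor = leak_factor,
                 vessel_death_threshold = vessel_death_threshold,
                 vessel_death_max = vessel_death_max,
                 arrest_slope = arrest_slope),
            class = "radiobiology_params")
}

#' Fractionation protocol
#'
#' @param frac_dose Dose per fraction, Gy.
#' @param interval_days Days between consecutive fractions (Delta T).
#' @param start_day First treatment day. Day `start_day` is defined to be a
#'   Monday for weekend handling.
#' @param weekends_off If `TRUE`, no fraction is delivered on Saturdays or
#'   Sundays; delivery resumes on the next weekday.
#' @param total_dose Total dose, Gy; must be an integer multiple of
#'   `frac_dose`.
#' @param horizon_days Last simulated day (observation window for
#'   recurrence).
#' @return An object of class `protocol`.
#' @export
protocol <- function(frac_dose, total_dose, interval_days = 1L,
                     start_day = 21L, weekends_off = TRUE,
                     horizon_days = 80L) {
  interval_days <- as.integer(interval_days)
  start_day <- as.integer(start_day)
  horizon_days <- as.integer(horizon_days)
  stopifnot(frac_dose > 0, total_dose >= 0, start_day >= 0)
  if (interval_days < 1) stop("interval_days must be >= 1")
  n_frac <- total_dose / frac_dose
  if (abs(n_frac - round(n_frac)) > 1e-9)
    stop("total_dose must be an integer multiple of frac_dose")
  p <- structure(list(frac_dose = frac_dose, total_dose = total_dose,
                      interval_days = interval_days, start_day = start_day,
                      weekends_off = weekends_off,
                      horizon_days = horizon_days),
                 class = "protocol")
  sched <- schedule(p)
  if (nrow(sched) > 0 && horizon_days < max(sched$day))
    stop("horizon_days ends before the last scheduled fraction")
  p
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("Tissue geometry:", x$grid_side, "x", x$grid_side, "px of",
      x$pixel_size_um, "um;",
      "tumour radius", x$tumour_radius_px, "px;",
      sprintf("%.1f%% vessels, %.0f%% normal tissue,", 100 * x$vessel_density,
              100 * x$normal_fraction),
      x$n_layers, "dividing layers\n")
  invisible(x)
}

#' @export
print.protocol <- function(x, ...) {
  n <- round(x$total_dose / x$frac_dose)
  cat(sprintf(
    "Protocol: %g Gy x %d fractions (total %g Gy), every %d day(s)%s, from day %d, horizon day %d\n",
    x$frac_dose, n, x$total_dose, x$interval_days,
    if (x$weekends_off) " excluding weekends" else "", x$start_day,
    x$horizon_days))
  invisible(x)
}
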