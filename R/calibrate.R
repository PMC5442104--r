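# -- Calibration pipelines -------------------------------------------------
# Four fits/sweeps pin the free constants of the model: the single-vessel
# O2 profile (s, sigma), the field amplitude against the tissue-level mean
# O2 condition, the Howard-Flanders HRF curve (m, K), and the sweep-based
# leak factor and growth-layer count.

.profile_columns <- function(data, pixel_size_um) {
  if ("distance_px" %in% names(data)) {
    x <- data$distance_px
  } else if ("distance_um" %in% names(data)) {
    x <- data$distance_um / pixel_size_um
  } else stop("profile data needs a distance_px or distance_um column")
  if ("o2_fraction" %in% names(data)) {
    y <- data$o2_fraction
  } else if ("o2_mmhg" %in% names(data)) {
    y <- data$o2_mmhg / 760   # fraction of sea-level atmospheric pressure
  } else stop("profile data needs an o2_fraction or o2_mmhg column")
  if (any(x < 0)) stop("distances must be non-negative")
  data.frame(x = x, y = y)
}

#' Fit the single-vessel oxygen profile
#'
#' Least-squares fit of `O2(x) = s * exp(-x^2 / (2 sigma^2))` to measured
#' O2 versus distance from a vessel wall. Distances in micrometres are
#' converted to pixels (15 um/px by default); partial pressures in mmHg are
#' converted to fractions of 760 mmHg (21% O2 ambient air reference).
#'
#' @param data Data frame with a distance column (`distance_px` or
#'   `distance_um`) and an O2 column (`o2_fraction` or `o2_mmhg`).
#' @param pixel_size_um Pixel size for the unit conversion.
#' @return List with `s` (wall O2 fraction), `sigma` (pixels),
#'   `ci95_sigma`, and the underlying `nls` fit.
#' @export
fit_o2_profile <- function(data, pixel_size_um = 15) {
  d <- .profile_columns(data, pixel_size_um)
  if (nrow(d) < 3L || diff(range(d$x)) <= 1)
    stop("need at least 3 points spanning more than one pixel")
  fit <- minpack.lm::nlsLM(y ~ s * exp(-x^2 / (2 * sigma^2)), data = d,
                           start = list(s = max(d$y),
                                        sigma = max(diff(range(d$x)) / 3,
                                                    0.5)),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500))
  cf <- stats::coef(fit)
  se_sigma <- summary(fit)$coefficients["sigma", "Std. Error"]
  list(s = unname(cf[["s"]]), sigma = abs(unname(cf[["sigma"]])),
       ci95_sigma = abs(cf[["sigma"]]) +
         c(-1, 1) * stats::qnorm(0.975) * se_sigma,
       fit = fit)
}

#' Calibrate the oxygen amplitude against the mean-oxygen condition
#'
#' The wall amplitude `s` is not directly measurable; it is chosen so that
#' the mean O2 over tumour sites at initialization equals a tissue-level
#' target (3% by default), averaged over seeded vessel placements. Because
#' the pre-cap field is linear in `s`, one convolution per seed suffices
#' and the target is found by bisection (the capped mean is continuous and
#' non-decreasing in `s`).
#'
#' @param geom [geometry_params()].
#' @param ox [oxygen_params()] supplying `sigma` and `cap`.
#' @param target_mean Target mean tumour O2 fraction.
#' @param seeds Integer seeds of the initializations averaged over.
#' @param tol Bisection tolerance on the achieved mean.
#' @return The calibrated amplitude `s`.
#' @export
calibrate_amplitude <- function(geom, ox, target_mean = 0.03,
                                seeds = 1:5, tol = 1e-6) {
  if (target_mean < 0) stop("target_mean must be >= 0")
  if (target_mean >= ox$cap)
    stop("target mean O2 of ", target_mean,
         " is unreachable: at or above the cap of ", ox$cap)
  if (target_mean == 0) return(0)
  u_tum <- lapply(seeds, function(sd) {
    st <- init_tissue(geom, seed = sd)
    u <- .oxygen_field_unit(st, ox$sigma)
    ts <- tumour_site_index(st)
    if (length(ts) == 0L) stop("no tumour sites at initialization")
    u[ts]
  })
  if (all(vapply(u_tum, function(u) all(u == 0), logical(1))))
    stop("no vessels present: target mean O2 is unreachable")
  f <- function(s)
    mean(vapply(u_tum, function(u) mean(pmin(s * u, ox$cap)), numeric(1)))
  hi <- 0.05
  while (f(hi) < target_mean) hi <- hi * 2
  lo <- 0
  while (hi - lo > tol * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (f(mid) < target_mean) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Select the diffusion sigma against the tissue-level oxygen conditions
#'
#' Sweeps candidate sigmas (re-calibrating the amplitude at each) and
#' evaluates the two tissue-level conditions on fresh initializations:
#' hypoxic fraction below `max_hypoxia` and mean tumour O2 at
#' `target_mean`. Among candidates meeting the hypoxia condition, the one
#' whose achieved mean is closest to the target is returned (ties broken
#' toward the smallest sigma).
#'
#' @param geom [geometry_params()].
#' @param sigma_range Numeric vector of candidate sigmas (pixels).
#' @param cap,hypoxia_threshold Oxygen-field constants, see
#'   [oxygen_params()].
#' @param target_mean Mean-O2 condition (fraction).
#' @param max_hypoxia Hypoxia condition: mean hypoxic fraction must be
#'   strictly below this.
#' @param seeds Seeds of the initializations averaged over (>= 10
#'   recommended).
#' @return List with `sigma` (selected), `s` (its calibrated amplitude)
#'   and `sweep`, a data frame of per-candidate metrics.
#' @export
calibrate_diffusion <- function(geom, sigma_range, cap = 0.05,
                                hypoxia_threshold = 0.002,
                                target_mean = 0.03, max_hypoxia = 0.01,
                                seeds = 1:10) {
  if (length(sigma_range) == 0L) stop("empty sigma_range")
  if (max_hypoxia < 0) stop("impossible constraint: max_hypoxia < 0")
  rows <- lapply(sigma_range, function(sg) {
    ox <- oxygen_params(sigma = sg, s = 1, cap = cap,
                        hypoxia_threshold = hypoxia_threshold)
    s_cal <- calibrate_amplitude(geom, ox, target_mean, seeds = seeds)
    ox$s <- s_cal
    mets <- vapply(seeds, function(sd) {
      st <- init_tissue(geom, seed = sd)
      o2 <- compute_oxygen_map(st, ox)
      c(hyp = hypoxic_fraction(o2, st, hypoxia_threshold),
        mo2 = mean_tumour_oxygen(o2, st))
    }, numeric(2))
    data.frame(sigma = sg, s = s_cal, hypoxic_fraction = mean(mets["hyp", ]),
               mean_o2 = mean(mets["mo2", ]))
  })
  sweep <- do.call(rbind, rows)
  ok <- sweep$hypoxic_fraction < max_hypoxia
  if (!any(ok)) {
    best <- sweep[which.min(sweep$hypoxic_fraction), ]
    stop(sprintf(
      "no sigma in the range satisfies hypoxic fraction < %g; best candidate sigma = %g (hypoxic fraction %.4f)",
      max_hypoxia, best$sigma, best$hypoxic_fraction))
  }
  cand <- sweep[ok, ]
  cand <- cand[order(abs(cand$mean_o2 - target_mean), cand$sigma), ]
  list(sigma = cand$sigma[1], s = cand$s[1], sweep = sweep)
}

#' Fit the Howard-Flanders hypoxia curve
#'
#' Least-squares fit of `HRF(O2) = (m K + O2) / (K + O2)` to measured HRF
#' versus O2 fraction.
#'
#' @param data Data frame with columns `o2_fraction` and `hrf`.
#' @param init_m,init_K Starting values for the optimizer.
#' @return List with `m`, `K` and the `nls` fit.
#' @export
fit_hrf <- function(data, init_m = 2.7, init_K = 0.002) {
  stopifnot(all(c("o2_fraction", "hrf") %in% names(data)))
  if (nrow(data) < 3L)
    stop("need at least 3 points to fit the two-parameter HRF curve")
  fit <- minpack.lm::nlsLM(hrf ~ (m * K + o2_fraction) / (K + o2_fraction),
                           data = data,
                           start = list(m = init_m, K = init_K),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500))
  cf <- stats::coef(fit)
  list(m = unname(cf[["m"]]), K = unname(cf[["K"]]), fit = fit)
}

#' Calibrate the leak factor against a hypoxic-fraction time series
#'
#' Sweeps the leak factor, simulating the reference protocol at each value
#' with the same seed, and returns the value minimizing the squared error
#' between the simulated and target hypoxic-fraction series on the days
#' both cover.
#'
#' @param target_series Data frame with columns `day` and
#'   `hypoxic_fraction`, covering the treatment window.
#' @param lf_range Candidate leak factors (default 1.0 to 2.0 by 0.1).
#' @param geom,ox,radio,prot Model parameters; `radio$leak_factor` is
#'   overridden by each candidate.
#' @param seed Simulation seed (one trajectory per candidate).
#' @param scenario Biology scenario for the sweep simulations.
#' @return List with `leak_factor` (best), and `sweep` (data frame of SSE
#'   per candidate).
#' @export
calibrate_leak_factor <- function(target_series,
                                  lf_range = seq(1, 2, by = 0.1),
                                  geom, ox, radio, prot, seed = 1,
                                  scenario = "dlo_vperf_vdeath") {
  if (length(lf_range) == 0L) stop("empty lf_range")
  stopifnot(all(c("day", "hypoxic_fraction") %in% names(target_series)))
  sse <- vapply(lf_range, function(lf) {
    r <- radio
    r$leak_factor <- lf
    traj <- run_simulation(geom, ox, r, prot, seed = seed,
                           scenario = scenario)
    m <- merge(target_series, traj[, c("day", "hypoxic_fraction")],
               by = "day", suffixes = c("_target", "_sim"))
    m <- m[stats::complete.cases(m), ]
    if (nrow(m) == 0L) stop("target series shares no days with the run")
    sum((m$hypoxic_fraction_target - m$hypoxic_fraction_sim)^2)
  }, numeric(1))
  sweep <- data.frame(leak_factor = lf_range, sse = sse)
  list(leak_factor = lf_range[which.min(sse)], sweep = sweep)
}

#' Calibrate the number of dividing layers against a growth curve
#'
#' Integer parameter sweep: simulates unirradiated growth for each
#' candidate layer count and returns the one minimizing the squared error
#' of the simulated volume trajectory against the target growth curve.
#'
#' @param target_growth Data frame with columns `day` and `volume_mm3`
#'   (>= 5 points).
#' @param n_range Candidate layer counts.
#' @param geom,ox Model parameters; `geom$n_layers` is overridden by each
#'   candidate.
#' @param seed Simulation seed.
#' @return List with `n_layers` (best) and `sweep` (SSE per candidate).
#' @export
calibrate_growth_layers <- function(target_growth, n_range = 1:5,
                                    geom, ox, seed = 1) {
  stopifnot(all(c("day", "volume_mm3") %in% names(target_growth)))
  if (nrow(target_growth) < 5L)
    stop("need at least 5 target growth points")
  horizon <- max(target_growth$day)
  prot <- protocol(frac_dose = 1, total_dose = 0, start_day = 0L,
                   horizon_days = horizon)
  radio <- radiobiology_params()
  sse <- vapply(n_range, function(n) {
    g <- geom
    g$n_layers <- as.integer(n)
    traj <- run_simulation(g, ox, radio, prot, seed = seed)
    m <- merge(target_growth, traj[, c("day", "volume_mm3")], by = "day",
               suffixes = c("_target", "_sim"))
    if (nrow(m) == 0L) stop("target growth shares no days with the run")
    sum((m$volume_mm3_target - m$volume_mm3_sim)^2)
  }, numeric(1))
  sweep <- data.frame(n_layers = n_range, sse = sse)
  list(n_layers = as.integer(n_range[which.min(sse)]), sweep = sweep)
}
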