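#' Howard-Flanders hypoxia reduction factor
#'
#' `HRF(c) = (m K + O2(c)) / (K + O2(c))`: the factor by which the locally
#' effective dose is reduced at low oxygen relative to the fully oxygenated
#' reference. Equals `m` at anoxia and tends to 1 at high O2; monotone
#' decreasing in O2.
#'
#' @param o2_c O2 fraction(s), >= 0 (vectorized).
#' @param p A [radiobiology_params()] object.
#' @return HRF value(s) in `[1, m]`.
#' @export
hrf <- function(o2_c, p) {
  if (any(o2_c < 0)) stop("O2 fraction must be >= 0")
  (p$hrf_m * p$hrf_K + o2_c) / (p$hrf_K + o2_c)
}

#' Linear-quadratic survival at local oxygen
#'
#' Survival of one tumour cell after one fraction:
#' `S = exp(-alpha Deq - beta Deq^2)` with the oxygen-equivalent dose
#' `Deq = fracD / HRF(O2)`. At 21% O2 the HRF is close to 1 and this
#' reduces to the standard LQ model.
#'
#' @param fracD Dose of the fraction, Gy (>= 0).
#' @param o2_c Local O2 fraction(s) (vectorized).
#' @param p A [radiobiology_params()] object.
#' @return Survival probability/probabilities in `(0, 1]`.
#' @export
survival_probability <- function(fracD, o2_c, p) {
  if (any(fracD < 0)) stop("dose must be >= 0")
  deq <- fracD / hrf(o2_c, p)
  exp(-p$alpha * deq - p$beta * deq^2)
}

#' Per-fraction probability that a vessel is hit (becomes leaky)
#'
#' `P = 1 - exp(-alpha_ec D - beta_ec D^2)`, the endothelial LQ kill
#' probability used as a proxy for vessel wall disruption.
#'
#' @param fracD Dose, Gy (>= 0).
#' @param p A [radiobiology_params()] object.
#' @return Probability in `[0, 1)`.
#' @export
vessel_hit_probability <- function(fracD, p) {
  if (any(fracD < 0)) stop("dose must be >= 0")
  1 - exp(-p$alpha_ec * fracD - p$beta_ec * fracD^2)
}

#' Per-fraction vessel death probability
#'
#' Linear in dose: 0 up to the threshold (6 Gy), ramping to 1 at the
#' saturation dose (35 Gy). Damage is not cumulative across fractions.
#'
#' @param fracD Dose, Gy (>= 0, vectorized).
#' @param p A [radiobiology_params()] object.
#' @return Probability in `[0, 1]`.
#' @export
vessel_death_probability <- function(fracD, p) {
  if (any(fracD < 0)) stop("dose must be >= 0")
  pmin(1, pmax(0, (fracD - p$vessel_death_threshold) /
                    (p$vessel_death_max - p$vessel_death_threshold)))
}

#' Growth-arrest duration after a fraction
#'
#' Arrest is proportional to dose; the default slope of 9 h/Gy is anchored
#' at 36 hours of arrest after a single 4 Gy exposure.
#'
#' @param fracD Dose, Gy (>= 0, vectorized).
#' @param p A [radiobiology_params()] object.
#' @return Arrest duration in hours.
#' @export
arrest_duration <- function(fracD, p) {
  if (any(fracD < 0)) stop("dose must be >= 0")
  p$arrest_slope * fracD
}

#' Apply one radiation fraction to the tissue
#'
#' Monte Carlo update, in order: (i) each vessel independently dies with
#' [vessel_death_probability()] (site becomes empty and stops sourcing O2);
#' (ii) each surviving vessel is independently hit with
#' [vessel_hit_probability()]; hit vessels take leak multiplier
#' `leak_factor` (a second hit does not compound it); (iii) each viable
#' tumour cell is condemned to mitotic catastrophe (type 5) with probability
#' `1 - survival_probability(fracD, O2 at its site)`; (iv) the global
#' growth-arrest timer is raised to at least [arrest_duration()]. The oxygen
#' map passed in must reflect the pre-fraction vessel configuration; vessel
#' changes made here affect the map from the next recomputation onwards.
#'
#' The uniform random numbers for vessel death and vessel hits are drawn
#' even when the corresponding mechanism is switched off (probability
#' forced to zero), so runs under different biology switches share aligned
#' RNG streams for a given seed.
#'
#' @param state A `tissue_state`.
#' @param o2 Oxygen matrix matching the grid, or a single scalar O2
#'   fraction (e.g. 0.21 for a fully oxygenated scenario).
#' @param fracD Dose of this fraction, Gy.
#' @param p A [radiobiology_params()] object.
#' @param perfusion Enable radiation-induced vessel leakiness.
#' @param vdeath Enable the vessel-death dose ramp.
#' @return Updated `tissue_state`.
#' @export
apply_fraction <- function(state, o2, fracD, p,
                           perfusion = TRUE, vdeath = TRUE) {
  if (fracD < 0) stop("dose must be >= 0")
  g <- state$grid
  leak <- state$leak
  vessels_changed <- FALSE

  nv <- length(leak)
  if (nv > 0L) {
    p_death <- if (vdeath) vessel_death_probability(fracD, p) else 0
    u_death <- stats::runif(nv)
    dead <- u_death < p_death
    if (any(dead)) {
      g[as.integer(names(leak)[dead])] <- PIXEL_STATES[["EMPTY"]]
      leak <- leak[!dead]
      vessels_changed <- TRUE
    }
    ns <- length(leak)
    if (ns > 0L) {
      u_hit <- stats::runif(ns)
      hit <- u_hit < vessel_hit_probability(fracD, p)
      if (perfusion && any(hit)) {
        newly <- hit & leak < p$leak_factor
        if (any(newly)) {
          leak[newly] <- p$leak_factor
          vessels_changed <- TRUE
        }
      }
    }
  }

  vi <- which(g == 1L | g == 2L)
  if (length(vi) > 0L) {
    o2v <- if (length(o2) == 1L) o2 else o2[vi]
    p_kill <- 1 - survival_probability(fracD, o2v, p)
    u <- stats::runif(length(vi))
    g[vi[u < p_kill]] <- PIXEL_STATES[["LETHAL"]]
  }

  state$grid <- g
  state$leak <- leak
  state$arrest_hours <- max(state$arrest_hours, arrest_duration(fracD, p))
  if (vessels_changed) state$o2 <- NULL
  state
}
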