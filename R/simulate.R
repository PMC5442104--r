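#' Fraction schedule for a protocol
#'
#' Fractions start on `start_day` and are spaced `interval_days` apart;
#' with `weekends_off`, delivery falling on a Saturday or Sunday slides to
#' the next weekday (`start_day` is defined to be a Monday).
#'
#' @param p A [protocol()] object.
#' @return Data frame with columns `fraction`, `day`, `dose`,
#'   `cumulative_dose`.
#' @export
schedule <- function(p) {
  stopifnot(inherits(p, "protocol"))
  n <- round(p$total_dose / p$frac_dose)
  days <- integer(n)
  d <- p$start_day
  is_weekend <- function(d) ((d - p$start_day) %% 7L) %in% c(5L, 6L)
  for (i in seq_len(n)) {
    if (p$weekends_off) while (is_weekend(d)) d <- d + 1L
    days[i] <- d
    d <- d + p$interval_days
  }
  data.frame(fraction = seq_len(n), day = days,
             dose = rep(p$frac_dose, n),
             cumulative_dose = p$frac_dose * seq_len(n))
}

#' Spherical tumour volume from the 2D cell count
#'
#' The simulated disk is read as the equatorial cross-section of a sphere:
#' with per-cell area `s_c`, disk area `s_c N` gives radius
#' `r = sqrt(s_c N / pi)` and volume
#' `V = 4/(3 sqrt(pi)) * s_c^(3/2) * N^(3/2)`, converted to mm^3.
#'
#' @param N Cell count (vectorized, >= 0).
#' @param cell_area_um2 Area of one cell in square micrometres.
#' @return Volume in mm^3.
#' @export
volume_from_count <- function(N, cell_area_um2 = 225) {
  if (any(N < 0)) stop("cell count must be >= 0")
  4 / (3 * sqrt(pi)) * cell_area_um2^1.5 * N^1.5 / 1e9
}

#' Biology switches for a simulation scenario
#'
#' The four nested scenarios used to dissect the role of the vasculature:
#' `"full_oxygenation"` (kill computed at 21% O2 everywhere),
#' `"dlo"` (diffusion-limited oxygenation: kill uses the O2 map),
#' `"dlo_vperf"` (adds radiation-induced vessel leakiness), and
#' `"dlo_vperf_vdeath"` (adds the vessel-death dose ramp; the full model).
#'
#' @param scenario Scenario name.
#' @return List of logical switches `use_o2_map`, `perfusion`, `vdeath`.
#' @export
scenario_switches <- function(scenario = c("dlo_vperf_vdeath",
                                           "full_oxygenation", "dlo",
                                           "dlo_vperf")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    full_oxygenation = list(use_o2_map = FALSE, perfusion = FALSE,
                            vdeath = FALSE),
    dlo = list(use_o2_map = TRUE, perfusion = FALSE, vdeath = FALSE),
    dlo_vperf = list(use_o2_map = TRUE, perfusion = TRUE, vdeath = FALSE),
    dlo_vperf_vdeath = list(use_o2_map = TRUE, perfusion = TRUE,
                            vdeath = TRUE))
}

# O2 fraction of ambient air, the in vitro clonogenic reference
O2_AMBIENT <- 0.21

#' Run one in-silico mouse
#'
#' Daily loop from day 0 (initialization) to the protocol horizon. Each
#' day: if a fraction is scheduled, it is applied first (using the oxygen
#' map of the current vessel configuration); if no growth arrest is pending
#' at that point, one n-layer growth step runs; the arrest timer then loses
#' 24 h as the day elapses; finally the oxygen map is refreshed (only
#' needed when the fraction changed vessels), tumour cells are reclassified
#' by local oxygen, and a trajectory row is recorded. Gating growth on the
#' pre-decrement timer means any same-day fraction blocks that day's
#' division even when its arrest is shorter than 24 h (e.g. 18 h at 2 Gy),
#' so daily dosing halts growth until a treatment-free day occurs. The pre-treatment growth phase (days before
#' `start_day`) is part of the same loop and the same seeded stream.
#'
#' A tumour is controlled when no viable (type 1/2) cells remain; since no
#' mechanism recreates viable cells, this condition is absorbing.
#'
#' @param geom [geometry_params()].
#' @param ox [oxygen_params()].
#' @param radio [radiobiology_params()].
#' @param prot [protocol()].
#' @param seed Integer seed for the whole run.
#' @param scenario Biology scenario, see [scenario_switches()].
#' @param stop_when_controlled If `TRUE`, the loop ends on the first day
#'   with zero viable cells (used by cohorts; control is absorbing so the
#'   remainder of the trajectory carries no information about control).
#' @return Object of class `trajectory`: a data frame with one row per
#'   simulated day (columns: day, state counts, `n_viable`, `volume_mm3`,
#'   `hypoxic_fraction`, `cumulative_dose`, `controlled`), with the
#'   schedule and scenario attached as attributes.
#' @export
run_simulation <- function(geom, ox, radio, prot, seed,
                           scenario = "dlo_vperf_vdeath",
                           stop_when_controlled = FALSE) {
  sw <- scenario_switches(scenario)
  sched <- schedule(prot)
  dose_on_day <- numeric(prot$horizon_days + 1L)
  dose_on_day[sched$day + 1L] <- sched$dose

  set.seed(seed)
  state <- init_tissue(geom)
  state <- .ensure_o2(state, ox)

  rows <- vector("list", prot$horizon_days + 1L)
  cum_dose <- 0
  for (day in 0:prot$horizon_days) {
    if (day > 0L) {
      fd <- dose_on_day[day + 1L]
      if (fd > 0) {
        state <- .ensure_o2(state, ox)
        o2_for_kill <- if (sw$use_o2_map) state$o2 else O2_AMBIENT
        state <- apply_fraction(state, o2_for_kill, fd, radio,
                                perfusion = sw$perfusion,
                                vdeath = sw$vdeath)
        cum_dose <- cum_dose + fd
      }
      if (state$arrest_hours == 0) state <- grow_step(state, geom)
      state$arrest_hours <- max(0, state$arrest_hours - 24)
      state$day <- day
    }
    state <- .ensure_o2(state, ox)
    state <- reclassify_oxygen_types(state, state$o2, ox$hypoxia_threshold)
    cs <- count_states(state)
    n_tum <- cs[["TUMOUR_NORMOXIC"]] + cs[["TUMOUR_HYPOXIC"]] +
      cs[["LETHAL"]]
    nv <- cs[["TUMOUR_NORMOXIC"]] + cs[["TUMOUR_HYPOXIC"]]
    hf <- if (n_tum > 0) hypoxic_fraction(state$o2, state,
                                          ox$hypoxia_threshold) else NA_real_
    rows[[day + 1L]] <- data.frame(
      day = day,
      n_normoxic = cs[["TUMOUR_NORMOXIC"]],
      n_hypoxic = cs[["TUMOUR_HYPOXIC"]],
      n_lethal = cs[["LETHAL"]],
      n_vessel = cs[["VESSEL"]],
      n_normal = cs[["NORMAL"]],
      n_viable = nv,
      volume_mm3 = volume_from_count(n_tum, geom$cell_area_um2),
      hypoxic_fraction = hf,
      cumulative_dose = cum_dose,
      controlled = nv == 0L)
    if (stop_when_controlled && nv == 0L) break
  }
  traj <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(traj) <- NULL
  attr(traj, "schedule") <- sched
  attr(traj, "scenario") <- scenario
  attr(traj, "seed") <- seed
  class(traj) <- c("trajectory", "data.frame")
  traj
}
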