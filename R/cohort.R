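#' Simulate a Monte Carlo cohort of in-silico mice
#'
#' Runs `n_mice` independent seeded simulations of the full protocol and
#' evaluates, after each fraction, whether the tumour has been controlled
#' (no viable type-1/2 cells). Control is absorbing - no mechanism
#' recreates viable cells - so each mouse's controlled sequence is
#' monotone, the cohort TCP curve is non-decreasing in cumulative dose by
#' construction, and a mouse's simulation ends once it is controlled.
#'
#' @inheritParams run_simulation
#' @param n_mice Number of simulated animals.
#' @param base_seed Mouse `i` uses seed `base_seed + i - 1`.
#' @return Object of class `tcp_curve`: list with `points` (data frame
#'   `fraction`, `day`, `cumulative_dose`, `tcp`), `controlled` (mice x
#'   fractions logical matrix), `n_mice`, `protocol`, `scenario`,
#'   `base_seed`.
#' @export
simulate_cohort <- function(geom, ox, radio, prot, n_mice = 100,
                            base_seed = 1,
                            scenario = "dlo_vperf_vdeath") {
  stopifnot(n_mice >= 1)
  sched <- schedule(prot)
  nf <- nrow(sched)
  if (nf == 0L) stop("protocol delivers no fractions")
  controlled <- matrix(FALSE, n_mice, nf)
  for (i in seq_len(n_mice)) {
    traj <- run_simulation(geom, ox, radio, prot,
                           seed = base_seed + i - 1,
                           scenario = scenario,
                           stop_when_controlled = TRUE)
    ctrl_days <- traj$day[traj$controlled]
    if (length(ctrl_days) > 0L) {
      # absorbing: controlled at every fraction delivered on/after that day
      controlled[i, ] <- sched$day >= min(ctrl_days)
    }
  }
  points <- data.frame(fraction = sched$fraction, day = sched$day,
                       cumulative_dose = sched$cumulative_dose,
                       tcp = colMeans(controlled))
  structure(list(points = points, controlled = controlled,
                 n_mice = n_mice, protocol = prot, scenario = scenario,
                 base_seed = base_seed),
            class = "tcp_curve")
}

#' @export
print.tcp_curve <- function(x, ...) {
  cat(sprintf("TCP curve: %d mice, scenario '%s', %g Gy x %d fractions\n",
              x$n_mice, x$scenario, x$protocol$frac_dose,
              nrow(x$points)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' @export
plot.tcp_curve <- function(x, ...) {
  plot(x$points$cumulative_dose, x$points$tcp, type = "b", pch = 16,
       xlab = "cumulative dose (Gy)", ylab = "TCP", ylim = c(0, 1), ...)
  invisible(x)
}

#' Sigmoid fit of a TCP curve and the TCP50
#'
#' Fits `TCP(Dt) = 1 / (1 + exp(-lambda Dt + delta))` to the controlled
#' fractions by nonlinear least squares. The 50%-control dose is
#' `TCP50 = delta / lambda`; its 95% confidence interval comes from the
#' delta method on the fit's parameter covariance
#' (`grad = (-delta/lambda^2, 1/lambda)`). A bootstrap over mice is
#' available when the raw per-mouse outcomes are supplied.
#'
#' @param points Either a `tcp_curve` from [simulate_cohort()] or a data
#'   frame with columns `cumulative_dose` (or `dose`) and `tcp`.
#' @param ci Confidence-interval method: `"delta"` (default) or
#'   `"bootstrap"` (requires a `tcp_curve`; resamples mice with
#'   replacement and refits).
#' @param n_boot Bootstrap replicates.
#' @return Object of class `tcp_fit`: list with `lambda`, `delta`,
#'   `tcp50`, `se_tcp50`, `ci95` (length-2 vector), `fit` (the `nls`
#'   object) and the input points.
#' @export
fit_tcp <- function(points, ci = c("delta", "bootstrap"), n_boot = 200) {
  ci <- match.arg(ci)
  curve <- NULL
  if (inherits(points, "tcp_curve")) {
    curve <- points
    points <- points$points
  }
  if (!("cumulative_dose" %in% names(points)) && "dose" %in% names(points))
    points$cumulative_dose <- points$dose
  stopifnot(all(c("cumulative_dose", "tcp") %in% names(points)))
  if (nrow(points) < 3L)
    stop("need at least 3 dose points to fit the sigmoid")
  if (length(unique(points$tcp)) == 1L)
    stop("degenerate TCP curve (constant at ", points$tcp[1],
         "): sigmoid fit is undetermined")
  pars <- .fit_tcp_core(points$cumulative_dose, points$tcp)
  lambda <- pars$lambda
  delta <- pars$delta
  tcp50 <- delta / lambda
  if (ci == "delta") {
    V <- stats::vcov(pars$fit)
    grad <- c(-delta / lambda^2, 1 / lambda)
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    ci95 <- tcp50 + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    if (is.null(curve))
      stop("bootstrap CI requires a tcp_curve with per-mouse outcomes")
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(curve$n_mice, replace = TRUE)
      tcp_b <- colMeans(curve$controlled[idx, , drop = FALSE])
      pb <- tryCatch(.fit_tcp_core(points$cumulative_dose, tcp_b),
                     error = function(e) NULL)
      if (is.null(pb)) NA_real_ else pb$delta / pb$lambda
    }, numeric(1))
    boots <- boots[is.finite(boots)]
    se <- stats::sd(boots)
    ci95 <- unname(stats::quantile(boots, c(0.025, 0.975)))
  }
  structure(list(lambda = lambda, delta = delta, tcp50 = tcp50,
                 se_tcp50 = se, ci95 = ci95, fit = pars$fit,
                 points = points),
            class = "tcp_fit")
}

.fit_tcp_core <- function(dose, tcp) {
  # starting values: logit-linear regression on the interior points,
  # falling back to a crude midpoint guess for degenerate interiors
  interior <- tcp > 0 & tcp < 1
  if (sum(interior) >= 2L) {
    lf <- stats::lm(stats::qlogis(tcp[interior]) ~ dose[interior])
    l0 <- max(unname(stats::coef(lf)[2]), 1e-3)
    d0 <- -unname(stats::coef(lf)[1])
  } else {
    d50 <- dose[which.min(abs(tcp - 0.5))]
    l0 <- 4 / max(diff(range(dose)), 1)
    d0 <- l0 * d50
  }
  fit <- minpack.lm::nlsLM(
    tcp ~ 1 / (1 + exp(-lambda * dose + delta)),
    data = data.frame(dose = dose, tcp = tcp),
    start = list(lambda = l0, delta = d0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["lambda"]]) || cf[["lambda"]] <= 0)
    stop("sigmoid fit failed: non-positive slope")
  list(lambda = cf[["lambda"]], delta = cf[["delta"]], fit = fit)
}

#' @export
print.tcp_fit <- function(x, ...) {
  cat(sprintf(
    "TCP sigmoid fit: lambda = %.4f /Gy, delta = %.3f\nTCP50 = %.2f Gy (95%% CI %.2f - %.2f)\n",
    x$lambda, x$delta, x$tcp50, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' TCP50 table across protocols and biology scenarios
#'
#' Runs one cohort per (protocol, scenario) pair and tabulates the fitted
#' TCP50 with its confidence interval, in the style of a
#' protocol-by-biology comparison panel.
#'
#' @inheritParams simulate_cohort
#' @param protocols Named list of [protocol()] objects.
#' @param scenarios Character vector of scenario names
#'   (see [scenario_switches()]).
#' @return Data frame with one row per (protocol, scenario): `protocol`,
#'   `scenario`, `frac_dose`, `tcp50`, `ci_lo`, `ci_hi`, `lambda`,
#'   `delta`, `tcp_max`.
#' @export
compare_scenarios <- function(protocols, scenarios, geom, ox, radio,
                              n_mice = 100, base_seed = 1) {
  if (inherits(protocols, "protocol")) protocols <- list(protocols)
  if (is.null(names(protocols)))
    names(protocols) <- vapply(protocols, function(p)
      sprintf("%gGyx%d", p$frac_dose, round(p$total_dose / p$frac_dose)),
      character(1))
  for (s in scenarios) scenario_switches(s)  # validate names up front
  rows <- list()
  for (pn in names(protocols)) {
    for (s in scenarios) {
      cu <- simulate_cohort(geom, ox, radio, protocols[[pn]],
                            n_mice = n_mice, base_seed = base_seed,
                            scenario = s)
      ft <- tryCatch(fit_tcp(cu), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        protocol = pn, scenario = s,
        frac_dose = protocols[[pn]]$frac_dose,
        tcp50 = if (is.null(ft)) NA_real_ else ft$tcp50,
        ci_lo = if (is.null(ft)) NA_real_ else ft$ci95[1],
        ci_hi = if (is.null(ft)) NA_real_ else ft$ci95[2],
        lambda = if (is.null(ft)) NA_real_ else ft$lambda,
        delta = if (is.null(ft)) NA_real_ else ft$delta,
        tcp_max = max(cu$points$tcp))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
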