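## ODE integration with IV dosing events.

#' Intravenous dosing regimen
#'
#' @param dose Dose in mg (per administration).
#' @param times Start times of each administration (h).
#' @param duration Infusion duration in h (0 = bolus). Recycled over doses.
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen(1000, times = 0, duration = 3 / 60)  # 1 g over 3 min
#' dose_regimen(750, times = c(0, 8))                # two IV boluses
#' @export
dose_regimen <- function(dose, times = 0, duration = 0) {
  if (any(dose <= 0)) abort("`dose` must be positive.")
  if (any(duration < 0)) abort("`duration` must be >= 0.")
  n <- length(times)
  structure(
    list(dose_ug = rep_len(dose * 1000, n), times = times,
         duration = rep_len(duration, n)),
    class = "dose_regimen"
  )
}

# Total amount administered by time t (ug)
.administered <- function(regimen, t) {
  total <- 0
  for (k in seq_along(regimen$times)) {
    t0 <- regimen$times[k]; dur <- regimen$duration[k]
    if (t <= t0) next
    if (dur == 0) total <- total + regimen$dose_ug[k]
    else total <- total + regimen$dose_ug[k] * min(t - t0, dur) / dur
  }
  total
}

# Infusion rate (ug/h) at time t
.infusion_rate <- function(regimen, t) {
  rate <- 0
  for (k in seq_along(regimen$times)) {
    dur <- regimen$duration[k]
    if (dur > 0 && t >= regimen$times[k] && t < regimen$times[k] + dur) {
      rate <- rate + regimen$dose_ug[k] / dur
    }
  }
  rate
}

#' Simulate a compartment graph under a dosing regimen
#'
#' Integrates the full ODE system with a stiff-capable solver (`lsoda`,
#' relative tolerance 1e-8, absolute tolerance 1e-10 ug), restarting at
#' every bolus time and infusion boundary. Tiny negative excursions within
#' solver tolerance are clipped to zero in the reported output.
#'
#' @param graph A [build_model()] result.
#' @param regimen A [dose_regimen()].
#' @param t_end Simulation horizon (h).
#' @param dt Output grid spacing (h).
#' @param rtol,atol Solver tolerances.
#' @return An object of class `pbpk_sim` with elements `profiles` (tibble:
#'   `time`, `compartment`, `amount` ug, `concentration` ug/mL),
#'   `mass_balance` (tibble: `time`, `residual` relative to total dose),
#'   `graph`, `regimen`.
#' @export
simulate_pbpk <- function(graph, regimen, t_end = 24, dt = 0.05,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(graph, "compartment_graph"),
            inherits(regimen, "dose_regimen"))
  nm <- graph$state_names
  y0 <- setNames(numeric(length(nm)), nm)
  central <- graph$plasma_compartment

  rhs <- function(t, y, parms) {
    list(graph$rhs(y, .infusion_rate(regimen, t)))
  }

  times <- sort(unique(c(seq(0, t_end, by = dt), t_end)))
  boluses <- regimen$times[regimen$duration == 0]
  bolus_dose <- regimen$dose_ug[regimen$duration == 0]
  # event table: boluses add to venous plasma; infusion boundaries force a
  # solver restart with a zero-amount event
  ev_t <- c(boluses,
            regimen$times[regimen$duration > 0],
            regimen$times[regimen$duration > 0] +
              regimen$duration[regimen$duration > 0])
  ev_v <- c(bolus_dose, numeric(sum(regimen$duration > 0) * 2))
  keep <- ev_t <= t_end
  events <- data.frame(var = central, time = ev_t[keep], value = ev_v[keep],
                       method = "add")
  events <- events[order(events$time), ]
  times <- sort(unique(c(times, events$time)))

  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol,
                        atol = atol, maxsteps = 50000,
                        events = if (nrow(events)) list(data = events) else NULL)
  if (attr(sol, "istate")[1] < 0) {
    abort(paste0("ODE solver failed (istate ",
                 attr(sol, "istate")[1], "); final state: ",
                 paste(sprintf("%s=%.3g", nm, sol[nrow(sol), -1]),
                       collapse = ", ")))
  }
  sol <- as.data.frame(sol)
  amounts <- as.matrix(sol[, nm, drop = FALSE])
  amounts[amounts < 0 & amounts > -1e-6] <- 0  # clip solver-noise negatives

  total_dose <- sum(regimen$dose_ug)
  given <- vapply(sol$time, function(t) .administered(regimen, t), numeric(1))
  residual <- (rowSums(amounts) - given) / total_dose

  vols <- graph$volumes
  profiles <- tibble::as_tibble(sol[, "time", drop = FALSE]) |>
    dplyr::bind_cols(tibble::as_tibble(amounts)) |>
    tidyr::pivot_longer(-"time", names_to = "compartment",
                        values_to = "amount") |>
    dplyr::mutate(concentration = .data$amount /
                    vols[.data$compartment])

  structure(
    list(profiles = profiles,
         mass_balance = tibble::tibble(time = sol$time, residual = residual),
         graph = graph, regimen = regimen, t_end = t_end),
    class = "pbpk_sim"
  )
}

#' @export
print.pbpk_sim <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<pbpk_sim> %s, %s | Cmax %.2f ug/mL @ %.2f h | AUC %.1f ug*h/mL | urine %.1f%% | |mass balance| <= %.1e\n",
    x$graph$drug$name,
    if (x$graph$params$pregnant)
      sprintf("GA %g wk", x$graph$subject$gestational_age) else "non-pregnant",
    g$cmax, g$tmax, g$auc, g$urinary_pct, g$mass_balance_max))
  invisible(x)
}

# concentration series for one compartment
.conc_series <- function(sim, compartment) {
  pr <- sim$profiles
  pr[pr$compartment == compartment, c("time", "concentration")]
}

#' Maternal plasma concentration series
#'
#' @param sim A `pbpk_sim`.
#' @param compartment Compartment to extract (default venous plasma).
#' @return Tibble `time`, `concentration` (ug/mL).
#' @export
plasma_concentration <- function(sim, compartment = NULL) {
  .conc_series(sim, compartment %||% sim$graph$plasma_compartment)
}

#' Cumulative urinary excretion over a time window
#'
#' Amount accumulated in the maternal urine sink over `window`, as percent
#' of the reference dose. For multi-dose windows the reference is the
#' amount administered within the window (per-interval dose accounting).
#'
#' @param sim A `pbpk_sim`.
#' @param window Numeric length-2 interval (h), default the full horizon.
#' @param reference `"window"` (dose given inside the window) or
#'   `"total"` (all administered drug).
#' @return Percent of the reference dose.
#' @export
urinary_excretion_pct <- function(sim, window = NULL, reference = c("window", "total")) {
  reference <- match.arg(reference)
  ur <- .amount_series(sim, "urine")
  if (nrow(ur) == 0) return(NA_real_)
  if (is.null(window)) window <- c(0, max(ur$time))
  if (window[1] < 0 || window[2] > max(ur$time) + 1e-9) {
    abort("`window` must lie within the simulated horizon.")
  }
  a <- function(t) approx(ur$time, ur$amount, xout = t, rule = 2)$y
  excreted <- a(window[2]) - a(window[1])
  reg <- sim$regimen
  ref_dose <- if (reference == "total") sum(reg$dose_ug) else {
    inside <- reg$times >= window[1] - 1e-9 & reg$times < window[2]
    if (!any(inside)) sum(reg$dose_ug) else sum(reg$dose_ug[inside])
  }
  100 * excreted / ref_dose
}

.amount_series <- function(sim, compartment) {
  pr <- sim$profiles
  pr[pr$compartment == compartment, c("time", "amount")]
}

#' Summary exposure metrics
#'
#' One-row tibble of Cmax, Tmax and AUC (trapezoidal) for maternal venous
#' plasma, cumulative urinary excretion, systemic clearance (dose/AUC) and
#' the worst mass-balance residual.
#'
#' @param x A `pbpk_sim`.
#' @param ... Unused.
#' @export
glance.pbpk_sim <- function(x, ...) {
  cp <- .conc_series(x, x$graph$plasma_compartment)
  auc <- sum(diff(cp$time) * (head(cp$concentration, -1) +
                                tail(cp$concentration, -1)) / 2)
  imax <- which.max(cp$concentration)
  tibble::tibble(
    cmax = cp$concentration[imax],
    tmax = cp$time[imax],
    auc = auc,
    clearance_L_h = sum(x$regimen$dose_ug) / auc / 1000,
    urinary_pct = urinary_excretion_pct(x, reference = "total"),
    mass_balance_max = max(abs(x$mass_balance$residual))
  )
}

#' Long tidy concentration table
#'
#' @param x A `pbpk_sim`.
#' @param ... Unused.
#' @return Tibble `time`, `compartment`, `amount` (ug), `concentration`
#'   (ug/mL; NA for the urine sink).
#' @export
tidy.pbpk_sim <- function(x, ...) x$profiles
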