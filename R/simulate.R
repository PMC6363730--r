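# ODE integration with bolus-dose impulse events, plus the closed-form
# two-compartment solution used as an independent oracle.

# Core solver.  Integrates the compiled RHS piecewise between break times
# (LPS production breakpoints and dose events) so the discontinuities are
# resolved exactly; applies concentration jumps at coptisine events.
# `times` must be sorted and unique.  Returns a matrix length(times) x 10.
# Values reported at an event time are post-jump (right-continuous).
solve_pkpd <- function(params, regimen, times, init = NULL,
                       rtol = 1e-8, atol = 1e-10, clamp = TRUE) {
  nstate <- 10L
  if (is.null(init)) {
    y <- numeric(nstate)
  } else {
    if (length(init) != nstate) abort("init must have length 10")
    y <- as.numeric(init)
    if (any(!is.finite(y)) || any(y < 0)) abort("init must be finite and >= 0")
  }
  t0 <- times[1]
  t_end <- times[length(times)]

  ev_times <- regimen$cop_events$time
  ev_jumps <- cop_bolus_jump(regimen$cop_events$dose_per_kg,
                             regimen$body_weight, params$V1)
  if (any(ev_times < t0 - 1e-12)) abort("dose events precede the time grid")

  brk <- if (regimen$lps) {
    regimen$lps_time + c(0, params$w1, params$w2)
  } else numeric(0)
  bounds <- sort(unique(c(t0, t_end,
                          brk[brk > t0 & brk < t_end],
                          ev_times[ev_times > t0 & ev_times < t_end])))

  # event exactly at t0: apply before integrating
  at0 <- which(abs(ev_times - t0) <= 1e-12)
  for (i in at0) y[1] <- y[1] + ev_jumps[i]

  parms <- parms_vector(params, regimen, clamp = clamp)
  out <- matrix(NA_real_, nrow = length(times), ncol = nstate)
  ti <- 1L
  if (abs(times[1] - t0) <= 1e-12) {
    out[1, ] <- y
    ti <- 2L
  }

  for (s in seq_len(length(bounds) - 1L)) {
    a <- bounds[s]; b <- bounds[s + 1L]
    sel <- which(times > a + 1e-12 & times <= b + 1e-12)
    tt <- sort(unique(c(a, times[sel], b)))
    sol <- tryCatch(
      deSolve::lsoda(y, tt, func = "pkpd_derivs", parms = parms,
                     dllname = "coptipkpd", initfunc = "pkpd_init",
                     rtol = rtol, atol = atol, maxsteps = 20000),
      warning = function(w) {
        abort(sprintf("ODE solver failed on interval [%g, %g]: %s",
                      a, b, conditionMessage(w)))
      }
    )
    if (attr(sol, "istate")[1] < 0) {
      abort(sprintf("ODE solver failed on interval [%g, %g]", a, b))
    }
    y <- sol[nrow(sol), -1]
    if (length(sel)) {
      rows <- match(round(times[sel], 12), round(sol[, 1], 12))
      out[sel, ] <- sol[rows, -1, drop = FALSE]
    }
    # apply any dose at the segment end so values at b are pre-jump only if
    # b is not an event; requested times equal to an event time get the
    # post-jump value
    hit <- which(abs(ev_times - b) <= 1e-12)
    for (i in hit) {
      y[1] <- y[1] + ev_jumps[i]
      at_b <- which(abs(times - b) <= 1e-12)
      if (length(at_b)) out[at_b, 1] <- y[1]
    }
  }

  # floor tiny negative solver excursions (within the accuracy the solver
  # can guarantee, i.e. a small multiple of atol); error on substantive ones
  neg <- out < 0
  if (any(neg, na.rm = TRUE)) {
    worst <- min(out[neg], na.rm = TRUE)
    if (worst < -max(1e-9, 100 * atol)) {
      abort(sprintf("negative state value %g exceeds solver slack", worst))
    }
    out[neg] <- 0
  }
  colnames(out) <- pkpd_states()
  out
}

#' Simulate the PK-PD model
#'
#' Integrates the 10-state system over a time grid with IV bolus events
#' applied as instantaneous jumps of the plasma coptisine concentration
#' (`dose_per_kg * body_weight * 1e6 / V1`).  Integration restarts at the
#' TNF-alpha production breakpoints and at each dose event so the
#' discontinuities are resolved exactly.  Values reported at an event time
#' are post-dose.
#'
#' @param params A [model_parameters()] set.
#' @param regimen A [dose_regimen()].
#' @param times Strictly increasing time grid, h, within `[0, 24]`
#'   (default a 0.02 h grid over 0-24 h including the dose/breakpoint times).
#' @param init Optional initial state (length 10, canonical order); default
#'   all zero at the LPS injection.
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param clamp Clamp the inhibition fraction at 1 (default `TRUE`); set
#'   `FALSE` for the strict linear inhibition model.
#' @return A tibble of class `pkpd_trajectory` with column `time` and one
#'   column per state (see [pkpd_states()]); attributes `params` and
#'   `regimen` carry the inputs.
#' @export
#' @examples
#' traj <- simulate_pkpd(model_parameters(),
#'                       dose_regimen(cop_dose = 7.74, cop_time = 0.5),
#'                       times = seq(0, 12, by = 0.1))
#' traj[traj$time == 0.5, "cop"]  # post-bolus concentration
simulate_pkpd <- function(params, regimen, times = NULL, init = NULL,
                          rtol = 1e-8, atol = 1e-10, clamp = TRUE) {
  validate_parameters(params)
  if (!inherits(regimen, "dose_regimen")) abort("regimen must be a dose_regimen")
  if (is.null(times)) {
    times <- sort(unique(c(seq(0, 24, by = 0.02), regimen$cop_events$time,
                           if (regimen$lps)
                             regimen$lps_time + c(params$w1, params$w2))))
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("times must be strictly increasing")
  }
  if (times[1] < 0 || times[length(times)] > 24) {
    abort("times must lie within [0, 24] h")
  }
  states <- solve_pkpd(params, regimen, times, init = init,
                       rtol = rtol, atol = atol, clamp = clamp)
  traj <- as_tibble(cbind(tibble(time = times), as_tibble(states)))
  class(traj) <- c("pkpd_trajectory", class(traj))
  attr(traj, "params") <- params
  attr(traj, "regimen") <- regimen
  attr(traj, "tol") <- c(rtol = rtol, atol = atol)
  traj
}

#' Closed-form two-compartment IV bolus solution (oracle)
#'
#' The standard biexponential solution of the linear two-compartment model
#' with central elimination: `C(t) = (dose/V1) (A e^(-alpha t) + B e^(-beta t))`
#' with `alpha + beta = k10 + k12 + k21`, `alpha * beta = k10 * k21`,
#' `A = (alpha - k21)/(alpha - beta)`, `B = (k21 - beta)/(alpha - beta)`.
#' Used as an independent oracle against the ODE solution.
#'
#' @param params A [model_parameters()] set (uses `V1`, `k10`, `k12`, `k21`).
#' @param dose_ng Dose in ng delivered to the central compartment.
#' @param t_since_dose Time(s) since the bolus, h (vectorized, >= 0).
#' @return Plasma concentration(s), ng/mL.
#' @export
#' @examples
#' closed_form_2cpt(model_parameters(), dose_ng = 7.74 * 0.2 * 1e6,
#'                  t_since_dose = c(0, 1, 4))
closed_form_2cpt <- function(params, dose_ng, t_since_dose) {
  if (any(t_since_dose < 0)) abort("t_since_dose must be >= 0")
  s <- params$k10 + params$k12 + params$k21
  p <- params$k10 * params$k21
  disc <- s^2 - 4 * p
  if (disc <= 1e-12 * s^2) {
    abort("degenerate case alpha == beta not supported by the biexponential form")
  }
  alpha <- (s + sqrt(disc)) / 2
  beta <- (s - sqrt(disc)) / 2
  A <- (alpha - params$k21) / (alpha - beta)
  B <- (params$k21 - beta) / (alpha - beta)
  (dose_ng / params$V1) * (A * exp(-alpha * t_since_dose) +
                             B * exp(-beta * t_since_dose))
}

#' Extract the measured observables from a trajectory
#'
#' Maps the 10 model states to the six measured observables (identity on
#' plasma/lung coptisine, plasma/lung TNF-alpha, lung iNOS and plasma NO)
#' and returns them in tidy long form.
#'
#' @param traj A `pkpd_trajectory` from [simulate_pkpd()].
#' @param dvid Observable codes to keep (default all six).
#' @return A tibble with columns `time`, `dvid`, `observable`, `value`.
#' @export
#' @examples
#' traj <- simulate_pkpd(model_parameters(), dose_regimen(),
#'                       times = seq(0, 12, by = 0.5))
#' observables(traj, dvid = c(3, 6))
observables <- function(traj, dvid = 1:6) {
  obs <- pkpd_observables()
  bad <- setdiff(dvid, obs$dvid)
  if (length(bad)) {
    abort(paste0("unknown observable code(s): ", paste(bad, collapse = ", ")))
  }
  obs <- obs[match(dvid, obs$dvid), ]
  purrr::map_dfr(seq_len(nrow(obs)), function(i) {
    tibble(time = traj$time, dvid = obs$dvid[i],
           observable = obs$observable[i],
           value = traj[[obs$state[i]]])
  })
}

#' Simulate group-mean observable curves
#'
#' Convenience wrapper: simulates the deterministic (population-mean)
#' trajectory for a regimen and returns the six observable series in tidy
#' form together with the trajectory.
#'
#' @inheritParams simulate_pkpd
#' @param dvid Observable codes (default all six).
#' @return A tibble as from [observables()], with the full trajectory in
#'   attribute `trajectory`.
#' @export
simulate_group_mean <- function(params, regimen, times = NULL, dvid = 1:6,
                                ...) {
  traj <- simulate_pkpd(params, regimen, times = times, ...)
  out <- observables(traj, dvid = dvid)
  attr(out, "trajectory") <- traj
  out
}

# Fast internal path: predicted observable values for one regimen at an
# observation schedule (tibble with columns time, dvid).  One solve per call.
predict_observables <- function(params, regimen, schedule,
                                rtol = 1e-8, atol = 1e-10) {
  tt <- sort(unique(c(0, schedule$time)))
  states <- solve_pkpd(params, regimen, tt, rtol = rtol, atol = atol)
  obs_map <- pkpd_observables()
  state_idx <- match(obs_map$state, pkpd_states())
  row <- match(round(schedule$time, 12), round(tt, 12))
  col <- state_idx[match(schedule$dvid, obs_map$dvid)]
  states[cbind(row, col)]
}

#' Export a trajectory to tidy CSV
#'
#' Writes columns `time`, `name`, `value` (states and the six observables
#' share state names where they coincide).
#'
#' @param traj A `pkpd_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  long <- tidyr::pivot_longer(as_tibble(traj), -"time",
                              names_to = "name", values_to = "value")
  readr::write_csv(long, path)
  invisible(path)
}
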