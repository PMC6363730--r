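# The right-hand-side algebra of the 10-state PK-PD system: two-compartment
# coptisine kinetics with lung distribution, piecewise zero-order TNF-alpha
# production under linear coptisine inhibition, Michaelis-Menten TNF-alpha
# elimination, diffusion-delayed lung TNF-alpha, the iNOS chain, and the
# precursor-pool NO model.

#' Zero-order plasma TNF-alpha production rate
#'
#' The LPS-triggered TNF-alpha burst is modelled as a piecewise-constant
#' zero-order input anchored at the LPS injection time: `k0_phase1` on
#' `[t_lps, t_lps + w1)`, `k0_phase2` on `[t_lps + w1, t_lps + w2)`, and 0
#' elsewhere (including before the LPS injection and for unchallenged
#' regimens).
#'
#' @param t Time(s), h (vectorized).
#' @param regimen A [dose_regimen()].
#' @param params A [model_parameters()] set.
#' @return Production rate(s), pg/(mL h).
#' @export
#' @examples
#' p <- model_parameters()
#' production_rate_tnfa(0.1, dose_regimen(), p)  # phase-1 rate
#' production_rate_tnfa(5, dose_regimen(), p)    # window closed
production_rate_tnfa <- function(t, regimen, params) {
  if (any(t < 0)) abort("t must be >= 0")
  if (!regimen$lps) return(rep(0, length(t)))
  tt <- t - regimen$lps_time
  out <- numeric(length(t))
  out[tt >= 0 & tt < params$w1] <- params$k0_phase1
  out[tt >= params$w1 & tt < params$w2] <- params$k0_phase2
  out
}

#' Fractional inhibition of TNF-alpha production by coptisine
#'
#' The linear inhibition model `f(cop) = InhibitCon * cop`, by default
#' clamped at 1 so the production term `k0 * (1 - f)` cannot go negative
#' (the unclamped linear model exceeds 1 above `1/InhibitCon`, about
#' 1133 ng/mL at the default estimate).  Set `clamp = FALSE` for the strict
#' linear form.
#'
#' @param cop_conc Plasma coptisine concentration(s), ng/mL (vectorized).
#' @param params A [model_parameters()] set.
#' @param clamp Clamp the fraction at 1 (default `TRUE`).
#' @return Inhibition fraction(s) in `[0, 1]` (or unbounded if `clamp = FALSE`).
#' @export
#' @examples
#' inhibition_fraction(619.8, model_parameters())
inhibition_fraction <- function(cop_conc, params, clamp = TRUE) {
  if (any(is.na(cop_conc)) || any(cop_conc < 0)) {
    abort("cop_conc must be non-negative")
  }
  f <- params$InhibitCon * cop_conc
  if (clamp) f <- pmin(f, 1)
  f
}

#' Time derivative of the 10-state PK-PD system
#'
#' Evaluates the model right-hand side at one time point.  Bolus dosing is
#' not part of the RHS: impulse events are applied as state jumps by
#' [simulate_pkpd()].  State order is [pkpd_states()].
#'
#' @param t Time, h.
#' @param state Numeric state vector of length 10 (named or in canonical
#'   order); all entries must be finite and non-negative.
#' @param params A [model_parameters()] set.
#' @param regimen A [dose_regimen()].
#' @param clamp Clamp the inhibition fraction at 1 (default `TRUE`).
#' @return Named numeric vector of the 10 derivatives.
#' @export
#' @examples
#' y <- setNames(numeric(10), pkpd_states())
#' pkpd_rhs(0.1, y, model_parameters(), dose_regimen())
pkpd_rhs <- function(t, state, params, regimen, clamp = TRUE) {
  if (length(state) != 10) abort("state must have length 10")
  if (any(!is.finite(state))) abort("state contains NA/NaN/Inf")
  if (any(state < 0)) abort("state entries must be >= 0")
  y <- setNames(as.numeric(state), pkpd_states())
  p <- params

  k0 <- production_rate_tnfa(t, regimen, p)
  f <- inhibition_fraction(y[["cop"]], p, clamp = clamp)

  d <- c(
    cop       = -p$k10 * y[["cop"]] - p$k12 * y[["cop"]] + p$k21 * y[["cop2"]],
    cop2      = p$k12 * y[["cop"]] - p$k21 * y[["cop2"]],
    cop_lung  = p$k13 * y[["cop"]] - p$k31 * y[["cop_lung"]],
    tnfa      = k0 * (1 - f) - p$Vm * y[["tnfa"]] / (p$km + y[["tnfa"]]),
    tnfa_lung = p$k_TNFapl * y[["tnfa"]] - p$k_outTNFa * y[["tnfa_lung"]],
    inos_mrna = p$k_iNOSmRNA * y[["tnfa_lung"]] - p$k_outiNOSmRNA * y[["inos_mrna"]],
    inos      = p$k_iNOS * y[["inos_mrna"]] - p$k_outiNOS * y[["inos"]],
    inos_p    = p$k_iNOSlp * y[["inos"]] - p$k_outiNOSp * y[["inos_p"]],
    no_pre    = p$k_iNOSNO * y[["inos_p"]]^p$delta - p$k_inNO * y[["no_pre"]],
    no_plasma = p$k_inNO * y[["no_pre"]] - p$k_outNO * y[["no_plasma"]]
  )
  d
}

# Parameter vector in the order expected by the compiled RHS.
parms_vector <- function(params, regimen, clamp = TRUE) {
  t_lps <- if (regimen$lps) regimen$lps_time else Inf
  c(params$k10, params$k12, params$k21, params$k13, params$k31,
    params$k0_phase1, params$k0_phase2, params$w1, params$w2, t_lps,
    params$InhibitCon, as.numeric(clamp),
    params$Vm, params$km,
    params$k_TNFapl, params$k_outTNFa,
    params$k_iNOSmRNA, params$k_outiNOSmRNA,
    params$k_iNOS, params$k_outiNOS,
    params$k_iNOSlp, params$k_outiNOSp,
    params$k_iNOSNO, params$delta, params$k_inNO, params$k_outNO)
}
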