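# Model parameters: the full set of rate constants, volumes and statistical
# parameters of the coptisine/LPS PK-PD model, with the published population
# estimates as packaged defaults.

# Structural (ODE) parameters, in canonical order.  V1 is carried in mL per
# animal; per-kg doses are converted through the regimen body weight.
PKPD_PARAM_NAMES <- c(
  "V1", "k10", "k12", "k21", "k13", "k31",
  "k0_phase1", "k0_phase2", "w1", "w2",
  "InhibitCon", "Vm", "km",
  "k_TNFapl", "k_outTNFa",
  "k_iNOSmRNA", "k_outiNOSmRNA",
  "k_iNOS", "k_outiNOS",
  "k_iNOSlp", "k_outiNOSp",
  "k_iNOSNO", "delta", "k_inNO", "k_outNO"
)

# Population estimates (the published final model).  Units: V1 mL/animal;
# k0 phases pg/(mL h); Vm pg/(mL h); km pg/mL; InhibitCon mL/ng; delta
# dimensionless; all other rate constants 1/h.
.default_estimates <- c(
  V1            = 2.63e3,
  k10           = 4.58e-1,
  k12           = 2.05,
  k21           = 6.68e-1,
  k13           = 1.21e-2,
  k31           = 3.77,
  k0_phase1     = 645.73,
  k0_phase2     = 5881.32,
  w1            = 0.333,
  w2            = 0.667,
  InhibitCon    = 8.83e-4,
  Vm            = 5.99e3,
  km            = 5.18e3,
  k_TNFapl      = 3.54e-7,
  k_outTNFa     = 2.34e-1,
  k_iNOSmRNA    = 3.38e-3,
  k_outiNOSmRNA = 2.36,
  k_iNOS        = 2.99e-1,
  k_outiNOS     = 3.72,
  k_iNOSlp      = 23.41,
  k_outiNOSp    = 1.92,
  k_iNOSNO      = 772.17,
  delta         = 1.23,
  k_inNO        = 354.68,
  k_outNO       = 3.46
)

#' Observable codes of the six measured quantities
#'
#' The measured quantities of the rat studies, keyed by the numeric
#' observable code (`dvid`) used in observation tables:
#' 1 plasma coptisine (ng/mL), 2 lung coptisine (ng/mL-equivalent),
#' 3 plasma TNF-alpha (pg/mL), 4 lung TNF-alpha (pg/mL),
#' 5 lung iNOS (relative ratio), 6 plasma NO, i.e. nitrite + nitrate
#' (umol/L).
#'
#' @return A tibble with columns `dvid`, `observable`, `state`, `unit`.
#' @export
#' @examples
#' pkpd_observables()
pkpd_observables <- function() {
  tibble(
    dvid = 1:6,
    observable = c("cop_plasma", "cop_lung", "tnfa_plasma",
                   "tnfa_lung", "inos_lung", "no_plasma"),
    state = c("cop", "cop_lung", "tnfa", "tnfa_lung", "inos", "no_plasma"),
    unit = c("ng/mL", "ng/mL", "pg/mL", "pg/mL", "relative ratio", "umol/L")
  )
}

#' Canonical state names of the 10-state PK-PD system
#'
#' Fixed ordering used by [simulate_pkpd()], [pkpd_rhs()] and the compiled
#' right-hand side: plasma/peripheral/lung coptisine, plasma and lung
#' TNF-alpha, the iNOS mRNA/protein/plasma chain, and the NO precursor pool
#' and plasma NO.
#'
#' @return Character vector of length 10.
#' @export
pkpd_states <- function() {
  c("cop", "cop2", "cop_lung", "tnfa", "tnfa_lung",
    "inos_mrna", "inos", "inos_p", "no_pre", "no_plasma")
}

# Default additive residual SDs per observable (dvid 1..6), each in the
# observable's units.  The published analysis states an additive normal
# residual model but not its magnitudes; these defaults are scaled to roughly
# 4-5% of each observable's peak under the default parameters and the high
# coptisine dose (see the methods vignette).
.default_sigma_add <- c(
  cop_plasma  = 25,
  cop_lung    = 0.08,
  tnfa_plasma = 80,
  tnfa_lung   = 2.5e-5,
  inos_lung   = 2.5e-9,
  no_plasma   = 2.5e-7
)

# Default log-normal between-animal variability SDs.  The published analysis
# assumes log-normal BAV but prints no omega values; 0.2 (about 20% CV) on
# the PK parameters and the TNF-alpha production phases is a documented
# stand-in, 0 elsewhere.
.default_omega_value <- 0.2
.default_omega_names <- c("V1", "k10", "k12", "k21", "k13", "k31",
                          "k0_phase1", "k0_phase2")

#' Construct a PK-PD parameter set
#'
#' Returns the full parameter set of the coptisine/LPS model: the structural
#' rate constants and volumes, per-observable additive residual SDs
#' (`sigma_add`), and per-parameter log-normal between-animal variability SDs
#' (`omega`).  Called with no arguments it returns the packaged default
#' (the published population estimates); any field can be overridden by name.
#'
#' Units: `V1` mL per animal (per-kg doses are converted through the regimen
#' body weight); `k0_phase1`/`k0_phase2` and `Vm` pg/(mL h); `km` pg/mL;
#' `InhibitCon` mL/ng; `w1`, `w2` h; `delta` dimensionless; remaining rate
#' constants 1/h.
#'
#' @param ... Named structural parameter overrides (see
#'   `pkpd_parameter_names()` for valid names).
#' @param sigma_add Named numeric vector of additive residual SDs for the six
#'   observables (names as in `pkpd_observables()$observable`); partial
#'   overrides are merged into the defaults.
#' @param omega Named numeric vector of log-normal between-animal variability
#'   SDs (dimensionless), named by structural parameter; partial overrides
#'   are merged (parameters not named have omega 0).
#'
#' @return An object of class `pkpd_params`: a named list with one element
#'   per structural parameter plus `sigma_add` and `omega`.
#' @export
#' @examples
#' p <- model_parameters()
#' p$Vm
#' model_parameters(InhibitCon = 0)$InhibitCon
model_parameters <- function(..., sigma_add = NULL, omega = NULL) {
  est <- as.list(.default_estimates)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      abort("structural parameter overrides must be named")
    }
    bad <- setdiff(names(dots), PKPD_PARAM_NAMES)
    if (length(bad)) {
      abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    }
    est <- modifyList(est, dots)
  }

  sig <- .default_sigma_add
  if (!is.null(sigma_add)) {
    bad <- setdiff(names(sigma_add), names(sig))
    if (length(bad)) {
      abort(paste0("unknown sigma_add observable(s): ",
                   paste(bad, collapse = ", ")))
    }
    sig[names(sigma_add)] <- sigma_add
  }

  om <- setNames(numeric(length(PKPD_PARAM_NAMES)), PKPD_PARAM_NAMES)
  om[.default_omega_names] <- .default_omega_value
  if (!is.null(omega)) {
    bad <- setdiff(names(omega), PKPD_PARAM_NAMES)
    if (length(bad)) {
      abort(paste0("unknown omega parameter(s): ", paste(bad, collapse = ", ")))
    }
    om[PKPD_PARAM_NAMES] <- 0
    om[.default_omega_names] <- .default_omega_value
    om[names(omega)] <- omega
  }

  params <- c(est[PKPD_PARAM_NAMES], list(sigma_add = sig, omega = om))
  class(params) <- "pkpd_params"
  validate_parameters(params)
  params
}

#' @rdname model_parameters
#' @export
default_parameters <- function() model_parameters()

#' Valid structural parameter names
#' @return Character vector in canonical order.
#' @export
pkpd_parameter_names <- function() PKPD_PARAM_NAMES

#' Validate a PK-PD parameter set
#'
#' Checks positivity of all rate constants, volumes and Michaelis-Menten
#' constants, ordering of the production-phase breakpoints (0 < w1 < w2),
#' non-negativity of `InhibitCon`, `sigma_add` and `omega`, and `delta > 0`.
#'
#' @param params A `pkpd_params` object.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "pkpd_params")) abort("not a pkpd_params object")
  missing <- setdiff(c(PKPD_PARAM_NAMES, "sigma_add", "omega"), names(params))
  if (length(missing)) {
    abort(paste0("missing parameter field(s): ", paste(missing, collapse = ", ")))
  }
  est <- unlist(params[PKPD_PARAM_NAMES])
  if (any(!is.finite(est))) abort("all parameters must be finite")
  strict_pos <- setdiff(PKPD_PARAM_NAMES, "InhibitCon")
  if (any(unlist(params[strict_pos]) <= 0)) {
    bad <- strict_pos[unlist(params[strict_pos]) <= 0]
    abort(paste0("parameter(s) must be strictly positive: ",
                 paste(bad, collapse = ", ")))
  }
  if (params$InhibitCon < 0) abort("InhibitCon must be >= 0")
  if (!(params$w1 > 0 && params$w2 > params$w1)) {
    abort("production-phase breakpoints must satisfy 0 < w1 < w2")
  }
  if (length(params$sigma_add) != 6 || any(params$sigma_add < 0)) {
    abort("sigma_add must be 6 non-negative values")
  }
  if (any(params$omega < 0)) abort("omega values must be >= 0")
  invisible(params)
}

#' @export
print.pkpd_params <- function(x, ...) {
  cat("<pkpd_params> coptisine/LPS PK-PD model parameters\n")
  est <- unlist(x[PKPD_PARAM_NAMES])
  print(tibble(parameter = names(est), estimate = unname(est),
               omega = unname(x$omega[names(est)])), n = length(est))
  cat("sigma_add:", paste(names(x$sigma_add),
                          signif(x$sigma_add, 3), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Tidy a parameter set into a tibble
#'
#' @param x A `pkpd_params` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `omega`.
#' @export
tidy.pkpd_params <- function(x, ...) {
  est <- unlist(x[PKPD_PARAM_NAMES])
  tibble(term = names(est), estimate = unname(est),
         omega = unname(x$omega[names(est)]))
}

#' Read and write parameter configuration files
#'
#' Parameter sets are serialized as flat key-value YAML: one key per
#' structural parameter, plus `sigma_add.<observable>` and
#' `omega.<parameter>` entries.  The packaged default configuration is
#' shipped as `extdata/params_table1.yaml`.
#'
#' @param path File path.
#' @return `read_parameters()` returns a `pkpd_params` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
#' @examples
#' path <- system.file("extdata", "params_table1.yaml", package = "coptipkpd")
#' p <- read_parameters(path)
#' p$k10
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  flat <- unlist(raw)
  est <- flat[names(flat) %in% PKPD_PARAM_NAMES]
  sig_keys <- grep("^sigma_add\\.", names(flat), value = TRUE)
  om_keys <- grep("^omega\\.", names(flat), value = TRUE)
  sigma_add <- setNames(unname(flat[sig_keys]),
                        sub("^sigma_add\\.", "", sig_keys))
  omega <- setNames(unname(flat[om_keys]), sub("^omega\\.", "", om_keys))
  do.call(model_parameters,
          c(as.list(est),
            list(sigma_add = if (length(sigma_add)) sigma_add else NULL,
                 omega = if (length(omega)) omega else NULL)))
}

#' @rdname read_parameters
#' @param params A `pkpd_params` object.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  flat <- c(params[PKPD_PARAM_NAMES],
            list(sigma_add = as.list(params$sigma_add),
                 omega = as.list(params$omega[params$omega > 0])))
  yaml::write_yaml(flat, path)
  invisible(path)
}
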