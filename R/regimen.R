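# Dosing regimens: an LPS trigger plus timed coptisine IV boluses with
# body-weight scaling.

#' Construct a dosing regimen
#'
#' A regimen is an LPS challenge (which acts on the model only through the
#' piecewise zero-order TNF-alpha production schedule anchored at `lps_time`)
#' plus zero or more coptisine IV bolus events.  Doses are per kg body weight
#' and are converted to plasma concentration jumps at simulation time as
#' `dose_per_kg * body_weight * 1e6 / V1` (mg/kg -> ng into a V1 mL central
#' compartment).
#'
#' @param cop_dose Numeric vector of coptisine doses, mg/kg (may be empty).
#' @param cop_time Times of the coptisine boluses, h; strictly increasing,
#'   same length as `cop_dose`. The studies dose at 0.5 h.
#' @param body_weight Body weight, kg (default 0.20; rats of 200 +/- 20 g).
#' @param lps_time Time of the LPS injection, h (default 0).
#' @param lps_dose LPS dose, ug/kg (default 100). Informational: set
#'   `lps = FALSE` for unchallenged control animals.
#' @param lps Logical; if `FALSE` the TNF-alpha production schedule is off
#'   (control group without LPS challenge).
#'
#' @return An object of class `dose_regimen`.
#' @export
#' @examples
#' dose_regimen(cop_dose = 7.74, cop_time = 0.5)
#' dose_regimen()           # LPS challenge only
#' dose_regimen(lps = FALSE) # untreated control
dose_regimen <- function(cop_dose = numeric(0), cop_time = numeric(0),
                         body_weight = 0.20, lps_time = 0, lps_dose = 100,
                         lps = TRUE) {
  if (length(cop_dose) != length(cop_time)) {
    abort("cop_dose and cop_time must have the same length")
  }
  if (length(cop_time) && (any(cop_time < 0) || is.unsorted(cop_time, strictly = TRUE))) {
    abort("cop_time values must be >= 0 and strictly increasing")
  }
  if (any(cop_dose < 0)) abort("coptisine doses must be >= 0")
  if (!is.numeric(body_weight) || length(body_weight) != 1 || body_weight <= 0) {
    abort("body_weight must be a single positive number (kg)")
  }
  if (lps_time < 0) abort("lps_time must be >= 0")
  if (lps_dose < 0) abort("lps_dose must be >= 0")
  structure(
    list(
      lps = isTRUE(lps),
      lps_time = lps_time,
      lps_dose_per_kg = lps_dose,
      cop_events = tibble(time = as.numeric(cop_time),
                          dose_per_kg = as.numeric(cop_dose)),
      body_weight = body_weight
    ),
    class = "dose_regimen"
  )
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat("<dose_regimen>",
      if (x$lps) sprintf("LPS %g ug/kg at %g h;", x$lps_dose_per_kg, x$lps_time)
      else "no LPS;",
      if (nrow(x$cop_events)) {
        paste0("coptisine ",
               paste(sprintf("%g mg/kg @ %g h", x$cop_events$dose_per_kg,
                             x$cop_events$time), collapse = ", "))
      } else "no coptisine",
      sprintf("(BW %g kg)\n", x$body_weight))
  invisible(x)
}

# Concentration jump (ng/mL) in the central compartment for one bolus.
cop_bolus_jump <- function(dose_per_kg, body_weight, V1) {
  dose_per_kg * body_weight * 1e6 / V1
}
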