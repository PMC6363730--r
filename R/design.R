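# The four rat study designs: group sizes, dosing, sampling schedules and
# sampling mode (serial tail-vein vs destructive terminal sampling).

#' Packaged rat study designs
#'
#' Returns one of the four study designs used for the coptisine/LPS
#' experiments:
#' * Study 1: PK; 3 groups of 3 (LPS-only, 7.74, 3.87 mg/kg), serial
#'   tail-vein sampling at 0.667-24 h, plasma coptisine only.
#' * Study 2: PD; 4 groups of 3 (LPS-only, 7.74, 3.87, 1.94 mg/kg), serial
#'   sampling at 0-24 h, plasma TNF-alpha and NO.
#' * Study 3: PK-PD; untreated control (n = 2, sampled at 0 h) plus 3 LPS
#'   groups of 24 (LPS-only, 7.74, 3.87 mg/kg), destructive sampling at
#'   0.667-12 h with n = 2 per group per time point, all six observables
#'   (74 animals in total).
#' * Study 4: PK-PD; untreated control (n = 3, 0 h) plus 3 LPS groups of 18,
#'   destructive sampling at 2-9 h with n = 3 per group per time point, all
#'   six observables (57 animals).
#'
#' @param study Study id, 1-4.
#' @param variant For Study 1 only: `"table"` (default; first sample at
#'   0.667 h) or `"text"` (first sample at 0.5 h) - the two sampling
#'   schedules reported for that study.
#' @return An object of class `pkpd_design`: a list with elements `study`,
#'   `groups` (tibble: `group`, `n`, `lps`, `lps_dose`, `cop_dose`,
#'   `cop_time`, `control`), `times`, `dvid`, `mode`
#'   (`"serial"`/`"destructive"`) and `n_per_time`.
#' @export
#' @examples
#' study_design(3)
study_design <- function(study, variant = c("table", "text")) {
  variant <- match.arg(variant)
  if (!study %in% 1:4) abort("study must be 1, 2, 3 or 4")
  des <- switch(as.character(study),
    "1" = list(
      study = 1L,
      groups = tibble(group = c("1A", "1B", "1C"), n = c(3L, 3L, 3L),
                      lps = TRUE, lps_dose = 100,
                      cop_dose = c(0, 7.74, 3.87), cop_time = 0.5,
                      control = FALSE),
      times = if (variant == "table") c(0.667, 1, 2, 4, 6, 8, 12, 24)
              else c(0.5, 1, 2, 4, 6, 8, 12, 24),
      dvid = 1L, mode = "serial", n_per_time = NA_integer_
    ),
    "2" = list(
      study = 2L,
      groups = tibble(group = c("2A", "2B", "2C", "2D"), n = 3L,
                      lps = TRUE, lps_dose = 100,
                      cop_dose = c(0, 7.74, 3.87, 1.94), cop_time = 0.5,
                      control = FALSE),
      times = c(0, 0.333, 0.667, 1, 2, 4, 6, 8, 12, 24),
      dvid = c(3L, 6L), mode = "serial", n_per_time = NA_integer_
    ),
    "3" = list(
      study = 3L,
      groups = tibble(group = c("3A", "3B", "3C", "3D"),
                      n = c(2L, 24L, 24L, 24L),
                      lps = c(FALSE, TRUE, TRUE, TRUE),
                      lps_dose = c(0, 100, 100, 100),
                      cop_dose = c(0, 0, 7.74, 3.87), cop_time = 0.5,
                      control = c(TRUE, FALSE, FALSE, FALSE)),
      times = c(0.667, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12),
      dvid = 1:6, mode = "destructive", n_per_time = 2L
    ),
    "4" = list(
      study = 4L,
      groups = tibble(group = c("4A", "4B", "4C", "4D"),
                      n = c(3L, 18L, 18L, 18L),
                      lps = c(FALSE, TRUE, TRUE, TRUE),
                      lps_dose = c(0, 100, 100, 100),
                      cop_dose = c(0, 0, 7.74, 3.87), cop_time = 0.5,
                      control = c(TRUE, FALSE, FALSE, FALSE)),
      times = c(2, 4, 6, 7, 8, 9),
      dvid = 1:6, mode = "destructive", n_per_time = 3L
    )
  )
  class(des) <- "pkpd_design"
  validate_design(des)
  des
}

#' Construct a custom study design
#'
#' Build a design other than the four packaged ones, e.g. for prospective
#' power exploration or fast test fixtures.
#'
#' @param groups Tibble with columns `group`, `n`, `lps` (logical),
#'   `lps_dose` (ug/kg), `cop_dose` (mg/kg, 0 for none), `cop_time` (h),
#'   `control` (logical; control groups are sampled at 0 h only).
#' @param times Scheduled sampling times, h.
#' @param dvid Observable codes measured (subset of 1-6).
#' @param mode `"serial"` or `"destructive"`.
#' @param n_per_time Animals per group per time point (destructive only).
#' @param study Numeric id tag (default 0 for custom).
#' @return A validated `pkpd_design`.
#' @export
pkpd_design <- function(groups, times, dvid, mode = c("serial", "destructive"),
                        n_per_time = NA_integer_, study = 0L) {
  mode <- match.arg(mode)
  des <- structure(list(study = as.integer(study), groups = as_tibble(groups),
                        times = as.numeric(times), dvid = as.integer(dvid),
                        mode = mode, n_per_time = as.integer(n_per_time)),
                   class = "pkpd_design")
  validate_design(des)
  des
}

#' Validate a study design
#'
#' Checks group sizes, time points within `[0, 24]` h, presence of
#' `n_per_time` for destructive designs, consistency of destructive group
#' sizes with `n_per_time * length(times)`, and that serial (tail-vein)
#' designs request no terminal lung observables.
#'
#' @param design A `pkpd_design`.
#' @return `design`, invisibly.
#' @export
validate_design <- function(design) {
  if (!inherits(design, "pkpd_design")) abort("not a pkpd_design object")
  g <- design$groups
  if (any(g$n <= 0)) abort("group sizes must be positive")
  if (any(design$times < 0 | design$times > 24)) {
    abort("sampling times must lie within [0, 24] h")
  }
  if (anyDuplicated(g$group)) abort("group labels must be unique")
  if (design$mode == "destructive") {
    if (is.na(design$n_per_time)) {
      abort("destructive designs must carry n_per_time")
    }
    full <- !g$control
    if (any(g$n[full] != design$n_per_time * length(design$times))) {
      abort("destructive group sizes must equal n_per_time * n_times")
    }
  } else if (any(design$dvid %in% c(2L, 4L, 5L))) {
    abort("serial tail-vein designs cannot measure terminal lung observables")
  }
  invisible(design)
}

#' @export
print.pkpd_design <- function(x, ...) {
  cat(sprintf("<pkpd_design> Study %d (%s sampling, %d animals)\n",
              x$study, x$mode, sum(x$groups$n)))
  print(x$groups)
  cat("times (h):", paste(x$times, collapse = ", "), "\n")
  cat("observables (dvid):", paste(x$dvid, collapse = ", "), "\n")
  invisible(x)
}

# Regimen for one design group at a given body weight.
group_regimen <- function(grow, body_weight = 0.20) {
  if (grow$cop_dose > 0) {
    dose_regimen(cop_dose = grow$cop_dose, cop_time = grow$cop_time,
                 body_weight = body_weight, lps = grow$lps,
                 lps_dose = grow$lps_dose)
  } else {
    dose_regimen(body_weight = body_weight, lps = grow$lps,
                 lps_dose = grow$lps_dose)
  }
}

# Deterministic observation skeleton for a design: one row per observation
# (animal x time x observable), animals numbered within study.
build_schedule <- function(design) {
  g <- design$groups
  rows <- list()
  next_id <- 1L
  for (i in seq_len(nrow(g))) {
    times <- if (g$control[i]) 0 else design$times
    if (design$mode == "serial" || g$control[i]) {
      for (a in seq_len(g$n[i])) {
        id <- sprintf("%s-%02d", g$group[i], a)
        rows[[length(rows) + 1L]] <-
          tidyr::expand_grid(animal_id = id, group = g$group[i],
                             time = times, dvid = design$dvid)
      }
    } else {
      a <- 0L
      for (tt in times) {
        for (k in seq_len(design$n_per_time)) {
          a <- a + 1L
          id <- sprintf("%s-%02d", g$group[i], a)
          rows[[length(rows) + 1L]] <-
            tidyr::expand_grid(animal_id = id, group = g$group[i],
                               time = tt, dvid = design$dvid)
        }
      }
    }
    next_id <- next_id + g$n[i]
  }
  dplyr::bind_rows(rows)
}
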