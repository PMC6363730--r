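# Synthetic study generation: log-normal between-animal variability,
# additive Gaussian residual error, and the event-record CSV dialect.

#' Draw individual parameters under log-normal between-animal variability
#'
#' Each randomized parameter is `theta_i = theta_pop * exp(eta_i)` with
#' `eta_i ~ Normal(0, omega_i^2)`; parameters with `omega_i = 0` are returned
#' unchanged.
#'
#' @param population A [model_parameters()] set (the population values).
#' @param omega Named vector of log-normal SDs (default
#'   `population$omega`).
#' @param seed Optional integer seed; when given, draws are reproducible and
#'   the caller's RNG state is untouched.
#' @return A `pkpd_params` object with the randomized values.
#' @export
#' @examples
#' ind <- sample_individual_params(model_parameters(), seed = 7)
#' ind$k10 / model_parameters()$k10
sample_individual_params <- function(population, omega = population$omega,
                                     seed = NULL) {
  validate_parameters(population)
  om <- setNames(numeric(length(PKPD_PARAM_NAMES)), PKPD_PARAM_NAMES)
  om[names(omega)] <- omega
  if (any(om < 0)) abort("omega values must be >= 0")
  draw <- function() {
    eta <- rnorm(length(om), 0, om)
    out <- population
    out[PKPD_PARAM_NAMES] <- as.list(unlist(population[PKPD_PARAM_NAMES]) *
                                       exp(eta))
    out
  }
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}

#' Generate a synthetic rat study
#'
#' Simulates one virtual study under a packaged (or custom) design: each
#' animal receives individual parameters (log-normal between-animal
#' variability), a body weight drawn Uniform(0.18, 0.22) kg, the group's
#' dosing regimen, and additive Gaussian residual noise per observable.
#' Negative noise draws are truncated at 0 and flagged in the `truncated`
#' column.
#'
#' In serial designs every animal is observed at all scheduled times; in
#' destructive designs each (non-control) animal contributes all observables
#' at exactly one terminal time point.
#'
#' @param design A [study_design()].
#' @param params Population parameters (default [model_parameters()]).
#' @param seed Integer seed (required for reproducibility).
#' @param omega Named log-normal BAV SDs (default `params$omega`); set to
#'   `numeric(0)` or all-zero for no between-animal variability.
#' @param sigma Named additive residual SDs per observable (default
#'   `params$sigma_add`); all-zero gives noise-free data.
#' @return A tibble with columns `animal_id`, `group`, `time`, `dvid`,
#'   `observable`, `value`, `body_weight`, `truncated`.  Attributes:
#'   `design`, `regimens` (nominal per-group regimens at 0.20 kg, for pooled
#'   fitting), `truth` (per-animal parameter draws and body weights, for
#'   recovery tests), `params`, `omega`, `sigma`, `seed`.
#' @export
#' @examples
#' dat <- generate_study(study_design(2), seed = 1)
#' dplyr::count(dat, group, dvid)
generate_study <- function(design, params = model_parameters(), seed,
                           omega = params$omega, sigma = params$sigma_add) {
  validate_design(design)
  validate_parameters(params)
  if (missing(seed)) abort("seed is required")
  obs_map <- pkpd_observables()
  if (!all(design$dvid %in% obs_map$dvid)) {
    abort("design requests unknown observable codes")
  }
  sig <- setNames(numeric(6), obs_map$observable)
  sig[names(sigma)] <- sigma
  if (any(sig < 0)) abort("sigma values must be >= 0")

  schedule <- build_schedule(design)
  animals <- dplyr::distinct(schedule, .data$animal_id, .data$group)

  withr::local_seed(seed)
  animals$body_weight <- runif(nrow(animals), 0.18, 0.22)

  truth <- vector("list", nrow(animals))
  pred <- numeric(nrow(schedule))
  for (i in seq_len(nrow(animals))) {
    ind <- sample_individual_params(params, omega = omega)
    truth[[i]] <- tibble(animal_id = animals$animal_id[i],
                         body_weight = animals$body_weight[i],
                         !!!ind[PKPD_PARAM_NAMES])
    grow <- design$groups[design$groups$group == animals$group[i], ]
    reg <- group_regimen(grow, body_weight = animals$body_weight[i])
    rows <- which(schedule$animal_id == animals$animal_id[i])
    pred[rows] <- predict_observables(ind, reg, schedule[rows, ])
  }

  noise <- rnorm(nrow(schedule), 0, sig[schedule$dvid])
  value <- pred + noise
  truncated <- value < 0
  value[truncated] <- 0

  out <- schedule
  out$observable <- obs_map$observable[match(out$dvid, obs_map$dvid)]
  out$value <- value
  out$body_weight <- animals$body_weight[match(out$animal_id,
                                               animals$animal_id)]
  out$truncated <- truncated
  out <- out[, c("animal_id", "group", "time", "dvid", "observable",
                 "value", "body_weight", "truncated")]

  regimens <- setNames(
    lapply(seq_len(nrow(design$groups)),
           function(i) group_regimen(design$groups[i, ], body_weight = 0.20)),
    design$groups$group
  )
  attr(out, "design") <- design
  attr(out, "regimens") <- regimens
  attr(out, "truth") <- dplyr::bind_rows(truth)
  attr(out, "params") <- params
  attr(out, "omega") <- omega
  attr(out, "sigma") <- sig
  attr(out, "seed") <- seed
  class(out) <- c("pkpd_observations", class(out))
  out
}

# ---- event-record CSV dialect -----------------------------------------
# Header: ID,GROUP,TIME,DVID,DV,AMT,CMT,BW
# Observation rows carry DVID (1..6) and DV; dose rows carry AMT with empty
# DV and CMT 1 (coptisine IV bolus, AMT in mg/kg) or 4 (the LPS challenge,
# AMT in ug/kg).

#' Write an observation table in the event-record CSV dialect
#'
#' Writes one row per observation (`DVID`, `DV` set; `AMT`, `CMT` empty) and,
#' when the table carries regimens (as tables from [generate_study()] do),
#' one dose row per animal and dose event (`AMT`, `CMT` set: CMT 1 =
#' coptisine bolus in mg/kg, CMT 4 = LPS challenge in ug/kg).  Rows are
#' sorted by animal, time, with dose rows before observations at the same
#' time.
#'
#' @param table An observation tibble (columns `animal_id`, `group`, `time`,
#'   `dvid`, `value`, `body_weight`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(table, path) {
  need <- c("animal_id", "group", "time", "dvid", "value", "body_weight")
  if (!all(need %in% names(table))) {
    abort(paste0("table must have columns: ", paste(need, collapse = ", ")))
  }
  obs <- tibble(
    ID = table$animal_id, GROUP = table$group, TIME = table$time,
    DVID = as.integer(table$dvid), DV = table$value,
    AMT = NA_real_, CMT = NA_integer_, BW = table$body_weight,
    .ord = 1L
  )
  doses <- NULL
  regimens <- attr(table, "regimens")
  if (!is.null(regimens) && nrow(table)) {
    an <- dplyr::distinct(tibble(ID = table$animal_id, GROUP = table$group,
                                 BW = table$body_weight))
    doses <- purrr::map_dfr(seq_len(nrow(an)), function(i) {
      reg <- regimens[[an$GROUP[i]]]
      if (is.null(reg)) return(NULL)
      rows <- NULL
      if (reg$lps) {
        rows <- tibble(ID = an$ID[i], GROUP = an$GROUP[i],
                       TIME = reg$lps_time, DVID = NA_integer_,
                       DV = NA_real_, AMT = reg$lps_dose_per_kg, CMT = 4L,
                       BW = an$BW[i], .ord = 0L)
      }
      if (nrow(reg$cop_events)) {
        rows <- dplyr::bind_rows(rows, tibble(
          ID = an$ID[i], GROUP = an$GROUP[i], TIME = reg$cop_events$time,
          DVID = NA_integer_, DV = NA_real_,
          AMT = reg$cop_events$dose_per_kg, CMT = 1L, BW = an$BW[i],
          .ord = 0L))
      }
      rows
    })
  }
  all_rows <- dplyr::bind_rows(doses, obs) |>
    dplyr::arrange(.data$ID, .data$TIME, .data$.ord) |>
    dplyr::select(-".ord")
  readr::write_csv(all_rows, path, na = "")
  invisible(path)
}

#' Read an observation table from the event-record CSV dialect
#'
#' Validates the header, observable codes (1-6), non-negative times and
#' values, and non-decreasing observation times per animal; malformed rows
#' are reported with their line numbers.  Dose rows (CMT 1/4) are folded back
#' into per-group [dose_regimen()] objects attached as the `regimens`
#' attribute (at the nominal 0.20 kg body weight).
#'
#' @param path CSV path written by [write_dataset()] (or hand-built in the
#'   same dialect).
#' @return An observation tibble as from [generate_study()] (without the
#'   `truth` attribute; `truncated` is `NA`).
#' @export
read_dataset <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    ID = readr::col_character(), GROUP = readr::col_character(),
    TIME = readr::col_double(), DVID = readr::col_integer(),
    DV = readr::col_double(), AMT = readr::col_double(),
    CMT = readr::col_integer(), BW = readr::col_double()
  ), na = c("", "NA"))
  need <- c("ID", "GROUP", "TIME", "DVID", "DV", "AMT", "CMT", "BW")
  if (!identical(names(raw), need)) {
    abort(paste0("malformed header: expected ", paste(need, collapse = ",")))
  }
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  is_dose <- !is.na(raw$CMT)
  is_obs <- !is_dose

  bad <- which(is_obs & (is.na(raw$DVID) | !(raw$DVID %in% 1:6)))
  if (length(bad)) {
    abort(paste0("unknown/missing observable code on line(s): ",
                 paste(line[bad], collapse = ", ")))
  }
  bad <- which(is_obs & (is.na(raw$DV) | raw$DV < 0))
  if (length(bad)) {
    abort(paste0("missing or negative DV on line(s): ",
                 paste(line[bad], collapse = ", ")))
  }
  bad <- which(is.na(raw$TIME) | raw$TIME < 0)
  if (length(bad)) {
    abort(paste0("missing or negative TIME on line(s): ",
                 paste(line[bad], collapse = ", ")))
  }
  bad <- which(is_dose & !(raw$CMT %in% c(1L, 4L)))
  if (length(bad)) {
    abort(paste0("unknown dose compartment on line(s): ",
                 paste(line[bad], collapse = ", ")))
  }
  # observation times must be non-decreasing within animal
  obs <- raw[is_obs, ]
  if (nrow(obs)) {
    dec <- obs |>
      dplyr::mutate(.line = line[is_obs]) |>
      dplyr::group_by(.data$ID) |>
      dplyr::filter(dplyr::row_number() > 1 &
                      .data$TIME < dplyr::lag(.data$TIME)) |>
      dplyr::ungroup()
    if (nrow(dec)) {
      abort(paste0("non-monotone observation times for animal(s) at line(s): ",
                   paste(dec$.line, collapse = ", ")))
    }
  }

  obs_map <- pkpd_observables()
  out <- tibble(
    animal_id = obs$ID, group = obs$GROUP, time = obs$TIME,
    dvid = obs$DVID,
    observable = obs_map$observable[match(obs$DVID, obs_map$dvid)],
    value = obs$DV, body_weight = obs$BW, truncated = NA
  )

  doses <- raw[is_dose, ]
  if (nrow(doses)) {
    regimens <- doses |>
      dplyr::distinct(.data$GROUP, .data$TIME, .data$AMT, .data$CMT) |>
      dplyr::group_by(.data$GROUP) |>
      dplyr::group_map(function(d, key) {
        lps <- d[d$CMT == 4L, ]
        cop <- d[d$CMT == 1L, ]
        cop <- cop[order(cop$TIME), ]
        dose_regimen(cop_dose = cop$AMT, cop_time = cop$TIME,
                     lps = nrow(lps) > 0,
                     lps_time = if (nrow(lps)) lps$TIME[1] else 0,
                     lps_dose = if (nrow(lps)) lps$AMT[1] else 0)
      })
    names(regimens) <- sort(unique(doses$GROUP))
    # groups with observations but no dose rows: unchallenged controls
    ctrl <- setdiff(unique(out$group), names(regimens))
    for (g in ctrl) regimens[[g]] <- dose_regimen(lps = FALSE, lps_dose = 0)
    attr(out, "regimens") <- regimens[order(names(regimens))]
  }
  class(out) <- c("pkpd_observations", class(out))
  out
}
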