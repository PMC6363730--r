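# Shared fixtures for the test suite.

default_p <- model_parameters()

high_dose_regimen <- function(bw = 0.20) {
  dose_regimen(cop_dose = 7.74, cop_time = 0.5, body_weight = bw)
}

lps_only_regimen <- function(bw = 0.20) dose_regimen(body_weight = bw)

# zero variability vectors
omega_zero <- setNames(numeric(length(pkpd_parameter_names())),
                       pkpd_parameter_names())
sigma_zero <- setNames(numeric(6), pkpd_observables()$observable)

# a small serial LPS-only design (no dosing, so body weight is irrelevant):
# used where degenerate/no-variability behaviour is under test
mini_design <- function(n = 3, times = c(0.667, 1, 2, 4, 8),
                        dvid = c(3L, 6L)) {
  pkpd_design(
    groups = tibble::tibble(group = "A", n = as.integer(n), lps = TRUE,
                            lps_dose = 100, cop_dose = 0, cop_time = 0.5,
                            control = FALSE),
    times = times, dvid = dvid, mode = "serial"
  )
}

# noise-free pooled observation table built from the deterministic model at
# the nominal 0.20 kg body weight (predictions match pooled regimens exactly)
pooled_noise_free <- function(params = default_p,
                              doses = c(0, 7.74),
                              times = c(0.667, 1, 2, 4, 6, 8, 12),
                              dvid = c(1L, 3L, 6L)) {
  regimens <- list()
  rows <- list()
  for (d in doses) {
    g <- paste0("g", d)
    reg <- if (d > 0) dose_regimen(cop_dose = d, cop_time = 0.5)
           else dose_regimen()
    regimens[[g]] <- reg
    traj <- simulate_pkpd(params, reg,
                          times = sort(unique(c(0, 0.5, times))))
    obs <- observables(traj, dvid = dvid)
    obs <- obs[obs$time %in% times, ]
    obs$group <- g
    rows[[g]] <- obs
  }
  out <- dplyr::bind_rows(rows)
  out <- out[, c("group", "time", "dvid", "observable", "value")]
  attr(out, "regimens") <- regimens
  out
}
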