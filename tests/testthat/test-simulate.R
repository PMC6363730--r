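test_that("the unstimulated, undosed system stays at zero", {
  traj <- simulate_pkpd(default_p, dose_regimen(lps = FALSE),
                        times = seq(0, 24, by = 0.5))
  expect_true(all(as.matrix(traj[, -1]) == 0))
})

test_that("an IV bolus jumps the plasma concentration by dose*BW/V1", {
  traj <- simulate_pkpd(default_p, high_dose_regimen(),
                        times = c(0, 0.4, 0.5, 0.6))
  # 7.74 mg/kg x 0.20 kg x 1e6 / 2630 mL = 588.59 ng/mL on top of ~0
  expect_equal(traj$cop[traj$time == 0.5], 588.5932, tolerance = 1e-6)
  expect_equal(traj$cop[traj$time == 0.4], 0)
  # the jump is reported post-dose (right-continuous)
  expect_gt(traj$cop[traj$time == 0.5], traj$cop[traj$time == 0.6])
})

test_that("ODE plasma kinetics match the closed-form biexponential oracle", {
  p <- default_p
  reg <- high_dose_regimen()
  times <- sort(unique(c(seq(0.5, 24, by = 0.05), 0.667)))
  traj <- simulate_pkpd(p, reg, times = c(0, times))
  cf <- closed_form_2cpt(p, 7.74 * 0.2 * 1e6, times - 0.5)
  ode <- traj$cop[traj$time >= 0.5]
  expect_lt(max(abs(ode - cf) / cf), 1e-6)
})

test_that("closed-form oracle identities hold", {
  p <- default_p
  # normalization: C(0) = dose / V1
  expect_equal(closed_form_2cpt(p, 1e6, 0), 1e6 / p$V1)
  # alpha+beta and alpha*beta from the micro-constants
  s <- p$k10 + p$k12 + p$k21
  pr <- p$k10 * p$k21
  expect_equal(s, 3.176)
  expect_equal(pr, 0.305944)
  # one-compartment limit: k12 = k21 -> 0
  p1 <- model_parameters(k12 = 1e-10, k21 = 1e-10)
  t <- c(0.5, 1, 2)
  expect_equal(closed_form_2cpt(p1, 1e6, t),
               1e6 / p1$V1 * exp(-p1$k10 * t), tolerance = 1e-6)
  expect_error(closed_form_2cpt(p, 1e6, -1), ">= 0")
})

test_that("coptisine exposure is exactly dose-linear", {
  doses <- c(1.94, 3.87, 7.74)
  aucs <- vapply(doses, function(d) {
    traj <- simulate_pkpd(default_p,
                          dose_regimen(cop_dose = d, cop_time = 0.5),
                          times = sort(unique(c(seq(0, 12, 0.01), 0.5))))
    auc_trapezoid(traj$time, traj$cop, 0, 12)
  }, numeric(1))
  cmaxs <- vapply(doses, function(d) {
    traj <- simulate_pkpd(default_p,
                          dose_regimen(cop_dose = d, cop_time = 0.5),
                          times = c(0, 0.5, 1))
    max(traj$cop)
  }, numeric(1))
  expect_equal(aucs[3] / aucs[1], doses[3] / doses[1], tolerance = 1e-3)
  expect_equal(aucs[2] / aucs[1], doses[2] / doses[1], tolerance = 1e-3)
  expect_equal(cmaxs / cmaxs[1], doses / doses[1], tolerance = 1e-6)
})

test_that("the inflammatory cascade peaks in causal order", {
  traj <- simulate_pkpd(default_p, lps_only_regimen(),
                        times = sort(unique(c(seq(0, 24, 0.01), 0.333, 0.667))))
  tmax <- vapply(c("tnfa", "tnfa_lung", "inos_mrna", "inos", "inos_p",
                   "no_plasma"),
                 function(s) traj$time[which.max(traj[[s]])], numeric(1))
  expect_true(all(diff(tmax) > 0))
  # plasma TNF-alpha peaks when the production window closes (within 1 h)
  expect_equal(unname(tmax["tnfa"]), 0.667, tolerance = 0.02)
})

test_that("reported AUCs are stable under grid and tolerance refinement", {
  reg <- high_dose_regimen()
  auc_of <- function(step, rtol, atol) {
    traj <- simulate_pkpd(default_p, reg,
                          times = sort(unique(c(seq(0, 12, step), 0.5))),
                          rtol = rtol, atol = atol)
    c(auc_trapezoid(traj$time, traj$tnfa, 0, 12),
      auc_trapezoid(traj$time, traj$no_plasma, 0, 12))
  }
  coarse <- auc_of(0.02, 1e-8, 1e-10)
  fine <- auc_of(0.01, 1e-9, 1e-11)
  expect_true(all(abs(coarse - fine) / fine < 1e-4))
})

test_that("trajectories are non-negative, NaN-free and span the grid", {
  traj <- simulate_pkpd(default_p, high_dose_regimen(),
                        times = seq(0, 24, by = 0.1))
  m <- as.matrix(traj[, -1])
  expect_false(anyNA(m))
  expect_true(all(m >= 0))
  expect_equal(range(traj$time), c(0, 24))
})

test_that("simulation input errors are caught", {
  expect_error(simulate_pkpd(default_p, high_dose_regimen(),
                             times = c(1, 0.5)), "strictly increasing")
  expect_error(simulate_pkpd(default_p, high_dose_regimen(),
                             times = c(0, 30)), "\\[0, 24\\]")
  expect_error(dose_regimen(cop_dose = -1, cop_time = 0.5), ">= 0")
  expect_error(simulate_pkpd(default_p, high_dose_regimen(),
                             times = c(0, 1), init = rep(-1, 10)))
})

test_that("observable extraction is the identity map on the matched states", {
  traj <- simulate_pkpd(default_p, high_dose_regimen(),
                        times = seq(0, 12, by = 0.5))
  obs <- observables(traj)
  expect_equal(obs$value[obs$observable == "cop_plasma" & obs$time == 1],
               traj$cop[traj$time == 1])
  expect_equal(obs$value[obs$observable == "no_plasma" & obs$time == 8],
               traj$no_plasma[traj$time == 8])
  expect_true(all(obs$value >= 0))
  expect_error(observables(traj, dvid = 9), "unknown observable")

  gm <- simulate_group_mean(default_p, high_dose_regimen(),
                            times = seq(0, 12, by = 0.5))
  expect_equal(dplyr::n_distinct(gm$dvid), 6)
})
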