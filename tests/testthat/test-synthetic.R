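test_that("packaged designs match the experimental layouts", {
  s1 <- study_design(1)
  expect_equal(sum(s1$groups$n), 9)
  expect_equal(s1$times[1], 0.667)
  expect_equal(study_design(1, variant = "text")$times[1], 0.5)

  s2 <- study_design(2)
  expect_equal(sum(s2$groups$n), 12)
  expect_equal(s2$dvid, c(3L, 6L))

  s3 <- study_design(3)
  expect_equal(sum(s3$groups$n), 74)  # 2 controls + 3 x 24
  expect_equal(length(s3$times), 12)
  expect_equal(s3$n_per_time, 2L)

  s4 <- study_design(4)
  expect_equal(sum(s4$groups$n), 57)  # 3 controls + 3 x 18
  expect_equal(s4$n_per_time, 3L)

  expect_error(study_design(7), "1, 2, 3 or 4")
  # serial designs cannot carry terminal lung observables
  expect_error(
    pkpd_design(groups = study_design(2)$groups, times = c(1, 2),
                dvid = c(3L, 5L), mode = "serial"),
    "lung observables"
  )
})

test_that("individual parameters follow the log-normal BAV law", {
  pop <- default_p
  # omega = 0 returns the population values exactly
  ind0 <- sample_individual_params(pop, omega = omega_zero, seed = 1)
  expect_equal(unlist(ind0[pkpd_parameter_names()]),
               unlist(pop[pkpd_parameter_names()]))
  # determinism under a fixed seed
  a <- sample_individual_params(pop, seed = 11)
  b <- sample_individual_params(pop, seed = 11)
  expect_equal(a, b)
  expect_false(isTRUE(all.equal(a$k10,
                                sample_individual_params(pop, seed = 12)$k10)))
  # Monte-Carlo check of the log-normal law at omega = 0.2
  om <- omega_zero; om["k10"] <- 0.2
  draws <- withr::with_seed(99, {
    vapply(seq_len(1e4),
           function(i) sample_individual_params(pop, omega = om)$k10,
           numeric(1))
  })
  lr <- log(draws / pop$k10)
  expect_lt(abs(mean(lr)), 3 * 0.2 / sqrt(1e4))
  expect_lt(abs(sd(lr) - 0.2) / 0.2, 0.05)
})

test_that("noise-free synthetic data equal the per-animal model predictions", {
  des <- study_design(2)
  dat <- generate_study(des, seed = 5, omega = omega_zero,
                        sigma = sigma_zero)
  expect_false(any(dat$truncated))
  # spot-check two animals against an end-to-end simulation at their BW
  for (aid in c("2A-01", "2B-03")) {
    sub <- dat[dat$animal_id == aid, ]
    g <- des$groups[des$groups$group == sub$group[1], ]
    reg <- if (g$cop_dose > 0) {
      dose_regimen(cop_dose = g$cop_dose, cop_time = g$cop_time,
                   body_weight = sub$body_weight[1])
    } else dose_regimen(body_weight = sub$body_weight[1])
    traj <- simulate_pkpd(default_p, reg,
                          times = sort(unique(c(0, 0.5, des$times))))
    obs <- observables(traj, dvid = des$dvid)
    pred <- obs$value[match(paste(sub$time, sub$dvid),
                            paste(obs$time, obs$dvid))]
    expect_equal(sub$value, pred, tolerance = 1e-8)
  }
})

test_that("study tables have the designed dimensions and sampling structure", {
  dat2 <- generate_study(study_design(2), seed = 2)
  expect_equal(nrow(dat2), 12 * 10 * 2)
  expect_equal(dplyr::n_distinct(dat2$animal_id), 12)

  dat3 <- generate_study(study_design(3), seed = 3)
  expect_equal(dplyr::n_distinct(dat3$animal_id), 74)
  # destructive: each non-control animal appears at exactly one time point
  per_animal <- dat3 |>
    dplyr::filter(.data$group != "3A") |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(nt = dplyr::n_distinct(.data$time))
  expect_true(all(per_animal$nt == 1))
  # n_per_time x n_times rows per group per observable
  counts <- dat3 |>
    dplyr::filter(.data$group != "3A") |>
    dplyr::count(.data$group, .data$dvid)
  expect_true(all(counts$n == 2 * 12))

  dat4 <- generate_study(study_design(4), seed = 4)
  expect_equal(dplyr::n_distinct(dat4$animal_id), 57)

  # body weights emulate 200 +/- 20 g rats
  expect_true(all(dat3$body_weight >= 0.18 & dat3$body_weight <= 0.22))
})

test_that("residual noise scales with sigma and truncates at zero", {
  des <- mini_design(n = 30, times = c(0.667, 1), dvid = 3L)
  sig_small <- sigma_zero; sig_small["tnfa_plasma"] <- 20
  sig_big <- sigma_zero; sig_big["tnfa_plasma"] <- 60
  d1 <- generate_study(des, seed = 8, omega = omega_zero, sigma = sig_small)
  d2 <- generate_study(des, seed = 8, omega = omega_zero, sigma = sig_big)
  d0 <- generate_study(des, seed = 8, omega = omega_zero, sigma = sigma_zero)
  r1 <- sd(d1$value - d0$value)
  r2 <- sd(d2$value - d0$value)
  expect_equal(r2 / r1, 3, tolerance = 0.05)

  # huge noise on a tiny-scale observable must truncate (and flag)
  sig_no <- sigma_zero; sig_no["no_plasma"] <- 1
  d3 <- generate_study(mini_design(n = 10, dvid = 6L), seed = 9,
                       omega = omega_zero, sigma = sig_no)
  expect_true(any(d3$truncated))
  expect_true(all(d3$value >= 0))
  expect_true(all(d3$value[d3$truncated] == 0))
})

test_that("the event-record CSV dialect round-trips losslessly", {
  dat <- generate_study(study_design(2), seed = 21)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_dataset(dat, tmp)
  back <- read_dataset(tmp)
  cols <- c("animal_id", "group", "time", "dvid", "observable", "value",
            "body_weight")
  expect_equal(back[cols], dat[cols], ignore_attr = TRUE)
  # dose rows are folded back into regimens
  regs <- attr(back, "regimens")
  expect_equal(regs[["2B"]]$cop_events$dose_per_kg, 7.74)
  expect_equal(regs[["2B"]]$cop_events$time, 0.5)
  expect_true(regs[["2A"]]$lps)
  expect_equal(nrow(regs[["2A"]]$cop_events), 0)

  # header line + 240 observation rows + 12 LPS + 9 dose rows
  expect_equal(length(readLines(tmp)), 1 + 240 + 12 + 9)
})

test_that("malformed datasets are rejected with line numbers", {
  dat <- generate_study(study_design(2), seed = 22)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_dataset(dat, tmp)
  lines <- readLines(tmp)

  bad <- sub("^([^,]*,[^,]*,[^,]*,)3,", "\\19,", lines[3])
  writeLines(c(lines[1:2], bad, lines[4:length(lines)]), tmp)
  expect_error(read_dataset(tmp), "line\\(s\\): 3")

  # empty table still writes a valid header-only file
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(dat[0, ], tmp2)
  expect_equal(readLines(tmp2), "ID,GROUP,TIME,DVID,DV,AMT,CMT,BW")
  expect_equal(nrow(read_dataset(tmp2)), 0)
})
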