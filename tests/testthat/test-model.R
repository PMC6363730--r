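test_that("TNF-alpha production follows the two-phase zero-order schedule", {
  p <- default_p
  reg <- lps_only_regimen()
  expect_equal(production_rate_tnfa(0.1, reg, p), 645.73)
  expect_equal(production_rate_tnfa(0.5, reg, p), 5881.32)
  expect_equal(production_rate_tnfa(5, reg, p), 0)
  # boundaries: half-open [0, w1), [w1, w2)
  expect_equal(production_rate_tnfa(c(0, 0.333, 0.667), reg, p),
               c(645.73, 5881.32, 0))
  # schedule anchored at the LPS time
  reg2 <- dose_regimen(lps_time = 1)
  expect_equal(production_rate_tnfa(c(0.5, 1.1, 1.5, 2), reg2, p),
               c(0, 645.73, 5881.32, 0))
  # no production without the LPS challenge
  expect_equal(production_rate_tnfa(c(0.1, 0.5), dose_regimen(lps = FALSE), p),
               c(0, 0))
  expect_error(production_rate_tnfa(-1, reg, p), ">= 0")
})

test_that("inhibition fraction is linear, clamped, monotone and bounded", {
  p <- default_p
  expect_equal(inhibition_fraction(0, p), 0)
  expect_equal(inhibition_fraction(619.8, p), 0.5473, tolerance = 1e-4)
  expect_equal(inhibition_fraction(2000, p), 1)            # raw 1.766, clamped
  expect_equal(inhibition_fraction(2000, p, clamp = FALSE), 1.766)
  expect_error(inhibition_fraction(-1, p), "non-negative")
  cc <- seq(0, 3000, by = 50)
  f <- inhibition_fraction(cc, p)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("the RHS matches the stated algebra at anchor states", {
  p <- default_p
  reg <- lps_only_regimen()
  y0 <- setNames(numeric(10), pkpd_states())

  # zero state after the production window: equilibrium
  expect_equal(unname(pkpd_rhs(5, y0, p, reg)), rep(0, 10))
  # zero state in phase 1: only plasma TNF-alpha production
  d <- pkpd_rhs(0.1, y0, p, reg)
  expect_equal(unname(d["tnfa"]), 645.73)
  expect_equal(unname(d[setdiff(names(d), "tnfa")]), rep(0, 9))
  # Michaelis-Menten half-saturation identity
  y <- y0; y["tnfa"] <- p$km
  d <- pkpd_rhs(5, y, p, reg)
  expect_equal(unname(d["tnfa"]), -p$Vm / 2)

  expect_error(pkpd_rhs(1, replace(y0, 1, -1), p, reg), ">= 0")
  expect_error(pkpd_rhs(1, replace(y0, 4, NaN), p, reg), "NA/NaN")
})

test_that("elimination of plasma TNF-alpha saturates at Vm", {
  p <- default_p
  y <- setNames(numeric(10), pkpd_states())
  y["tnfa"] <- 1e9
  d <- pkpd_rhs(0.1, y, p, lps_only_regimen())
  expect_equal(unname(d["tnfa"]), 645.73 - p$Vm, tolerance = 1e-4)
})

test_that("PD decouples from PK when InhibitCon = 0", {
  p0 <- model_parameters(InhibitCon = 0)
  reg <- high_dose_regimen()
  y <- setNames(numeric(10), pkpd_states())
  y["tnfa"] <- 500
  y1 <- y; y1[c("cop", "cop2", "cop_lung")] <- c(800, 300, 2)
  d0 <- pkpd_rhs(0.4, y, p0, reg)
  d1 <- pkpd_rhs(0.4, y1, p0, reg)
  expect_equal(d0["tnfa"], d1["tnfa"])
})

test_that("the coptisine subsystem is linear in its own states", {
  p <- default_p
  reg <- high_dose_regimen()
  y <- setNames(numeric(10), pkpd_states())
  y[c("cop", "cop2", "cop_lung")] <- c(100, 40, 0.5)
  pk <- c("cop", "cop2", "cop_lung")
  d1 <- pkpd_rhs(1, y, p, reg)[pk]
  d3 <- pkpd_rhs(1, replace(y, pk, 3 * y[pk]), p, reg)[pk]
  expect_equal(unname(d3), unname(3 * d1))
})

test_that("the R-level RHS agrees with the compiled solver path", {
  p <- default_p
  reg <- high_dose_regimen()
  times <- c(0.2, 0.333, 0.4, 0.667, 1, 2, 4)  # avoids the dose instant
  # identical tight tolerances on both paths: the comparison isolates the
  # derivative algebra (the smallest states live near the default atol)
  compiled <- simulate_pkpd(p, reg, times = c(0, times),
                            rtol = 1e-10, atol = 1e-14)

  # same integration with the (slower) R-level derivative function
  f <- function(t, y, parms) list(pkpd_rhs(t, pmax(y, 0), p, reg))
  y <- numeric(10)
  segs <- c(0, 0.333, 0.5, 0.667, 4)
  ref <- matrix(NA_real_, nrow = length(times), ncol = 10)
  for (s in seq_len(length(segs) - 1)) {
    sel <- which(times > segs[s] & times <= segs[s + 1])
    tt <- sort(unique(c(segs[s], times[sel], segs[s + 1])))
    sol <- deSolve::lsoda(y, tt, f, NULL, rtol = 1e-10, atol = 1e-14)
    y <- sol[nrow(sol), -1]
    ref[sel, ] <- sol[match(times[sel], sol[, 1]), -1]
    if (segs[s + 1] == 0.5) y[1] <- y[1] + 7.74 * 0.2 * 1e6 / p$V1
  }
  got <- as.matrix(compiled[compiled$time > 0, -1])
  for (j in 1:10) {
    expect_lt(max(abs(got[, j] - ref[, j])) / max(ref[, j]), 1e-6)
  }
})
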