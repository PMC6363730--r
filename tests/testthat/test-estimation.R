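test_that("the Gaussian -2LL has its closed-form anchors", {
  dat <- pooled_noise_free(doses = c(0, 7.74), dvid = c(3L, 6L))
  regs <- attr(dat, "regimens")
  sig <- c(tnfa_plasma = 50, no_plasma = 1e-7)

  # perfect-fit limit: residuals vanish, only the normalizing constant stays
  n3 <- sum(dat$dvid == 3)
  n6 <- sum(dat$dvid == 6)
  expect_equal(negloglik(default_p, dat, regs, sigma = sig),
               n3 * log(2 * pi * 50^2) + n6 * log(2 * pi * (1e-7)^2),
               tolerance = 1e-8)

  # a single one-SD residual contributes log(2 pi sigma^2) + 1
  one <- dat[dat$dvid == 3, ][3, ]
  pred <- one$value
  one$value <- pred + 50
  attr(one, "regimens") <- regs
  expect_equal(negloglik(default_p, one, regs, sigma = sig),
               log(2 * pi * 50^2) + 1, tolerance = 1e-6)

  # doubling sigma changes -2LL by n log(4) - (3/4) RSS / sigma^2
  noisy <- dat
  noisy$value <- withr::with_seed(3, pmax(dat$value +
    rnorm(nrow(dat), 0, sig[dat$observable]), 0))
  attr(noisy, "regimens") <- regs
  rss_term <- negloglik(default_p, noisy, regs, sigma = sig) -
    sum(log(2 * pi * sig[noisy$observable]^2))
  got <- negloglik(default_p, noisy, regs, sigma = 2 * sig) -
    negloglik(default_p, noisy, regs, sigma = sig)
  expect_equal(got, nrow(noisy) * log(4) - (3 / 4) * rss_term,
               tolerance = 1e-8)

  expect_error(negloglik(default_p, dat[0, ], regs), "empty")
  expect_error(negloglik(default_p, dat, regs,
                         sigma = c(tnfa_plasma = 50)), "> 0")
})

test_that("AIC/BIC identities hold", {
  expect_equal(aic_bic(0, 0, 10), c(AIC = 0, BIC = 0))
  expect_equal(unname(aic_bic(100, 5, exp(2))["BIC"]), 110)
  expect_equal(unname(aic_bic(100, 5, exp(2))["AIC"]), 110)
  expect_equal(aic_bic(50, 0, 7), c(AIC = 50, BIC = 50))
  expect_error(aic_bic(1, 1, 0), ">= 1")
})

test_that("an empty free set returns the initial values and their objective", {
  dat <- pooled_noise_free(doses = 7.74, dvid = 3L)
  regs <- attr(dat, "regimens")
  sig <- c(tnfa_plasma = 50)
  fit <- fit_pkpd(dat, free = character(0), regimens = regs, sigma = sig)
  expect_s3_class(fit, "pkpd_fit")
  expect_equal(fit$params, default_p)
  expect_equal(fit$objective, negloglik(default_p, dat, regs, sigma = sig))
  expect_equal(fit$aic, fit$objective)
  expect_true(fit$converged)
  expect_equal(glance(fit)$k, 0)
})

test_that("free PK parameters are recovered from noise-free plasma data", {
  dat <- pooled_noise_free(doses = c(3.87, 7.74), dvid = 1L,
                           times = c(0.6, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12))
  regs <- attr(dat, "regimens")
  init <- model_parameters(V1 = 2630 * 1.4, k10 = 0.458 * 0.7,
                           k12 = 2.05 * 1.3, k21 = 0.668 * 0.75)
  free <- c("V1", "k10", "k12", "k21")
  # fixed sigma: with noise-free data the profiled objective is unbounded
  fit <- fit_pkpd(dat, init = init, free = free, regimens = regs,
                  sigma = c(cop_plasma = 5), n_starts = 1, seed = 2,
                  maxit = 500)
  expect_true(fit$converged)
  est <- unlist(fit$params[free])
  truth <- unlist(default_p[free])
  expect_true(all(abs(est - truth) / truth < 0.01))
  td <- tidy(fit)
  expect_equal(sort(td$term[!td$fixed]), sort(free))
})

test_that("multi-start jitter is seeded and the best start wins", {
  dat <- pooled_noise_free(doses = 7.74, dvid = 1L,
                           times = c(0.6, 1, 2, 4, 8, 12))
  regs <- attr(dat, "regimens")
  f1 <- fit_pkpd(dat, free = "k10", regimens = regs,
                 sigma = c(cop_plasma = 5), n_starts = 3, seed = 7,
                 maxit = 100)
  f2 <- fit_pkpd(dat, free = "k10", regimens = regs,
                 sigma = c(cop_plasma = 5), n_starts = 3, seed = 7,
                 maxit = 100)
  expect_equal(f1$params$k10, f2$params$k10)
  expect_equal(nrow(f1$starts), 3)
  # final objective is recomputed at tight solver tolerance
  expect_equal(f1$objective, min(f1$starts$objective), tolerance = 1e-4)
})

test_that("sequential strategy fits PK first, then the PD parameters", {
  dat <- pooled_noise_free(doses = c(0, 7.74), dvid = c(1L, 3L),
                           times = c(0.6, 1, 2, 4, 8, 12))
  regs <- attr(dat, "regimens")
  init <- model_parameters(k10 = 0.458 * 1.3, k0_phase2 = 5881.32 * 0.8)
  fit <- fit_pkpd(dat, init = init, free = c("k10", "k0_phase2"),
                  regimens = regs, strategy = "sequential", n_starts = 1,
                  sigma = c(cop_plasma = 5, tnfa_plasma = 20),
                  seed = 3, maxit = 300)
  expect_equal(fit$strategy, "sequential")
  expect_equal(fit$params$k10, 0.458, tolerance = 0.01)
  expect_equal(fit$params$k0_phase2, 5881.32, tolerance = 0.01)
})

test_that("parametric-bootstrap RSEs are computable and positive", {
  dat <- pooled_noise_free(doses = 7.74, dvid = 1L,
                           times = c(0.6, 1, 2, 4, 8, 12))
  regs <- attr(dat, "regimens")
  noisy <- dat
  noisy$value <- withr::with_seed(5, pmax(dat$value + rnorm(nrow(dat), 0, 20), 0))
  attr(noisy, "regimens") <- regs
  fit <- fit_pkpd(noisy, free = "k10", regimens = regs, n_starts = 1,
                  seed = 1, maxit = 200)
  rse <- fit_rse(fit, noisy, n_boot = 4, seed = 2, maxit = 100)
  expect_named(rse, c("term", "estimate", "rse_pct"))
  expect_true(all(rse$rse_pct > 0))
})
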