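# Simulation-based model qualification: visual predictive check bands,
# numerical predictive check coverage, and rank-based NPDE.

# Simulate n_sim replicate studies under a design and return the DV values
# aligned to the design's observation skeleton: a list with the template
# schedule and an nrow(template) x n_sim matrix.  Each replicate redraws
# body weights, individual parameters (log-normal BAV) and additive residual
# noise, truncated at zero like the generator.
simulate_replicates <- function(design, params, omega = params$omega,
                                sigma = params$sigma_add, n_sim = 1000,
                                seed = 1) {
  validate_design(design)
  validate_parameters(params)
  schedule <- build_schedule(design)
  obs_map <- pkpd_observables()
  sig <- setNames(numeric(6), obs_map$observable)
  sig[names(sigma)] <- sigma
  sig_rows <- sig[schedule$dvid]

  pop <- unlist(params[PKPD_PARAM_NAMES])
  om <- setNames(numeric(length(pop)), names(pop))
  om[names(omega)] <- omega

  animals <- dplyr::distinct(schedule, .data$animal_id, .data$group)
  arow <- lapply(animals$animal_id,
                 function(a) which(schedule$animal_id == a))
  asched <- lapply(arow, function(r) schedule[r, c("time", "dvid")])
  agrow <- lapply(animals$group,
                  function(g) design$groups[design$groups$group == g, ])

  M <- matrix(NA_real_, nrow = nrow(schedule), ncol = n_sim)
  withr::local_seed(seed)
  for (k in seq_len(n_sim)) {
    bw <- runif(nrow(animals), 0.18, 0.22)
    for (i in seq_len(nrow(animals))) {
      theta <- pop * exp(rnorm(length(pop), 0, om))
      reg <- group_regimen(agrow[[i]], body_weight = bw[i])
      M[arow[[i]], k] <- predict_observables(as.list(theta), reg,
                                             asched[[i]])
    }
    M[, k] <- pmax(M[, k] + rnorm(nrow(schedule), 0, sig_rows), 0)
  }
  list(schedule = schedule, sims = M, n_sim = n_sim, seed = seed)
}

# Bin key shared by observed data and the simulation template.
bin_key <- function(df) paste(df$group, df$dvid, round(df$time, 9))

check_schedule <- function(data, schedule) {
  missing <- setdiff(unique(bin_key(data)), unique(bin_key(schedule)))
  if (length(missing)) {
    abort(paste0("data contains bins absent from the design schedule: ",
                 paste(head(missing, 5), collapse = "; ")))
  }
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate studies from the model (between-animal
#' variability plus residual noise), computes the requested percentiles of
#' the simulated values in each bin - bins are the scheduled nominal times,
#' stratified by group and observable - and the envelope of each percentile
#' across replicates; the same empirical percentiles of the observed data are
#' computed on the same bins.  Bins with fewer than 2 observations are kept
#' but flagged.
#'
#' @param data Observation tibble matching the design's schedule.
#' @param params Population parameters.
#' @param design The [study_design()] that produced (or mirrors) `data`.
#' @param omega,sigma Variability parameters (defaults from `params`).
#' @param n_sim Number of replicate studies (>= 100; default 2000, the
#'   number used to qualify the published model).
#' @param seed Integer seed.
#' @param probs Percentiles to check (default 5th/50th/95th).
#' @param envelope Coverage of the percentile envelope across replicates
#'   (default 0.95, i.e. 2.5-97.5%).
#' @return A tibble of class `pkpd_vpc` with columns `group`, `dvid`,
#'   `time`, `prob`, `n_obs`, `observed`, `sim_lo`, `sim_med`, `sim_hi`,
#'   `flagged`; attributes `n_sim`, `seed`, `envelope`.
#' @export
vpc <- function(data, params, design, omega = params$omega,
                sigma = params$sigma_add, n_sim = 2000, seed = 1,
                probs = c(0.05, 0.5, 0.95), envelope = 0.95) {
  if (n_sim < 100) abort("n_sim must be >= 100")
  rep <- simulate_replicates(design, params, omega = omega, sigma = sigma,
                             n_sim = n_sim, seed = seed)
  check_schedule(data, rep$schedule)
  skey <- bin_key(rep$schedule)
  dkey <- bin_key(data)

  bins <- dplyr::distinct(data[, c("group", "dvid", "time")])
  out <- purrr::map_dfr(seq_len(nrow(bins)), function(i) {
    key <- bin_key(bins[i, ])
    obs <- data$value[dkey == key]
    simrows <- rep$sims[skey == key, , drop = FALSE]
    # per-replicate percentile of the bin, then envelope across replicates
    purrr::map_dfr(probs, function(pr) {
      per_rep <- apply(simrows, 2, quantile, probs = pr, names = FALSE)
      env <- quantile(per_rep,
                      probs = c((1 - envelope) / 2, 0.5, (1 + envelope) / 2),
                      names = FALSE)
      tibble(group = bins$group[i], dvid = bins$dvid[i], time = bins$time[i],
             prob = pr, n_obs = length(obs),
             observed = quantile(obs, probs = pr, names = FALSE),
             sim_lo = env[1], sim_med = env[2], sim_hi = env[3],
             flagged = length(obs) < 2)
    })
  })
  class(out) <- c("pkpd_vpc", class(out))
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  attr(out, "envelope") <- envelope
  out
}

#' Numerical predictive check
#'
#' For each prediction-interval width, the fraction of observations falling
#' inside the simulation-derived interval of their bin (group x observable x
#' scheduled time), with an exact binomial 95% confidence interval on that
#' coverage.
#'
#' Coverage is only interpretable under the additive-error model's
#' continuity assumption: observations truncated at zero (and bins whose
#' simulated values pile up at zero) carry a point mass that distorts
#' interval coverage; restrict `data` to high-signal bins when checking
#' nominal coverage.
#'
#' @inheritParams vpc
#' @param intervals Prediction-interval widths (default 50% and 90%).
#' @param by_dvid Also stratify coverage by observable (animals are
#'   independent within an observable, so these rows carry valid binomial
#'   confidence bounds even when the pooled rows do not; default `FALSE`).
#' @return A tibble with columns `interval`, `dvid` (`NA` for the pooled
#'   rows), `n`, `n_inside`, `coverage`, `conf_lo`, `conf_hi`; attributes
#'   `n_sim`, `seed`.
#' @export
npc <- function(data, params, design, omega = params$omega,
                sigma = params$sigma_add, intervals = c(0.5, 0.9),
                n_sim = 2000, seed = 1, by_dvid = FALSE) {
  if (!length(intervals)) abort("intervals must be non-empty")
  if (any(intervals <= 0 | intervals >= 1)) {
    abort("intervals must lie in (0, 1)")
  }
  rep <- simulate_replicates(design, params, omega = omega, sigma = sigma,
                             n_sim = n_sim, seed = seed)
  check_schedule(data, rep$schedule)
  skey <- bin_key(rep$schedule)
  dkey <- bin_key(data)

  cov_row <- function(iv, inside, dvid) {
    ct <- stats::binom.test(sum(inside), length(inside))
    tibble(interval = iv, dvid = dvid, n = length(inside),
           n_inside = sum(inside), coverage = mean(inside),
           conf_lo = ct$conf.int[1], conf_hi = ct$conf.int[2])
  }
  out <- purrr::map_dfr(intervals, function(iv) {
    lo_p <- (1 - iv) / 2
    hi_p <- (1 + iv) / 2
    inside <- purrr::map_lgl(seq_len(nrow(data)), function(i) {
      sims <- as.vector(rep$sims[skey == dkey[i], , drop = FALSE])
      b <- quantile(sims, probs = c(lo_p, hi_p), names = FALSE)
      data$value[i] >= b[1] && data$value[i] <= b[2]
    })
    res <- cov_row(iv, inside, NA_integer_)
    if (by_dvid) {
      res <- dplyr::bind_rows(res, purrr::map_dfr(
        sort(unique(data$dvid)),
        function(d) cov_row(iv, inside[data$dvid == d], d)
      ))
    }
    res
  })
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  out
}

# Rank-based pde for one observation against its simulated counterparts:
# ties mid-ranked, extreme ranks pulled in by half a count.
pde_value <- function(obs, sims) {
  n <- length(sims)
  pde <- (sum(sims < obs) + 0.5 * sum(sims == obs)) / n
  min(max(pde, 1 / (2 * n)), 1 - 1 / (2 * n))
}

#' Normalized prediction distribution errors (rank-based)
#'
#' For each observation, its rank among `n_sim` simulated counterparts (the
#' matching animal slot, time and observable across replicate studies) is
#' mapped through the standard-normal quantile function.  Ties are
#' mid-ranked and ranks of 0 or `n_sim` are adjusted by half a count.  No
#' decorrelation step is applied: serial correlation within animals is
#' ignored (exact for destructive designs, where each animal contributes one
#' observation per observable).
#'
#' Under the null (data generated by the same model), the NPDEs are
#' approximately standard normal.
#'
#' @inheritParams vpc
#' @param n_sim Number of replicate studies (>= 500).
#' @return A tibble of class `pkpd_npde`: the observation rows plus `pde`
#'   and `npde` columns; attributes `n_sim`, `seed`.
#' @export
npde <- function(data, params, design, omega = params$omega,
                 sigma = params$sigma_add, n_sim = 1000, seed = 1) {
  if (n_sim < 500) abort("n_sim must be >= 500")
  rep <- simulate_replicates(design, params, omega = omega, sigma = sigma,
                             n_sim = n_sim, seed = seed)
  check_schedule(data, rep$schedule)

  # align each observation to a template row: same bin, occurrence order
  occ <- function(df) {
    df |>
      dplyr::mutate(.key = bin_key(df)) |>
      dplyr::group_by(.data$.key) |>
      dplyr::mutate(.occ = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  d <- occ(as_tibble(data))
  s <- occ(rep$schedule)
  idx <- match(paste(d$.key, d$.occ), paste(s$.key, s$.occ))
  if (anyNA(idx)) {
    abort("data has more observations in a bin than the design schedule")
  }
  pde <- purrr::map_dbl(seq_len(nrow(d)),
                        function(i) pde_value(d$value[i], rep$sims[idx[i], ]))
  out <- as_tibble(data)
  out$pde <- pde
  out$npde <- qnorm(pde)
  class(out) <- c("pkpd_npde", class(out))
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  out
}
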