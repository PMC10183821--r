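test_that("split-chain R-hat behaves on canonical cases", {
  set.seed(31)
  # one long stationary stream split into two chains: R-hat near 1
  x <- rnorm(4000)
  expect_lt(abs(rhat(x, chain = rep(1:2, each = 2000)) - 1), 0.05)
  # disjoint chains: far above the 1.1 threshold
  y <- c(rnorm(500, 0, 0.1), rnorm(500, 10, 0.1))
  expect_gt(rhat(y, chain = rep(1:2, each = 500)), 2)
  # constant identical chains: defined as 1
  expect_equal(unname(rhat(rep(3.7, 200), chain = rep(1:2, each = 100))), 1)
  expect_error(rhat(x, chain = rep(1, 4000)), "2 chains")
})

test_that("weight of evidence splits posterior mass around zero", {
  arr <- suppressWarnings(encode_surveys(tiny_survey()))
  draws <- cbind(pos = abs(rnorm(40)) + 0.01, sym = rep(c(-1, -1, 1, 1), 10))
  f <- fake_fit(arr, matrix(0L, 4, arr$nsite * arr$nyear), draws = draws,
                chain = rep(1:2, each = 20))
  expect_equal(weight_of_evidence(f, "pos"),
               c(omega_plus = 1, omega_minus = 0))
  expect_equal(weight_of_evidence(f, "sym"),
               c(omega_plus = 0.5, omega_minus = 0.5))
  expect_error(weight_of_evidence(f, "nope"), "unknown")
  # zero draws are counted to neither side
  f$draws <- cbind(mix = c(rep(0, 10), rep(1, 20), rep(-1, 10)))
  expect_equal(weight_of_evidence(f, "mix"),
               c(omega_plus = 2 / 3, omega_minus = 1 / 3))
})

small_fit <- function(seed = 19, variant = "full", iterations = 1200) {
  sim <- suppressWarnings(simulate_surveys(
    sim_scenario(n_parks = 2, sites_per_park = 25, years = 2016:2021,
                 surveyed_years = c(2016, 2018:2021), park_skip_prob = 0,
                 seed = seed)))
  fit <- suppressWarnings(fit_occupancy(
    sim, variant,
    config = sampler_config(chains = 2, iterations = iterations,
                            burn_in = iterations %/% 2, seed = seed),
    rerun = FALSE))
  list(sim = sim, fit = fit)
}

test_that("posterior predictive p-values flag gross misfit", {
  sf <- small_fit(19)
  fit <- sf$fit
  set.seed(2)
  p_ok <- ppc_pvalue(fit, "FS")
  expect_gt(p_ok, 0.01)
  expect_lt(p_ok, 0.99)
  # corrupt the observed data: all FS detections set to one
  bad <- fit
  bad$arr$y[, "FS"] <- 1L
  set.seed(3)
  p_bad <- ppc_pvalue(bad, "FS")
  expect_lt(p_bad, 0.05)
  expect_error(ppc_pvalue(fit, "XX"), "not part")
})

test_that("a dataset with no detections fits without crashing", {
  det <- default_detection_params()
  det$beta_fp <- lapply(det$beta_fp,
                        function(b) { if (length(b)) { b[] <- 0; b[1] <- -50 }; b })
  sim <- suppressWarnings(simulate_surveys(
    sim_scenario(n_parks = 2, sites_per_park = 15, years = 2018:2021,
                 surveyed_years = 2018:2021, detection = det,
                 dynamics = dynamics_params(lambda = c(-50, 0),
                                            gamma = c(-50, 0, 0),
                                            eps = c(0, 0)),
                 seed = 4)))
  expect_equal(sum(sim$data$records[, 7:10]), 0)
  fit <- suppressWarnings(fit_occupancy(
    sim, "full",
    config = sampler_config(chains = 2, iterations = 600, burn_in = 300,
                            seed = 1),
    rerun = FALSE))
  # occupancy-related quantities stay low; nothing blows up
  occ1 <- mean(fit$z_draws[, seq_len(fit$arr$nsite)])
  expect_lt(occ1, 0.35)
  expect_true(all(is.finite(fit$loglik)))
})

test_that("perfect-detection fit recovers counted transition frequencies", {
  # data in which detection is genuinely perfect: one survey per site-year
  # that reports exactly z
  set.seed(55)
  sc <- sim_scenario(n_parks = 2, sites_per_park = 75, years = 2014:2021,
                     surveyed_years = 2014:2021, park_skip_prob = 0,
                     resurvey_fraction = 0, seed = 55)
  shell <- preprocess_covariates(simulate_covariates(sc))
  # constant transition rates so counted frequencies estimate the same
  # quantity as the site-year averaged probabilities
  dyn <- dynamics_params(lambda = c(0, 0.5), gamma = c(qlogis(0.10), 0, 0),
                         eps = c(qlogis(0.15), 0))
  z <- simulate_occupancy(dyn, shell, effects = zero_effects(2, 8))
  arr0 <- suppressWarnings(encode_surveys(shell))
  grid <- tidyr::expand_grid(i = seq_len(arr0$nsite),
                             t = seq_len(arr0$nyear))
  rec <- tibble::tibble(
    site_id = arr0$site_id[grid$i],
    park_id = arr0$park_levels[arr0$park[grid$i]],
    year = arr0$years[grid$t], survey_index = 1L,
    season = 0L, survey_period = 1L,
    det_fs = as.integer(z[cbind(grid$i, grid$t)]),
    det_fh = 0L, det_pc = 0L, det_ps = 0L,
    unamb_fs = 0L, unamb_fh = 0L, unamb_pc = 0L, unamb_ps = 0L
  )
  data <- shell
  data$records <- rec
  fit <- suppressWarnings(fit_occupancy(
    data, "perfect",
    config = sampler_config(chains = 2, iterations = 1500, burn_in = 750,
                            seed = 9),
    rerun = FALSE))
  # the latent states are fully pinned by the data
  zhat <- matrix(colMeans(fit$z_draws), fit$arr$nsite, fit$arr$nyear)
  expect_equal(zhat, matrix(as.numeric(z), nrow(z), ncol(z)),
               ignore_attr = TRUE)
  # counted frequencies vs posterior turnover
  prev <- z[, -ncol(z)]
  curr <- z[, -1]
  turn <- turnover_rates(fit)
  expect_equal(turn$mean[1], mean(curr[prev == 0]), tolerance = 1e-6)
  expect_equal(turn$mean[2], mean(1 - curr[prev == 1]), tolerance = 1e-6)
  # posterior mean site-year colonization/extinction probabilities close
  # to the counted rates
  cmp <- compare_variants(list(perfect = fit))
  expect_lt(abs(cmp$colonization - mean(curr[prev == 0])), 0.05)
  expect_lt(abs(cmp$extinction - mean(1 - curr[prev == 1])), 0.08)
})

test_that("a full-model fit without unambiguous detections warns about identifiability", {
  sim <- suppressMessages(suppressWarnings(simulate_surveys(
    sim_scenario(n_parks = 2, sites_per_park = 10, years = 2019:2021,
                 surveyed_years = 2019:2021, seed = 2))))
  sim$data$records$unamb_fs <- 0L
  sim$data$records$unamb_ps <- 0L
  sim$data$records$det_ps <- 0L
  expect_warning(
    fit_occupancy(sim$data, "full",
                  config = sampler_config(chains = 2, iterations = 200,
                                          burn_in = 100, seed = 1),
                  rerun = FALSE),
    class = "pika_identifiability_warning"
  )
})

test_that("tidy and glance summarize a fit in broom conventions", {
  sf <- small_fit(23, iterations = 800)
  td <- tidy(sf$fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high",
                    "omega_plus", "rhat") %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_equal(td$omega_plus + td$omega_minus, rep(1, nrow(td)))
  gl <- glance(sf$fit)
  expect_equal(gl$variant, "full")
  expect_equal(gl$n_chains, 2L)
  p <- ggplot2::autoplot(sf$fit)
  expect_s3_class(p, "ggplot")
})
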