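intercept_only_params <- function(p = c(FS = 0.8, FH = 0.3, PC = 0.4,
                                        PS = 0.1),
                                  fp = c(FS = 0.02, FH = 0.02, PC = 0.04)) {
  detection_params(
    beta = list(FS = qlogis(p[["FS"]]), FH = qlogis(p[["FH"]]),
                PC = qlogis(p[["PC"]]), PS = qlogis(p[["PS"]])),
    beta_fp = list(FS = qlogis(fp[["FS"]]), FH = qlogis(fp[["FH"]]),
                   PC = qlogis(fp[["PC"]]), PS = numeric(0)),
    designs = list(
      p = list(FS = "intercept", FH = "intercept", PC = "intercept",
               PS = "intercept"),
      fp = list(FS = "intercept", FH = "intercept", PC = "intercept",
                PS = character(0))
    )
  )
}

test_that("detection probabilities are inverse-logit linear predictors", {
  prm <- intercept_only_params()
  expect_equal(p_detect("FS", c(intercept = 1), prm), 0.8)
  zero <- detection_params(beta = list(FS = c(0, 0)),
                           designs = list(p = list(FS = c("intercept",
                                                          "forb")),
                                          fp = list(FS = character(0))))
  expect_equal(p_detect("FS", c(1, 0.7), zero), 0.5)
  # a forb coefficient of 0.336 at forb = 1 (intercept 0)
  fh <- detection_params(beta = list(FH = c(0, 0.336)),
                         designs = list(p = list(FH = c("intercept", "forb")),
                                        fp = list(FH = character(0))))
  expect_equal(p_detect("FH", c(1, 1), fh), plogis(0.336))
  expect_equal(round(p_detect("FH", c(1, 1), fh), 4), 0.5832)
  expect_error(p_detect("FS", c(1, 2, 3), zero), "length")
})

test_that("false-positive probabilities respect the structural zeros", {
  prm <- intercept_only_params()
  # unambiguous observations can never be false positives
  expect_equal(p_false("FS", c(intercept = 1), prm, unambiguous = 1), 0)
  # an always-unambiguous sign type has no false-positive process at all
  expect_equal(p_false("PS", c(intercept = 1), prm), 0)
  zero <- detection_params(beta = list(FS = 0), beta_fp = list(FS = 0),
                           designs = list(p = list(FS = "intercept"),
                                          fp = list(FS = "intercept")))
  expect_equal(p_false("FS", c(intercept = 1), zero), 0.5)
})

test_that("survey log-likelihood multiplies independent sign processes", {
  prm <- intercept_only_params()
  y <- c(FS = 1, FH = 1, PC = 1, PS = 1)
  u <- c(FS = 0, FH = 0, PC = 0, PS = 0)
  ll <- survey_loglik(y, u, z = 1, x = c(season = 0), prm)
  expect_equal(ll, log(0.8 * 0.3 * 0.4 * 0.1))
  expect_equal(ll, log(0.0096))
  # unoccupied site with an unambiguous detection: impossible
  expect_equal(survey_loglik(y, c(FS = 1, FH = 0, PC = 0, PS = 0), z = 0,
                             x = c(season = 0), prm), -Inf)
  # unoccupied, nothing detected: product of (1 - p^xi)
  y0 <- c(FS = 0, FH = 0, PC = 0, PS = 0)
  expect_equal(survey_loglik(y0, u, z = 0, x = c(season = 0), prm),
               log(0.98) + log(0.98) + log(0.96) + log(1))
  expect_error(survey_loglik(y0, c(FS = 1, FH = 0, PC = 0, PS = 0), z = 1,
                             x = c(season = 0), prm),
               class = "pika_integrity_error")
})

test_that("the annual transition kernel is the two-branch Bernoulli rate", {
  expect_equal(transition_prob(1, gamma = 0.5, eps = 0.062), 0.938)
  expect_equal(transition_prob(0, gamma = 0, eps = 0.5), 0)
  expect_equal(transition_prob(0, gamma = 0.058, eps = 0.5), 0.058)
  # monotonicity: persistence never increases with extinction
  eps_grid <- seq(0, 1, by = 0.1)
  pers <- transition_prob(rep(1, 11), 0.3, eps_grid)
  expect_true(all(diff(pers) <= 0))
})

test_that("marginal site likelihood agrees with brute-force enumeration", {
  set.seed(404)
  for (rep in 1:25) {
    cs <- random_case()
    for (variant in c("full", "nofp", "perfect")) {
      for (i in seq_len(cs$arr$nsite)) {
        got <- site_loglik_marginal(cs$arr, i, cs$detection, cs$dynamics,
                                    cs$effects, variant)
        want <- enum_site_loglik(cs$arr, i, cs$detection, cs$dynamics,
                                 cs$effects, variant)
        if (is.infinite(want)) expect_true(got < -1e200 || is.infinite(got))
        else expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("a site with no surveys has marginal likelihood one", {
  sd <- tiny_survey()
  sd$records <- sd$records[sd$records$site_id != "B1", ]
  arr <- suppressWarnings(encode_surveys(sd))
  b1 <- which(arr$site_id == "B1")
  ll <- site_loglik_marginal(arr, b1, default_detection_params(),
                             default_dynamics_params(),
                             zero_effects(arr$npark, arr$nyear))
  expect_equal(ll, 0)
})

test_that("an unambiguous sighting annihilates the unoccupied branch", {
  # single modeled year, one survey, PS detected (hence unambiguous)
  rec <- tiny_records()[4, ]
  sd <- survey_data(rec, tiny_sites(), tiny_climate(2018), years = 2018)
  arr <- suppressWarnings(encode_surveys(sd))
  prm <- intercept_only_params()
  dyn <- default_dynamics_params()
  i <- which(arr$site_id == "A2")
  eff <- zero_effects(arr$npark, 1)
  psi1 <- plogis(dyn$lambda[["intercept"]] +
                   dyn$lambda[["complexity"]] * arr$complexity[i])
  # z = 1 branch only: psi1 * p_ps * (1-p_fs)(1-p_fh)(1-p_pc)
  want <- log(psi1 * 0.1 * 0.2 * 0.7 * 0.6)
  expect_equal(site_loglik_marginal(arr, i, prm, dyn, eff), want,
               tolerance = 1e-12)
})

test_that("compiled likelihood matches the reference implementation", {
  sim <- suppressWarnings(simulate_surveys(
    sim_scenario(n_parks = 2, sites_per_park = 12, years = 2015:2020,
                 surveyed_years = c(2015, 2017:2020), seed = 7)))
  arr <- suppressWarnings(encode_surveys(sim$data))
  for (v in c("full", "nofp", "standard", "perfect")) {
    det <- apply_variant(sim$detection, v)
    if (v == "standard") det$beta$ANY <- c(1.2, -0.3, -0.2)
    dat <- pikasign:::build_cpp_data(arr, det, default_dyn_designs(), v)
    th <- pikasign:::params_to_theta(arr, det, sim$dynamics, sim$effects, v)
    llr <- loglik_total(arr, det, sim$dynamics, sim$effects, v)
    expect_equal(pikasign:::cpp_loglik_total(dat, th), llr,
                 tolerance = 1e-10)
  }
})

test_that("variant reductions are consistent limits of the full model", {
  set.seed(77)
  cs <- random_case(T = 4)
  arr <- cs$arr
  # full model with false-positive coefficients pushed to -infinity
  det_lim <- cs$detection
  det_lim$beta_fp <- lapply(det_lim$beta_fp, function(b) {
    if (length(b)) { b[] <- 0; b[1] <- -40 }
    b
  })
  ll_lim <- loglik_total(arr, det_lim, cs$dynamics, cs$effects, "full")
  ll_nofp <- loglik_total(arr, apply_variant(cs$detection, "nofp"),
                          cs$dynamics, cs$effects, "nofp")
  expect_equal(ll_lim, ll_nofp, tolerance = 1e-8)
})

test_that("single-sign no-false-positive model equals the collapsed standard model", {
  set.seed(99)
  cs <- random_case(T = 4)
  arr <- cs$arr
  # keep only the FS detections: a one-sign multi-sign model
  arr1 <- arr
  arr1$y <- arr$y[, "FS", drop = FALSE]
  arr1$u <- matrix(0L, nrow(arr$y), 1, dimnames = list(NULL, "FS"))
  det1 <- detection_params(
    beta = list(FS = cs$detection$beta$FS),
    designs = list(p = list(FS = cs$detection$designs$p$FS),
                   fp = list(FS = character(0)))
  )
  ll_one <- loglik_total(arr1, det1, cs$dynamics, cs$effects, "nofp")
  # standard variant on the same data: any-sign = FS since only FS kept
  det_std <- detection_params(
    beta = list(ANY = cs$detection$beta$FS),
    designs = list(p = list(ANY = cs$detection$designs$p$FS),
                   fp = list(ANY = character(0)))
  )
  arr_std <- arr
  arr_std$y <- arr1$y
  arr_std$u <- arr1$u
  ll_std <- loglik_total(arr_std, det_std, cs$dynamics, cs$effects,
                         "standard")
  expect_equal(ll_one, ll_std, tolerance = 1e-12)
})

test_that("likelihood is invariant to permuting replicate surveys", {
  set.seed(15)
  cs <- random_case(T = 3, nsurv_max = 3)
  arr <- cs$arr
  ll1 <- loglik_total(arr, cs$detection, cs$dynamics, cs$effects, "full")
  # reverse the order of surveys globally; site/year assignment unchanged
  perm <- rev(seq_len(nrow(arr$surveys)))
  arr2 <- arr
  arr2$surveys <- arr$surveys[perm, ]
  arr2$y <- arr$y[perm, , drop = FALSE]
  arr2$u <- arr$u[perm, , drop = FALSE]
  ll2 <- loglik_total(arr2, cs$detection, cs$dynamics, cs$effects, "full")
  expect_equal(ll2, ll1, tolerance = 1e-12)
})

test_that("variant reduction rules transform parameters as specified", {
  prm <- default_detection_params()
  nofp <- apply_variant(prm, "nofp")
  expect_true(all(lengths(nofp$beta_fp) == 0))
  std <- apply_variant(prm, "standard")
  expect_equal(names(std$beta), "ANY")
  perf <- apply_variant(prm, "perfect")
  expect_equal(length(perf$beta), 0)
  expect_error(apply_variant(prm, "bogus"), "unknown")
  # standard collapse: any sign detected -> any = 1
  arrs <- suppressWarnings(encode_surveys(tiny_survey()))
  coll <- pikasign:::collapse_any_sign(arrs)
  expect_equal(as.vector(coll$y),
               as.integer(rowSums(arrs$y) > 0))
  # perfect on a surveyed site-year with zero detections pins z to 0
  sd0 <- tiny_survey()
  em <- pikasign:::perfect_emissions(suppressWarnings(encode_surveys(sd0)))
  arr0 <- suppressWarnings(encode_surveys(sd0))
  a2 <- which(arr0$site_id == "A2")
  t2019 <- which(arr0$years == 2019)
  expect_equal(em$e1[a2, t2019], 0)  # surveyed, nothing detected
  expect_equal(em$e0[a2, t2019], 1)
})
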