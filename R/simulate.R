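#' Define a synthetic survey scenario
#'
#' Describes the design of a simulated multi-park monitoring program:
#' numbers of parks and sites, the modeled and surveyed year grid, the
#' resurvey fraction, the generating detection and dynamics parameters,
#' and the probability that a true fresh-scat detection presents
#' unambiguous features. The defaults mirror a five-park program with
#' about 100 sites per park surveyed annually over 2010-2021 with a
#' two-year gap (2015-2016), 30% resurveys, occasional unsurveyed
#' park-years, and generating parameters at the posterior operating point
#' of the fitted full model.
#'
#' @param n_parks Number of parks.
#' @param sites_per_park Sites per park.
#' @param years Modeled (consecutive) calendar years.
#' @param surveyed_years Subset of `years` in which surveys occur.
#' @param resurvey_fraction Fraction of sites resurveyed within the
#'   closure period each surveyed park-year.
#' @param park_skip_prob Probability that a given park skips a surveyed
#'   year entirely (emulating park-level gaps in real programs).
#' @param p_unambiguous_fs Probability that a true fresh-scat detection
#'   presents unambiguous features (mucous-bound morphology) in the notes.
#' @param p_fall Probability a site's surveys in a year happen in fall
#'   rather than summer.
#' @param detection Generating `pika_detection_params`.
#' @param dynamics Generating `pika_dynamics_params`.
#' @param seed Integer seed; fully determines the simulated dataset.
#'
#' @return Object of class `pika_scenario`.
#' @export
sim_scenario <- function(n_parks = 5, sites_per_park = 100,
                         years = 2010:2021,
                         surveyed_years = c(2010:2014, 2017:2021),
                         resurvey_fraction = 0.3,
                         park_skip_prob = 0.1,
                         p_unambiguous_fs = 0.3,
                         p_fall = 0.5,
                         detection = default_detection_params(),
                         dynamics = default_dynamics_params(),
                         seed = 1L) {
  stopifnot(resurvey_fraction >= 0, resurvey_fraction <= 1,
            park_skip_prob >= 0, park_skip_prob <= 1,
            p_unambiguous_fs >= 0, p_unambiguous_fs <= 1,
            all(surveyed_years %in% years))
  structure(
    list(n_parks = n_parks, sites_per_park = sites_per_park,
         years = as.integer(years),
         surveyed_years = as.integer(surveyed_years),
         resurvey_fraction = resurvey_fraction,
         park_skip_prob = park_skip_prob,
         p_unambiguous_fs = p_unambiguous_fs, p_fall = p_fall,
         detection = detection, dynamics = dynamics, seed = as.integer(seed)),
    class = "pika_scenario"
  )
}

#' Simulate site and climate covariates for a scenario
#'
#' Draws raw (unstandardized) covariates: percent covers from bounded beta
#' distributions, substrate complexity uniform over its three levels, and
#' climate built from park-level means plus annual and site-level
#' variation. Returns a survey-data shell (no detection records yet).
#' Uses the current RNG state; seed the stream (or use
#' [simulate_surveys()]) for reproducibility.
#'
#' @param scenario A `pika_scenario`.
#' @return A `pika_survey` with empty `records`.
#' @export
simulate_covariates <- function(scenario) {
  np <- scenario$n_parks
  ns <- scenario$sites_per_park
  years <- scenario$years
  park_id <- sprintf("P%02d", seq_len(np))
  sites <- tibble::tibble(
    site_id = sprintf("%s_S%03d", rep(park_id, each = ns),
                      rep(seq_len(ns), np)),
    park_id = rep(park_id, each = ns),
    forb = stats::rbeta(np * ns, 2, 8) * 100,
    rock = stats::rbeta(np * ns, 5, 3) * 100,
    shrub = stats::rbeta(np * ns, 2, 10) * 100,
    complexity = sample(c("low", "intermediate", "high"), np * ns,
                        replace = TRUE)
  )
  tmax_park <- runif(np, 18, 28)
  tmax_year <- rnorm(length(years), 0, 0.8)
  prcp_park <- runif(np, 300, 3000)
  prcp_year <- rnorm(length(years), 0, 0.2)
  site_tmax_dev <- rnorm(np * ns, 0, 1.2)
  site_prcp_dev <- rnorm(np * ns, 0, 0.25)
  pk <- rep(seq_len(np), each = ns)
  climate <- tidyr::expand_grid(i = seq_len(np * ns), t = seq_along(years)) %>%
    mutate(
      site_id = sites$site_id[.data$i],
      year = years[.data$t],
      tmaxmean = tmax_park[pk[.data$i]] + tmax_year[.data$t] +
        site_tmax_dev[.data$i],
      precip = prcp_park[pk[.data$i]] *
        exp(prcp_year[.data$t] + site_prcp_dev[.data$i])
    ) %>%
    select("site_id", "year", "tmaxmean", "precip")

  empty_rec <- tibble::tibble(
    site_id = character(), park_id = character(), year = integer(),
    survey_index = integer(), season = integer(), survey_period = integer(),
    det_fs = integer(), det_fh = integer(), det_pc = integer(),
    det_ps = integer(), unamb_fs = integer(), unamb_fh = integer(),
    unamb_pc = integer(), unamb_ps = integer()
  )
  survey_data(empty_rec, sites, climate, years = years)
}

# Draw the random-effect realizations used by the state process.
draw_dynamics_effects <- function(dynamics, npark, nyear) {
  s <- dynamics$sigma
  list(
    park_int = rnorm(npark, 0, s[["lambda_int"]]),
    park_slope = rnorm(npark, 0, s[["lambda_slope"]]),
    re_gamma = matrix(rnorm(npark * (nyear - 1), 0, s[["gamma"]]),
                      npark, nyear - 1),
    re_eps = matrix(rnorm(npark * (nyear - 1), 0, s[["eps"]]),
                    npark, nyear - 1)
  )
}

# Linear predictors for the state process on an encoded array.
dyn_linear_predictors <- function(arr, dynamics, effects) {
  Xl <- cbind(intercept = rep(1, arr$nsite), complexity = arr$complexity)
  lam_lin <- Xl[, "intercept"] * dynamics$lambda[["intercept"]] +
    arr$complexity * dynamics$lambda[["complexity"]] +
    effects$park_int[arr$park] + effects$park_slope[arr$park] * arr$complexity
  Xg <- dyn_design_matrix(arr, dynamics$designs$gamma)
  Xe <- dyn_design_matrix(arr, dynamics$designs$eps)
  g_lin <- matrix(as.vector(Xg %*% dynamics$gamma), arr$nsite, arr$nyear)
  e_lin <- matrix(as.vector(Xe %*% dynamics$eps), arr$nsite, arr$nyear)
  if (arr$nyear > 1) {
    for (t in 2:arr$nyear) {
      g_lin[, t] <- g_lin[, t] + effects$re_gamma[arr$park, t - 1]
      e_lin[, t] <- e_lin[, t] + effects$re_eps[arr$park, t - 1]
    }
  }
  list(psi1 = plogis(lam_lin),
       gamma = plogis(g_lin),  # column t = colonization prob into year t
       eps = plogis(e_lin))
}

#' Simulate the latent occupancy process
#'
#' Draws initial occupancy from the complexity-dependent initial
#' probability and propagates it through the annual
#' colonization/extinction kernel: an occupied site stays occupied with
#' probability 1 - eps, an unoccupied site becomes occupied with
#' probability gamma, both logit-linear in covariates plus park-year
#' random intercepts.
#'
#' @param dynamics A `pika_dynamics_params`.
#' @param shell A `pika_survey` shell (covariates present; standardized
#'   internally if needed).
#' @param effects Optional list of random-effect realizations
#'   (`park_int`, `park_slope`, `re_gamma`, `re_eps`); drawn from their
#'   scale parameters when `NULL`.
#' @return Binary site-by-year matrix `z` with the realized `effects`
#'   attached as an attribute.
#' @export
simulate_occupancy <- function(dynamics, shell, effects = NULL) {
  arr <- if (inherits(shell, "pika_array")) shell else encode_surveys(shell)
  if (is.null(effects)) {
    effects <- draw_dynamics_effects(dynamics, arr$npark, arr$nyear)
  }
  lp <- dyn_linear_predictors(arr, dynamics, effects)
  z <- matrix(0L, arr$nsite, arr$nyear,
              dimnames = list(arr$site_id, as.character(arr$years)))
  z[, 1] <- rbinom(arr$nsite, 1, lp$psi1)
  if (arr$nyear > 1) {
    for (t in 2:arr$nyear) {
      pr <- ifelse(z[, t - 1] == 1L, 1 - lp$eps[, t], lp$gamma[, t])
      z[, t] <- rbinom(arr$nsite, 1, pr)
    }
  }
  attr(z, "effects") <- effects
  z
}

#' Simulate multi-sign detection records given the latent states
#'
#' Realizes the survey design (which park-years are surveyed, which sites
#' are resurveyed, survey seasons) and then draws per-survey, per-sign
#' detections: Bernoulli with the sign's true-detection probability at
#' occupied sites and its false-positive probability at unoccupied sites
#' (zero for sightings). Unambiguous flags arise only from true
#' detections: a fresh-scat detection at an occupied site is unambiguous
#' with probability `p_unambiguous_fs`, or whenever a fresh haypile was
#' truly detected in the same survey; sightings are unambiguous whenever
#' detected. Unoccupied sites never yield unambiguous flags.
#'
#' @param z Binary site-by-year occupancy matrix.
#' @param detection A `pika_detection_params`.
#' @param scenario A `pika_scenario` (survey-design settings).
#' @param shell The covariate shell the scenario generated.
#' @return A `pika_survey` with simulated records (standardized
#'   covariates).
#' @export
simulate_detections <- function(z, detection, scenario, shell) {
  arr <- encode_surveys(shell)
  nsite <- arr$nsite

  # realize survey design: site-years surveyed, resurvey draws, seasons
  sv_list <- list()
  surveyed_idx <- match(scenario$surveyed_years, arr$years)
  for (p in seq_len(arr$npark)) {
    psites <- which(arr$park == p)
    for (t in surveyed_idx) {
      if (runif(1) < scenario$park_skip_prob) next
      season_site <- rbinom(length(psites), 1, scenario$p_fall)
      n_re <- round(scenario$resurvey_fraction * length(psites))
      re_sites <- if (n_re > 0) sample(psites, n_re) else integer(0)
      sv_list[[length(sv_list) + 1]] <- tibble::tibble(
        site = c(psites, re_sites),
        year_idx = t,
        survey_index = c(rep(1L, length(psites)),
                         rep(2L, length(re_sites))),
        season = c(season_site, season_site[match(re_sites, psites)])
      )
    }
  }
  sv <- if (length(sv_list)) bind_rows(sv_list) else
    tibble::tibble(site = integer(), year_idx = integer(),
                   survey_index = integer(), season = integer())
  sv <- arrange(sv, .data$site, .data$year_idx, .data$survey_index)
  sv$period <- as.numeric(arr$years[sv$year_idx] >= 2017)

  # per-survey design covariates
  tmp_arr <- arr
  tmp_arr$surveys <- tibble::tibble(site = sv$site, year_idx = sv$year_idx,
                                    survey_index = sv$survey_index,
                                    season = as.numeric(sv$season),
                                    period = sv$period)
  n_surv <- nrow(sv)
  zz <- z[cbind(sv$site, sv$year_idx)]
  y <- matrix(0L, n_surv, 4, dimnames = list(NULL, SIGN_CODES))
  u <- y
  for (k in seq_along(SIGN_CODES)) {
    s <- SIGN_CODES[k]
    Xp <- obs_design_matrix(tmp_arr, detection$designs$p[[s]])
    p1 <- plogis(as.vector(Xp %*% detection$beta[[s]]))
    cols_fp <- detection$designs$fp[[s]]
    p0 <- if (length(cols_fp) == 0) rep(0, n_surv) else
      plogis(as.vector(obs_design_matrix(tmp_arr, cols_fp) %*%
                         detection$beta_fp[[s]]))
    pd <- ifelse(zz == 1L, p1, p0)
    y[, k] <- rbinom(n_surv, 1, pd)
  }
  # ambiguity flags: only true detections can be unambiguous
  note_unamb <- rbinom(n_surv, 1, scenario$p_unambiguous_fs)
  u[, "FS"] <- as.integer(y[, "FS"] == 1L & zz == 1L &
                            (note_unamb == 1L | y[, "FH"] == 1L))
  u[, "PS"] <- y[, "PS"]  # PS only ever detected at occupied sites

  rec <- tibble::tibble(
    site_id = arr$site_id[sv$site],
    park_id = arr$park_levels[arr$park[sv$site]],
    year = arr$years[sv$year_idx],
    survey_index = sv$survey_index,
    season = as.integer(sv$season),
    survey_period = as.integer(sv$period),
    det_fs = y[, "FS"], det_fh = y[, "FH"], det_pc = y[, "PC"],
    det_ps = y[, "PS"],
    unamb_fs = u[, "FS"], unamb_fh = 0L, unamb_pc = 0L, unamb_ps = u[, "PS"]
  )
  out <- shell
  out$records <- rec
  out
}

#' Simulate a complete multi-sign survey dataset
#'
#' End-to-end generator: covariates, latent occupancy, survey design and
#' detections, fully determined by `scenario$seed`. The returned object
#' carries the simulated dataset together with the generating truth
#' (latent states, parameters and realized random effects) for
#' parameter-recovery scoring.
#'
#' @param scenario A `pika_scenario`.
#' @return Object of class `pika_sim`: list with `data` (a preprocessed
#'   `pika_survey`), `z` (true occupancy matrix), `effects` (realized
#'   random effects), `detection`, `dynamics` and `scenario`.
#' @export
#' @examples
#' sim <- simulate_surveys(sim_scenario(n_parks = 2, sites_per_park = 10,
#'                                      years = 2018:2021,
#'                                      surveyed_years = 2018:2021,
#'                                      seed = 42))
#' sim$data
simulate_surveys <- function(scenario) {
  stopifnot(inherits(scenario, "pika_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  shell <- simulate_covariates(scenario)
  shell <- preprocess_covariates(shell)
  z <- simulate_occupancy(scenario$dynamics, shell)
  data <- simulate_detections(z, scenario$detection, scenario, shell)
  structure(
    list(data = data, z = `attr<-`(z, "effects", NULL),
         effects = attr(z, "effects"),
         detection = scenario$detection, dynamics = scenario$dynamics,
         scenario = scenario),
    class = "pika_sim"
  )
}

#' @export
print.pika_sim <- function(x, ...) {
  cat("<pika_sim> seed ", x$scenario$seed, ": ", sep = "")
  print(x$data)
  invisible(x)
}
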