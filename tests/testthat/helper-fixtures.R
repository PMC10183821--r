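# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; nothing is read from disk except files the tests
# write themselves.

# A tiny hand-built survey dataset: 2 parks, 3 sites, 3 modeled years
# (middle year unsurveyed at site A1), with one resurvey and a mix of
# ambiguous/unambiguous detections.
tiny_records <- function() {
  tibble::tribble(
    ~site_id, ~park_id, ~year, ~survey_index, ~season, ~survey_period,
    ~det_fs, ~det_fh, ~det_pc, ~det_ps, ~unamb_fs, ~unamb_fh, ~unamb_pc,
    ~unamb_ps,
    "A1", "PA", 2018L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L,
    "A1", "PA", 2018L, 2L, 0L, 1L, 1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L,
    "A1", "PA", 2020L, 1L, 1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L,
    "A2", "PA", 2018L, 1L, 0L, 1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L,
    "A2", "PA", 2019L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
    "B1", "PB", 2019L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L
  )
}

tiny_sites <- function() {
  tibble::tibble(
    site_id = c("A1", "A2", "B1"),
    park_id = c("PA", "PA", "PB"),
    forb = c(10, 20, 30), rock = c(55, 60, 80), shrub = c(5, 12, 9),
    complexity = c("low", "high", "intermediate")
  )
}

tiny_climate <- function(years = 2018:2020) {
  grid <- expand.grid(site_id = c("A1", "A2", "B1"), year = years,
                      stringsAsFactors = FALSE)
  grid$tmaxmean <- 20 + seq_len(nrow(grid)) * 0.5
  grid$precip <- 800 + seq_len(nrow(grid)) * 25
  tibble::as_tibble(grid)
}

tiny_survey <- function() {
  survey_data(tiny_records(), tiny_sites(), tiny_climate(),
              years = 2018:2020)
}

# Long observation-format CSV fixture written to a temp dir; returns the
# three file paths.
write_obs_fixture <- function(dir = NULL, obs = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  if (is.null(obs)) {
    obs <- tibble::tribble(
      ~site_id, ~park_id, ~year, ~survey_index, ~season, ~survey_period,
      ~sign_code, ~count, ~notes,
      "A1", "PA", 2018L, 1L, 0L, 1L, "FS", 2L, "scat stacked in small tower",
      "A1", "PA", 2018L, 1L, 0L, 1L, "FS", 1L, "",
      "A1", "PA", 2018L, 1L, 0L, 1L, "FS", 1L, "loose pellets",
      "A1", "PA", 2020L, 1L, 1L, 1L, "PC", 1L, "call NE corner",
      "A2", "PA", 2018L, 1L, 0L, 1L, "PS", 1L, "adult seen",
      "B1", "PB", 2019L, 1L, 1L, 1L, "FS", 1L, "",
      "B1", "PB", 2019L, 1L, 1L, 1L, "FH", 1L, "fresh haypile under ledge"
    )
  }
  fo <- file.path(dir, "observations.csv")
  readr::write_csv(obs, fo)
  fs <- file.path(dir, "sites.csv")
  st <- tiny_sites()
  names(st) <- c("site_id", "park_id", "forb_pct", "rock_pct", "shrub_pct",
                 "complexity")
  readr::write_csv(st, fs)
  fc <- file.path(dir, "climate.csv")
  cl <- tiny_climate()
  names(cl) <- c("site_id", "year", "tmaxmean_c", "precip_mm")
  readr::write_csv(cl, fc)
  list(obs = fo, sites = fs, climate = fc, dir = dir)
}

# Independent brute-force oracle for the marginal site likelihood:
# enumerates all 2^T latent sequences and sums their joint probabilities,
# computing every term from first principles (plogis / dbinom only).
enum_site_loglik <- function(arr, site, detection, dynamics, effects,
                             variant = "full") {
  T <- arr$nyear
  pk <- arr$park[site]
  psi1 <- plogis(dynamics$lambda[["intercept"]] +
                   dynamics$lambda[["complexity"]] * arr$complexity[site] +
                   effects$park_int[pk] +
                   effects$park_slope[pk] * arr$complexity[site])
  dyn_x <- function(cols, t) {
    vals <- c(intercept = 1, forb = arr$forb[site], rock = arr$rock[site],
              shrub = arr$shrub[site], complexity = arr$complexity[site],
              tmaxmean = arr$tmax[site, t], precip = arr$precip[site, t])
    vals[cols]
  }
  gam <- sapply(seq_len(T), function(t) {
    if (t == 1) return(NA)
    plogis(sum(dyn_x(dynamics$designs$gamma, t) * dynamics$gamma) +
             effects$re_gamma[pk, t - 1])
  })
  eps <- sapply(seq_len(T), function(t) {
    if (t == 1) return(NA)
    plogis(sum(dyn_x(dynamics$designs$eps, t) * dynamics$eps) +
             effects$re_eps[pk, t - 1])
  })
  rows <- which(arr$surveys$site == site)

  obs_prob <- function(t, z) {
    jt <- rows[arr$surveys$year_idx[rows] == t]
    if (length(jt) == 0) return(1)
    pr <- 1
    for (j in jt) {
      xv <- c(intercept = 1, season = arr$surveys$season[j],
              period = arr$surveys$period[j],
              complexity = arr$complexity[site], forb = arr$forb[site])
      if (variant == "perfect") next
      for (s in names(detection$beta)) {
        k <- match(s, colnames(arr$y))
        y <- arr$y[j, k]
        u <- arr$u[j, k]
        p1 <- plogis(sum(xv[detection$designs$p[[s]]] * detection$beta[[s]]))
        cols <- detection$designs$fp[[s]]
        p0 <- if (variant != "full" || length(cols) == 0 || u == 1) 0 else
          plogis(sum(xv[cols] * detection$beta_fp[[s]]))
        pd <- if (z == 1) p1 else p0
        pr <- pr * dbinom(y, 1, pd)
      }
    }
    pr
  }
  perfect_prob <- function(t, z) {
    jt <- rows[arr$surveys$year_idx[rows] == t]
    if (length(jt) == 0) return(1)
    any_det <- as.integer(any(arr$y[jt, , drop = FALSE] == 1))
    as.numeric(any_det == z)
  }
  emit <- if (variant == "perfect") perfect_prob else obs_prob

  total <- 0
  for (code in 0:(2^T - 1)) {
    zseq <- as.integer(intToBits(code))[seq_len(T)]
    pr <- if (zseq[1] == 1) psi1 else 1 - psi1
    pr <- pr * emit(1, zseq[1])
    if (T > 1) {
      for (t in 2:T) {
        ptrans <- if (zseq[t - 1] == 1) 1 - eps[t] else gam[t]
        pr <- pr * (if (zseq[t] == 1) ptrans else 1 - ptrans) * emit(t, zseq[t])
      }
    }
    total <- total + pr
  }
  unname(log(total))
}

zero_effects <- function(npark, nyear) {
  list(park_int = rep(0, npark), park_slope = rep(0, npark),
       re_gamma = matrix(0, npark, max(nyear - 1, 0)),
       re_eps = matrix(0, npark, max(nyear - 1, 0)))
}

# Random small datasets + parameters for the oracle-equivalence property.
random_case <- function(T = sample(1:6, 1), nsurv_max = 2) {
  nsite <- 2
  years <- 2000 + seq_len(T)
  rec <- list()
  for (i in seq_len(nsite)) {
    for (t in seq_len(T)) {
      ns <- sample(0:nsurv_max, 1)
      for (k in seq_len(ns)) {
        y <- rbinom(4, 1, 0.4)
        u <- c(y[1] * rbinom(1, 1, 0.5), 0L, 0L, y[4])
        rec[[length(rec) + 1]] <- tibble::tibble(
          site_id = paste0("S", i), park_id = "P1", year = years[t],
          survey_index = k, season = rbinom(1, 1, 0.5),
          survey_period = rbinom(1, 1, 0.5),
          det_fs = y[1], det_fh = y[2], det_pc = y[3], det_ps = y[4],
          unamb_fs = u[1], unamb_fh = 0L, unamb_pc = 0L, unamb_ps = u[4]
        )
      }
    }
  }
  rec <- if (length(rec)) dplyr::bind_rows(rec) else tiny_records()[0, ]
  sites <- tibble::tibble(
    site_id = paste0("S", seq_len(nsite)), park_id = "P1",
    forb = runif(nsite, 5, 60), rock = runif(nsite, 20, 90),
    shrub = runif(nsite, 1, 30),
    complexity = sample(c("low", "intermediate", "high"), nsite, TRUE)
  )
  clim <- expand.grid(site_id = sites$site_id, year = years,
                      stringsAsFactors = FALSE)
  clim$tmaxmean <- runif(nrow(clim), 15, 30)
  clim$precip <- runif(nrow(clim), 100, 4000)
  sd <- survey_data(rec, sites, tibble::as_tibble(clim), years = years)
  arr <- suppressWarnings(encode_surveys(sd))

  detection <- detection_params(
    beta = list(FS = rnorm(2, 0, 1.2), FH = rnorm(3, 0, 1.2),
                PC = rnorm(3, 0, 1.2), PS = rnorm(3, 0, 1.2)),
    beta_fp = list(FS = rnorm(2, -1, 1), FH = rnorm(2, -1, 1),
                   PC = rnorm(3, -1, 1), PS = numeric(0))
  )
  dynamics <- dynamics_params(
    lambda = rnorm(2, 0, 1), gamma = rnorm(3, -1, 1), eps = rnorm(2, -1, 1),
    sigma = c(lambda_int = 1, lambda_slope = 0.5, gamma = 0.6, eps = 0.6)
  )
  effects <- list(
    park_int = rnorm(1, 0, 1), park_slope = rnorm(1, 0, 0.5),
    re_gamma = matrix(rnorm(max(T - 1, 0), 0, 0.6), 1),
    re_eps = matrix(rnorm(max(T - 1, 0), 0, 0.6), 1)
  )
  list(arr = arr, detection = detection, dynamics = dynamics,
       effects = effects)
}

# Reduced-scale recovery scenario used by the acceptance experiments:
# three parks of 40 sites over 2014-2021 with a two-year survey gap,
# generating values at the defaults (the fitted model's posterior
# operating point).
recovery_scenario <- function(seed) {
  sim_scenario(n_parks = 3, sites_per_park = 40, years = 2014:2021,
               surveyed_years = c(2014, 2017:2021), park_skip_prob = 0.05,
               seed = seed)
}

# Generating values in the sampler's parameter naming, for recovery
# scoring.
truth_vector <- function(sim) {
  det <- sim$detection
  dyn <- sim$dynamics
  v <- c()
  for (s in names(det$beta)) {
    x <- det$beta[[s]]
    names(x) <- paste0("beta_", tolower(s), "_", names(x))
    v <- c(v, x)
  }
  for (s in names(det$beta_fp)) {
    x <- det$beta_fp[[s]]
    if (length(x)) {
      names(x) <- paste0("beta_", tolower(s), "_xi_", names(x))
      v <- c(v, x)
    }
  }
  lam <- dyn$lambda
  names(lam) <- paste0("alpha_lam_", names(lam))
  g <- dyn$gamma
  names(g) <- paste0("alpha_gam_", names(g))
  e <- dyn$eps
  names(e) <- paste0("alpha_eps_", names(e))
  s <- dyn$sigma
  names(s) <- c("sigma_lam_int", "sigma_lam_slope", "sigma_gam", "sigma_eps")
  c(v, lam, g, e, s)
}

# Minimal fit-like object for summary-level tests that only need latent
# draws (and optionally parameter draws).
fake_fit <- function(arr, z_draws, draws = NULL, chain = NULL,
                     variant = "full") {
  n <- nrow(z_draws)
  if (is.null(draws)) draws <- matrix(0, n, 0)
  if (is.null(chain)) chain <- rep(1L, nrow(draws))
  structure(
    list(draws = draws, chain = chain, z_draws = z_draws,
         z_chain = rep(1L, n), z_index = seq_len(n),
         rhat = setNames(rep(1, ncol(draws)), colnames(draws)),
         arr = arr, variant = variant,
         dyn_designs = default_dyn_designs(),
         config = sampler_config(),
         fingerprint = c(arr$nsite, arr$nyear, nrow(arr$surveys),
                         sum(arr$y), sum(arr$u))),
    class = "pika_fit"
  )
}
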