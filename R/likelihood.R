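#' Per-sign true-detection probability
#'
#' Inverse-logit of the sign's linear predictor, `logit(p) = x' beta`.
#'
#' @param sign Sign code (`"FS"`, `"FH"`, `"PC"`, `"PS"`).
#' @param x Numeric covariate vector (or matrix, rows = observations)
#'   matching the sign's true-detection design.
#' @param params A `pika_detection_params`.
#' @return Probability in (0, 1) (vector if `x` is a matrix).
#' @export
#' @examples
#' p <- default_detection_params()
#' p_detect("FH", c(intercept = 0, complexity = 0, forb = 1),
#'          detection_params(beta = list(FH = c(0, 0, 0.336)),
#'                           designs = list(p = list(FH = c("intercept",
#'                             "complexity", "forb")),
#'                             fp = list(FH = character(0)))))
p_detect <- function(sign, x, params) {
  beta <- params$beta[[sign]]
  if (is.null(beta)) abort(paste0("no true-detection design for sign ", sign))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != length(beta)) {
    abort(paste0("covariate vector has length ", ncol(x),
                 " but the ", sign, " design has ", length(beta)))
  }
  drop(plogis(x %*% beta))
}

#' Per-sign false-positive probability
#'
#' Inverse-logit of the sign's false-positive linear predictor, with the
#' structural zeros of the model: an unambiguous observation has
#' false-detection probability 0, and an always-unambiguous sign type
#' (pika sightings) has false-detection probability 0 everywhere.
#'
#' @inheritParams p_detect
#' @param unambiguous Binary flag; 1 forces the probability to 0.
#' @return Probability in \[0, 1).
#' @export
p_false <- function(sign, x, params, unambiguous = 0) {
  if (unambiguous == 1) return(0)
  beta <- params$beta_fp[[sign]]
  if (is.null(beta) || length(beta) == 0) return(0)
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != length(beta)) {
    abort(paste0("covariate vector has length ", ncol(x),
                 " but the ", sign, " false-positive design has ",
                 length(beta)))
  }
  drop(plogis(x %*% beta))
}

#' Annual transition probability of the latent state
#'
#' Probability that a site is occupied in year t given its state in year
#' t-1: `1 - eps` if previously occupied, `gamma` if previously empty.
#'
#' @param z_prev Binary previous state.
#' @param gamma Colonization probability.
#' @param eps Extinction probability.
#' @return Probability of occupancy at t.
#' @export
transition_prob <- function(z_prev, gamma, eps) {
  stopifnot(gamma >= 0, gamma <= 1, eps >= 0, eps <= 1)
  ifelse(z_prev == 1, 1 - eps, gamma)
}

#' Log-likelihood of one survey's multi-sign observations
#'
#' Sum over sign types of the Bernoulli log-mass of each binary detection,
#' with success probability equal to the sign's true-detection probability
#' at an occupied site and its false-positive probability at an unoccupied
#' site. A detection flagged unambiguous contributes `log p` if the site
#' is occupied and log 0 (i.e. `-Inf`) if not: unambiguous detections
#' annihilate the unoccupied branch. Sign types are conditionally
#' independent given the latent state.
#'
#' @param y Named binary detection vector over sign codes.
#' @param u Named binary unambiguous-flag vector (must satisfy `u <= y`).
#' @param z Binary occupancy state of the site-year.
#' @param x Named per-survey covariate values (`season`, `period`,
#'   `complexity`, `forb`; intercept added automatically).
#' @param params A `pika_detection_params`.
#' @param variant Model variant code (see [model_variants()]).
#' @return Log-probability (may be `-Inf`).
#' @export
survey_loglik <- function(y, u, z, x, params, variant = "full") {
  variant <- match.arg(variant, c("full", "nofp", "standard"))
  if (any(u > y)) {
    abort("unambiguous flag set for an undetected sign (u > y)",
          class = "pika_integrity_error")
  }
  xfull <- c(intercept = 1, x)
  signs <- names(params$beta)
  ll <- 0
  for (s in signs) {
    ys <- y[[s]]
    us <- if (s %in% names(u)) u[[s]] else 0
    p1 <- p_detect(s, xfull[params$designs$p[[s]]], params)
    p0 <- if (variant == "full") {
      p_false(s, xfull[params$designs$fp[[s]]], params, unambiguous = us)
    } else 0
    pd <- if (z == 1) p1 else p0
    ll <- ll + stats::dbinom(ys, 1, pd, log = TRUE)
  }
  unname(ll)
}

# Per-site-year emission probabilities P(all surveys' obs | z) on the
# probability scale: matrices e1, e0 (nsite x nyear), 1 where unsurveyed.
emission_probs <- function(arr, detection, variant = "full") {
  nsv <- nrow(arr$surveys)
  e1 <- matrix(1, arr$nsite, max(arr$nyear, 1))
  e0 <- e1
  if (nsv == 0 || arr$nyear == 0) return(list(e1 = e1, e0 = e0))

  if (variant == "standard") {
    yany <- as.integer(rowSums(arr$y) > 0)
    Xp <- obs_design_matrix(arr, detection$designs$p[["ANY"]])
    p1 <- plogis(as.vector(Xp %*% detection$beta[["ANY"]]))
    f1 <- ifelse(yany == 1L, p1, 1 - p1)
    f0 <- ifelse(yany == 1L, 0, 1)
  } else {
    f1 <- rep(1, nsv)
    f0 <- rep(1, nsv)
    for (s in names(detection$beta)) {
      k <- match(s, colnames(arr$y))
      Xp <- obs_design_matrix(arr, detection$designs$p[[s]])
      p1 <- plogis(as.vector(Xp %*% detection$beta[[s]]))
      cols_fp <- detection$designs$fp[[s]]
      p0 <- if (variant == "nofp" || length(cols_fp) == 0) rep(0, nsv) else
        plogis(as.vector(obs_design_matrix(arr, cols_fp) %*%
                           detection$beta_fp[[s]]))
      p0[arr$u[, k] == 1L] <- 0  # unambiguous: no false-positive mass
      ys <- arr$y[, k]
      f1 <- f1 * ifelse(ys == 1L, p1, 1 - p1)
      f0 <- f0 * ifelse(ys == 1L, p0, 1 - p0)
    }
  }
  for (j in seq_len(nsv)) {
    i <- arr$surveys$site[j]
    t <- arr$surveys$year_idx[j]
    e1[i, t] <- e1[i, t] * f1[j]
    e0[i, t] <- e0[i, t] * f0[j]
  }
  list(e1 = e1, e0 = e0)
}

# Two-state forward recursion on the probability scale with per-step
# normalization; returns the site's marginal log-likelihood.
forward_loglik <- function(e1, e0, psi1, gamma, eps) {
  T <- length(e1)
  a1 <- psi1 * e1[1]
  a0 <- (1 - psi1) * e0[1]
  ll <- 0
  c1 <- a1 + a0
  if (c1 <= 0) return(-Inf)
  ll <- ll + log(c1)
  a1 <- a1 / c1
  a0 <- a0 / c1
  if (T > 1) {
    for (t in 2:T) {
      n1 <- (a0 * gamma[t] + a1 * (1 - eps[t])) * e1[t]
      n0 <- (a0 * (1 - gamma[t]) + a1 * eps[t]) * e0[t]
      ct <- n1 + n0
      if (ct <= 0) return(-Inf)
      ll <- ll + log(ct)
      a1 <- n1 / ct
      a0 <- n0 / ct
    }
  }
  ll
}

#' Marginal log-likelihood of one site's detection history
#'
#' Marginalizes the latent annual occupancy sequence out of the joint
#' probability of a site's multi-sign detection history by a two-state
#' forward recursion: the filter over (occupied, unoccupied) is
#' initialized with the initial-occupancy probability, propagated through
#' the annual colonization/extinction kernel, and multiplied by the
#' product of per-survey emission likelihoods in surveyed years
#' (unsurveyed years contribute emission 1). Equals the log of the sum
#' over all `2^T` latent sequences.
#'
#' @param arr A `pika_array`.
#' @param site Site index (1-based, in array order).
#' @param detection A `pika_detection_params` (ignored for the
#'   perfect-detection variant).
#' @param dynamics A `pika_dynamics_params`.
#' @param effects Random-effect realizations as in [simulate_occupancy()];
#'   zero effects when `NULL`.
#' @param variant One of `"full"`, `"nofp"`, `"standard"`, `"perfect"`.
#' @return Log-likelihood (scalar; `-Inf` if the data are impossible
#'   under the parameters).
#' @export
site_loglik_marginal <- function(arr, site, detection, dynamics,
                                 effects = NULL, variant = "full") {
  variant <- match.arg(variant, c("full", "nofp", "standard", "perfect"))
  if (is.null(effects)) {
    effects <- list(park_int = rep(0, arr$npark),
                    park_slope = rep(0, arr$npark),
                    re_gamma = matrix(0, arr$npark, max(arr$nyear - 1, 0)),
                    re_eps = matrix(0, arr$npark, max(arr$nyear - 1, 0)))
  }
  lp <- dyn_linear_predictors(arr, dynamics, effects)
  em <- if (variant == "perfect") perfect_emissions(arr) else
    emission_probs(arr, detection, variant)
  if (any(!is.finite(c(lp$psi1[site], lp$gamma[site, ], lp$eps[site, ])))) {
    abort("non-finite covariate or linear predictor for site")
  }
  forward_loglik(em$e1[site, ], em$e0[site, ], lp$psi1[site],
                 lp$gamma[site, ], lp$eps[site, ])
}

# Perfect-detection emissions: a surveyed site-year pins the state to the
# observed any-sign indicator, with replicate surveys OR-ed together (a
# detection in any survey of the year implies occupancy); unsurveyed years
# stay latent.
perfect_emissions <- function(arr) {
  e1 <- matrix(1, arr$nsite, max(arr$nyear, 1))
  e0 <- e1
  if (nrow(arr$surveys) > 0) {
    yany <- as.integer(rowSums(arr$y) > 0)
    pin <- matrix(-1L, arr$nsite, arr$nyear)
    for (j in seq_len(nrow(arr$surveys))) {
      i <- arr$surveys$site[j]
      t <- arr$surveys$year_idx[j]
      pin[i, t] <- max(pin[i, t], yany[j])
    }
    e0[pin == 1L] <- 0
    e1[pin == 0L] <- 0
  }
  list(e1 = e1, e0 = e0)
}

#' Total marginal log-likelihood of a dataset
#'
#' Sum of [site_loglik_marginal()] over all sites.
#'
#' @inheritParams site_loglik_marginal
#' @return Scalar log-likelihood.
#' @export
loglik_total <- function(arr, detection, dynamics, effects = NULL,
                         variant = "full") {
  variant <- match.arg(variant, c("full", "nofp", "standard", "perfect"))
  if (arr$nsite == 0) return(0)
  vapply(seq_len(arr$nsite), function(i) {
    site_loglik_marginal(arr, i, detection, dynamics, effects, variant)
  }, numeric(1)) |> sum()
}
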