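#' Finite-sample occupancy rates per park and year
#'
#' For each stored posterior draw of the latent states, the fraction of
#' monitored sites (sites with at least one survey in that park-year)
#' whose drawn state is occupied; summarized as the posterior mean, the
#' posterior variance and an equal-tailed credible interval. Park-years
#' with no monitored sites are excluded (with a message).
#'
#' @param fit A `pika_fit`.
#' @param level Credible-interval level (default 0.9).
#' @param monitored_only Restrict the denominator to sites surveyed in
#'   that year (default `TRUE`); otherwise all modeled sites count.
#' @return A tibble of class `pika_occupancy`: `park_id`, `year`, `mean`,
#'   `var`, `lo`, `hi`, `n_sites`.
#' @export
occupancy_rates <- function(fit, level = 0.9, monitored_only = TRUE) {
  stopifnot(inherits(fit, "pika_fit"))
  arr <- fit$arr
  a <- (1 - level) / 2
  sv <- arr$surveys
  out <- list()
  skipped <- 0
  for (p in seq_len(arr$npark)) {
    psites <- which(arr$park == p)
    for (t in seq_len(arr$nyear)) {
      mon <- if (monitored_only) {
        intersect(psites, unique(sv$site[sv$year_idx == t]))
      } else psites
      if (length(mon) == 0) { skipped <- skipped + 1; next }
      zcols <- mon + arr$nsite * (t - 1)
      fr <- rowMeans(fit$z_draws[, zcols, drop = FALSE])
      out[[length(out) + 1]] <- tibble::tibble(
        park_id = arr$park_levels[p], year = arr$years[t],
        mean = mean(fr), var = var(fr),
        lo = unname(quantile(fr, a)), hi = unname(quantile(fr, 1 - a)),
        n_sites = length(mon)
      )
    }
  }
  if (skipped > 0) {
    message(skipped, " park-year(s) without monitored sites excluded")
  }
  res <- bind_rows(out)
  class(res) <- c("pika_occupancy", class(res))
  res
}

#' Inverse-variance weighted occupancy trends per park
#'
#' Weighted least-squares regression of the park's posterior-mean
#' occupancy rate on calendar year, one model per park, with weights
#' equal to the inverse posterior variance of each estimate, so that
#' well-determined years dominate the trend. Significance is the slope's
#' t-test at `alpha` (default 0.1).
#'
#' @param series A `pika_occupancy` tibble from [occupancy_rates()].
#' @param alpha Significance level for flagging trends.
#' @return A tibble: `park_id`, `slope`, `se`, `p_value`, `significant`,
#'   `n_years`.
#' @export
trend_regression <- function(series, alpha = 0.1) {
  stopifnot(all(c("park_id", "year", "mean", "var") %in% names(series)))
  purrr::map_dfr(split(series, series$park_id), function(d) {
    if (nrow(d) < 3) {
      abort(paste0("park ", d$park_id[1], " has fewer than 3 surveyed ",
                   "years; trend regression needs at least 3"),
            class = "pika_insufficient_data_error")
    }
    w <- 1 / pmax(d$var, 1e-12)
    m <- lm(mean ~ year, data = d, weights = w)
    sm <- summary(m)$coefficients
    tibble::tibble(
      park_id = d$park_id[1],
      slope = sm["year", "Estimate"],
      se = sm["year", "Std. Error"],
      p_value = sm["year", "Pr(>|t|)"],
      significant = sm["year", "Pr(>|t|)"] < alpha,
      n_years = nrow(d)
    )
  })
}

#' Sign-specific detection-rate table conditional on drawn occupancy
#'
#' Reconstructs the empirical true- and false-positive detection rates
#' from the raw detections and the posterior of the latent states: for
#' each stored draw, each survey is classified occupied or unoccupied by
#' the drawn state of its site-year, and the per-sign detection
#' frequencies are accumulated separately over the two classes (each
#' survey counting equally, i.e. averages are weighted by survey). The
#' overall rate is the frequency of at least one sign detected. Rates are
#' averaged over draws, per park and pooled (`AVG` row). Variants without
#' false positives report structurally zero false-positive columns.
#'
#' @param fit A `pika_fit` with an observation model (`full`, `nofp` or
#'   `standard`).
#' @return A tibble with one row per park plus `AVG`: `true_overall`,
#'   `true_<sign>`, `fp_overall`, `fp_<sign>` columns.
#' @export
detection_rate_table <- function(fit) {
  stopifnot(inherits(fit, "pika_fit"))
  if (fit$variant == "perfect") {
    abort("the perfect-detection variant has no observation process")
  }
  arr <- fit$arr
  sv <- arr$surveys
  if (nrow(sv) == 0) abort("no surveys in the fitted data")
  signs <- colnames(arr$y)
  yany <- as.integer(rowSums(arr$y) > 0)
  nz <- nrow(fit$z_draws)
  park_of <- arr$park[sv$site]
  groups <- c(arr$park_levels, "AVG")

  acc <- array(0, dim = c(length(groups), length(signs) + 1, 2),
               dimnames = list(groups, c("overall", signs), c("true", "fp")))
  cnt <- acc
  for (d in seq_len(nz)) {
    zz <- fit$z_draws[d, sv$site + arr$nsite * (sv$year_idx - 1)]
    for (gi in seq_along(groups)) {
      in_g <- if (groups[gi] == "AVG") rep(TRUE, nrow(sv)) else
        park_of == gi
      occ <- in_g & zz == 1
      emp <- in_g & zz == 0
      if (any(occ)) {
        acc[gi, "overall", "true"] <- acc[gi, "overall", "true"] + mean(yany[occ])
        cnt[gi, "overall", "true"] <- cnt[gi, "overall", "true"] + 1
        for (s in signs) {
          k <- match(s, signs)
          acc[gi, s, "true"] <- acc[gi, s, "true"] + mean(arr$y[occ, k])
          cnt[gi, s, "true"] <- cnt[gi, s, "true"] + 1
        }
      }
      if (any(emp)) {
        acc[gi, "overall", "fp"] <- acc[gi, "overall", "fp"] + mean(yany[emp])
        cnt[gi, "overall", "fp"] <- cnt[gi, "overall", "fp"] + 1
        for (s in signs) {
          k <- match(s, signs)
          acc[gi, s, "fp"] <- acc[gi, s, "fp"] + mean(arr$y[emp, k])
          cnt[gi, s, "fp"] <- cnt[gi, s, "fp"] + 1
        }
      }
    }
  }
  rate <- acc / ifelse(cnt > 0, cnt, NA)
  if (fit$variant %in% c("nofp", "standard")) rate[, , "fp"] <- 0
  out <- tibble::tibble(park_id = groups)
  for (s in c("overall", signs)) {
    out[[paste0("true_", tolower(s))]] <- rate[, s, "true"]
  }
  for (s in c("overall", signs)) {
    out[[paste0("fp_", tolower(s))]] <- rate[, s, "fp"]
  }
  out
}

# Posterior draws of site-year averaged colonization/extinction
# probabilities, evaluated at the stored-z draw indices to bound cost.
dyn_rate_draws <- function(fit) {
  arr <- fit$arr
  Xg <- dyn_design_matrix(arr, fit$dyn_designs$gamma)
  Xe <- dyn_design_matrix(arr, fit$dyn_designs$eps)
  gnm <- paste0("alpha_gam_", fit$dyn_designs$gamma)
  enm <- paste0("alpha_eps_", fit$dyn_designs$eps)
  trans_rows <- which(rep(seq_len(arr$nyear), each = arr$nsite) > 1)
  park_rep <- rep(arr$park, arr$nyear)[trans_rows]
  year_rep <- rep(seq_len(arr$nyear), each = arr$nsite)[trans_rows] - 1L
  gm <- em <- numeric(0)
  for (d in seq_len(nrow(fit$z_draws))) {
    di <- which(fit$chain == fit$z_chain[d])[fit$z_index[d]]
    reg <- matrix(fit$draws[di, grep("^re_gam_", colnames(fit$draws))],
                  arr$npark)
    ree <- matrix(fit$draws[di, grep("^re_eps_", colnames(fit$draws))],
                  arr$npark)
    glin <- as.vector(Xg[trans_rows, , drop = FALSE] %*%
                        fit$draws[di, gnm]) +
      reg[cbind(park_rep, year_rep)]
    elin <- as.vector(Xe[trans_rows, , drop = FALSE] %*%
                        fit$draws[di, enm]) +
      ree[cbind(park_rep, year_rep)]
    gm <- c(gm, mean(plogis(glin)))
    em <- c(em, mean(plogis(elin)))
  }
  list(gamma = gm, eps = em)
}

#' Between-park correlation of annual process variation
#'
#' Pearson correlation, across transition years, of the posterior-mean
#' park-year random intercepts of the colonization and extinction
#' processes, for every pair of parks. High positive values mean two
#' parks' annual deviations rise and fall together.
#'
#' @param fit A `pika_fit`.
#' @return A tibble: `process`, `park_a`, `park_b`, `correlation`
#'   (`NA` when fewer than 3 shared years).
#' @export
process_correlations <- function(fit) {
  stopifnot(inherits(fit, "pika_fit"))
  arr <- fit$arr
  out <- list()
  for (proc in c("gam", "eps")) {
    cols <- grep(paste0("^re_", proc, "_"), colnames(fit$draws), value = TRUE)
    if (length(cols) == 0) next
    eff <- matrix(colMeans(fit$draws[, cols, drop = FALSE]), arr$npark)
    for (a in seq_len(arr$npark - 1)) {
      for (b in (a + 1):arr$npark) {
        r <- if (ncol(eff) < 3) NA_real_ else cor(eff[a, ], eff[b, ])
        out[[length(out) + 1]] <- tibble::tibble(
          process = if (proc == "gam") "colonization" else "extinction",
          park_a = arr$park_levels[a], park_b = arr$park_levels[b],
          correlation = r
        )
      }
    }
  }
  bind_rows(out)
}

#' Compare posterior summaries across observation-model variants
#'
#' One row per fitted variant: posterior-mean initial occupancy (the
#' finite-sample fraction of sites occupied in the first modeled year),
#' mean annual colonization and extinction rates (both the posterior mean
#' of site-year averaged probabilities and the realized turnover of the
#' latent states, see [turnover_rates()]), random-effect scale summaries, and
#' the standard deviation of the park-year occupancy-rate surface. All
#' fits must be to the same dataset.
#'
#' @param fits Named list of `pika_fit` objects (names = variant labels).
#' @return A tibble with one row per variant.
#' @export
compare_variants <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "pika_fit")))
  fps <- vapply(fits, function(f) paste(f$fingerprint, collapse = "/"), "")
  if (length(unique(fps)) != 1) {
    abort("variant fits were made on different datasets (fingerprint mismatch)")
  }
  purrr::map_dfr(fits, function(f) {
    z1 <- rowMeans(f$z_draws[, seq_len(f$arr$nsite), drop = FALSE])
    rates <- dyn_rate_draws(f)
    turn <- turnover_rates(f)
    occ <- occupancy_rates(f)
    tibble::tibble(
      variant = f$variant,
      initial_occupancy = mean(z1),
      colonization = mean(rates$gamma),
      extinction = mean(rates$eps),
      colonization_realized = turn$mean[1],
      extinction_realized = turn$mean[2],
      mu_sigma_lambda = mean(f$draws[, "sigma_lam_int"]),
      mu_sigma_gamma = mean(f$draws[, "sigma_gam"]),
      mu_sigma_eps = mean(f$draws[, "sigma_eps"]),
      sd_frac_occupied = sd(occ$mean)
    )
  })
}

#' Posterior realized colonization and extinction rates
#'
#' Finite-sample annual turnover: for each stored draw of the latent
#' states, the fraction of site-year transitions out of unoccupied that
#' end occupied (colonization) and out of occupied that end unoccupied
#' (extinction), pooled over all sites and transition years; summarized
#' by the posterior mean and an equal-tailed credible interval. Unlike
#' the site-year average of the model's transition probabilities, this is
#' a property of the realized state sequence, so it weights each site by
#' its actual exposure.
#'
#' @param fit A `pika_fit`.
#' @param level Credible-interval level (default 0.9).
#' @return A tibble with rows `colonization` and `extinction`: `mean`,
#'   `lo`, `hi`.
#' @export
turnover_rates <- function(fit, level = 0.9) {
  stopifnot(inherits(fit, "pika_fit"))
  arr <- fit$arr
  if (arr$nyear < 2) abort("turnover rates need at least 2 modeled years")
  a <- (1 - level) / 2
  nz <- nrow(fit$z_draws)
  col <- ext <- numeric(nz)
  for (d in seq_len(nz)) {
    z <- matrix(fit$z_draws[d, ], arr$nsite, arr$nyear)
    prev <- z[, -arr$nyear, drop = FALSE]
    curr <- z[, -1, drop = FALSE]
    col[d] <- if (any(prev == 0)) mean(curr[prev == 0]) else NA_real_
    ext[d] <- if (any(prev == 1)) mean(1 - curr[prev == 1]) else NA_real_
  }
  tibble::tibble(
    process = c("colonization", "extinction"),
    mean = c(mean(col, na.rm = TRUE), mean(ext, na.rm = TRUE)),
    lo = c(quantile(col, a, na.rm = TRUE), quantile(ext, a, na.rm = TRUE)),
    hi = c(quantile(col, 1 - a, na.rm = TRUE),
           quantile(ext, 1 - a, na.rm = TRUE))
  )
}
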