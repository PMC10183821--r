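#' Naive occupancy under perfect detection
#'
#' The covariate-screening stage assumes perfect detection and no false
#' positives: a site-year is scored occupied (1) if any sign was detected
#' in any of its surveys, unoccupied (0) if it was surveyed without
#' detections, and missing if unsurveyed.
#'
#' @param data A `pika_survey` or `pika_array`.
#' @return A tibble: `site_id`, `year`, `naive_z` (0/1/NA).
#' @export
naive_occupancy <- function(data) {
  arr <- if (inherits(data, "pika_array")) data else encode_surveys(data)
  z <- matrix(NA_integer_, arr$nsite, arr$nyear)
  if (nrow(arr$surveys) > 0) {
    yany <- as.integer(rowSums(arr$y) > 0)
    for (j in seq_len(nrow(arr$surveys))) {
      i <- arr$surveys$site[j]
      t <- arr$surveys$year_idx[j]
      z[i, t] <- max(z[i, t], yany[j], na.rm = TRUE)
    }
  }
  tidyr::expand_grid(i = seq_len(arr$nsite), t = seq_len(arr$nyear)) %>%
    mutate(site_id = arr$site_id[.data$i], year = arr$years[.data$t],
           naive_z = z[cbind(.data$i, .data$t)]) %>%
    select("site_id", "year", "naive_z")
}

#' Exposure sets for the colonization and extinction processes
#'
#' Builds the regression datasets of the covariate-screening stage from
#' the naive occupancy matrix: extinction rows are site-year pairs that
#' were (naively) occupied in the previous year, with outcome 1 if the
#' site became unoccupied; colonization rows are pairs that were
#' unoccupied in the previous year, with outcome 1 if the site became
#' occupied. Only consecutive modeled years with a known naive state at
#' both ends contribute; transitions spanning unsurveyed years are
#' dropped. Covariates (vegetation covers, complexity, climate at the
#' destination year) are attached to each row.
#'
#' @param naive_z Tibble from [naive_occupancy()].
#' @param data The `pika_survey` or `pika_array` the naive states came
#'   from.
#' @return List with tibbles `extinction` and `colonization`, each with
#'   `site_id`, `year` (destination), `outcome` and covariate columns.
#' @export
build_exposure_sets <- function(naive_z, data) {
  arr <- if (inherits(data, "pika_array")) data else encode_surveys(data)
  zm <- matrix(NA_integer_, arr$nsite, arr$nyear)
  zm[cbind(match(naive_z$site_id, arr$site_id),
           match(naive_z$year, arr$years))] <- naive_z$naive_z

  rows <- list(extinction = list(), colonization = list())
  if (arr$nyear > 1) {
    for (t in 2:arr$nyear) {
      prev <- zm[, t - 1]
      curr <- zm[, t]
      ok <- !is.na(prev) & !is.na(curr)
      for (i in which(ok)) {
        row <- tibble::tibble(
          site_id = arr$site_id[i], year = arr$years[t],
          forb = arr$forb[i], rock = arr$rock[i], shrub = arr$shrub[i],
          cplx = arr$complexity[i],
          tmaxmean = arr$tmax[i, t], precip = arr$precip[i, t]
        )
        if (prev[i] == 1L) {
          row$outcome <- as.integer(curr[i] == 0L)
          rows$extinction[[length(rows$extinction) + 1]] <- row
        } else {
          row$outcome <- as.integer(curr[i] == 1L)
          rows$colonization[[length(rows$colonization) + 1]] <- row
        }
      }
    }
  }
  empty <- tibble::tibble(site_id = character(), year = integer(),
                          forb = numeric(), rock = numeric(),
                          shrub = numeric(), cplx = numeric(),
                          tmaxmean = numeric(), precip = numeric(),
                          outcome = integer())
  list(
    extinction = if (length(rows$extinction)) bind_rows(rows$extinction)
      else empty,
    colonization = if (length(rows$colonization)) bind_rows(rows$colonization)
      else empty
  )
}

#' Reverse step-wise AIC covariate selection
#'
#' Backward elimination on a logistic regression: starting from the full
#' covariate set, iteratively drop the covariate whose removal most
#' lowers the AIC until no single removal lowers it further. The result
#' is advisory — the Bayesian fit takes an explicit covariate design, and
#' this stage mirrors a two-stage workflow in which screening under a
#' perfect-detection assumption precedes the full model.
#'
#' @param exposure Exposure tibble (from [build_exposure_sets()]) with an
#'   `outcome` column.
#' @param covariates Character vector of candidate covariate columns
#'   (default: all of forb, rock, shrub, cplx, tmaxmean, precip present).
#' @return Character vector of retained covariates (may be empty:
#'   intercept-only model). The fitted final `glm` is attached as
#'   attribute `model`.
#' @export
stepwise_aic <- function(exposure,
                         covariates = intersect(c("forb", "rock", "shrub",
                                                  "cplx", "tmaxmean",
                                                  "precip"),
                                                names(exposure))) {
  stopifnot("outcome" %in% names(exposure), length(covariates) >= 1)
  df <- as.data.frame(exposure[, c("outcome", covariates)])
  full <- suppressWarnings(
    glm(stats::reformulate(covariates, response = "outcome"),
        data = df, family = binomial())
  )
  sep <- abs(full$fitted.values - df$outcome) < 1e-4
  if (any(sep) || !full$converged) {
    worst <- names(which.max(abs(coef(full)[-1])))
    warn(paste0("possible complete separation in the exposure set ",
                "(fitted probabilities of 0/1; largest coefficient: ",
                worst, "); selected covariates may be unstable"),
         class = "pika_separation_warning")
  }
  red <- stats::step(full, direction = "backward", trace = 0)
  sel <- setdiff(attr(stats::terms(red), "term.labels"), character(0))
  attr(sel, "model") <- red
  sel
}
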