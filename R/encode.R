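#' Encode a survey dataset into model-ready arrays
#'
#' Converts a (classified, standardized) survey dataset into the
#' rectangular arrays consumed by the likelihood and sampler: binary
#' detection and ambiguity matrices over flattened surveys, integer site
#' and year indices, per-site covariates, and site-by-year climate
#' matrices. Site-years without surveys are simply absent from the survey
#' list; the latent occupancy state is still modeled for them.
#'
#' @param data A `pika_survey` object (preprocessing is applied first if it
#'   has not been already).
#' @return An object of class `pika_array`.
#' @export
encode_surveys <- function(data) {
  stopifnot(inherits(data, "pika_survey"))
  if (!isTRUE(data$preprocessed)) data <- preprocess_covariates(data)

  sites <- arrange(data$sites, .data$park_id, .data$site_id)
  site_id <- sites$site_id
  park_levels <- sort(unique(sites$park_id))
  park <- match(sites$park_id, park_levels)
  years <- data$years
  nsite <- length(site_id)
  nyear <- length(years)

  tmax <- matrix(NA_real_, nsite, nyear,
                 dimnames = list(site_id, as.character(years)))
  precip <- tmax
  if (nrow(data$climate) > 0 && nsite > 0 && nyear > 0) {
    ci <- match(data$climate$site_id, site_id)
    cj <- match(data$climate$year, years)
    keep <- !is.na(ci) & !is.na(cj)
    tmax[cbind(ci[keep], cj[keep])] <- data$climate$tmaxmean[keep]
    precip[cbind(ci[keep], cj[keep])] <- data$climate$precip[keep]
  }

  rec <- arrange(data$records, match(.data$site_id, .env$site_id),
                 .data$year, .data$survey_index)
  y <- as.matrix(rec[, paste0("det_", tolower(SIGN_CODES))])
  u <- as.matrix(rec[, paste0("unamb_", tolower(SIGN_CODES))])
  colnames(y) <- colnames(u) <- SIGN_CODES
  storage.mode(y) <- "integer"
  storage.mode(u) <- "integer"

  surveys <- tibble::tibble(
    site = match(rec$site_id, site_id),
    year_idx = match(rec$year, years),
    survey_index = rec$survey_index,
    season = as.numeric(rec$season),
    period = as.numeric(rec$survey_period)
  )

  structure(
    list(
      site_id = site_id, park = park, park_levels = park_levels,
      years = years, nsite = nsite, nyear = nyear,
      npark = length(park_levels),
      complexity = sites$complexity, forb = sites$forb, rock = sites$rock,
      shrub = sites$shrub,
      complexity_missing = if ("complexity_missing" %in% names(sites))
        sites$complexity_missing else rep(FALSE, nsite),
      tmax = tmax, precip = precip,
      surveys = surveys, y = y, u = u,
      scaling = data$scaling
    ),
    class = "pika_array"
  )
}

#' @export
print.pika_array <- function(x, ...) {
  cat("<pika_array> ", x$nsite, " sites x ", x$nyear, " years, ",
      nrow(x$surveys), " surveys, ", x$npark, " parks\n", sep = "")
  invisible(x)
}

#' Decode arrays back into a survey-record tibble
#'
#' Inverse of [encode_surveys()] for the modeled fields: reconstructs the
#' survey-level records tibble (ids, year, survey index, season, period,
#' detections and ambiguity flags) from a `pika_array`.
#'
#' @param arr A `pika_array`.
#' @return A tibble in the same layout as `survey_data()$records`.
#' @export
decode_surveys <- function(arr) {
  stopifnot(inherits(arr, "pika_array"))
  sv <- arr$surveys
  out <- tibble::tibble(
    site_id = arr$site_id[sv$site],
    park_id = arr$park_levels[arr$park[sv$site]],
    year = arr$years[sv$year_idx],
    survey_index = sv$survey_index,
    season = as.integer(sv$season),
    survey_period = as.integer(sv$period)
  )
  for (k in seq_along(SIGN_CODES)) {
    out[[paste0("det_", tolower(SIGN_CODES[k]))]] <- arr$y[, k]
    out[[paste0("unamb_", tolower(SIGN_CODES[k]))]] <- arr$u[, k]
  }
  out
}

# Per-survey observation covariate matrix for a design given as a character
# vector over {intercept, season, period, complexity, forb}.
obs_design_matrix <- function(arr, cols) {
  sv <- arr$surveys
  n <- nrow(sv)
  avail <- list(
    intercept = rep(1, n),
    season = sv$season,
    period = sv$period,
    complexity = arr$complexity[sv$site],
    forb = arr$forb[sv$site]
  )
  bad <- setdiff(cols, names(avail))
  if (length(bad) > 0) {
    abort(paste0("unknown observation covariate(s): ",
                 paste(bad, collapse = ", ")))
  }
  m <- do.call(cbind, avail[cols])
  if (length(cols) == 0) m <- matrix(0, n, 0)
  colnames(m) <- cols
  m
}

# Site-by-year dynamics design matrix, rows stacked site-major per year
# (row = site + nsite * (year_idx - 1)). Supports site-level covers,
# complexity, and year-varying climate covariates.
dyn_design_matrix <- function(arr, cols) {
  n <- arr$nsite * arr$nyear
  avail <- list(
    intercept = rep(1, n),
    forb = rep(arr$forb, arr$nyear),
    rock = rep(arr$rock, arr$nyear),
    shrub = rep(arr$shrub, arr$nyear),
    complexity = rep(arr$complexity, arr$nyear),
    tmaxmean = as.vector(arr$tmax),
    precip = as.vector(arr$precip)
  )
  bad <- setdiff(cols, names(avail))
  if (length(bad) > 0) {
    abort(paste0("unknown dynamics covariate(s): ",
                 paste(bad, collapse = ", ")))
  }
  m <- do.call(cbind, avail[cols])
  if (length(cols) == 0) m <- matrix(0, n, 0)
  colnames(m) <- cols
  m
}
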