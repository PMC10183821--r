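#' Standardize covariates for model fitting
#'
#' Centers and scales every non-binary covariate to mean 0 and standard
#' deviation 1 (vegetation covers over sites, climate covariates over all
#' modeled site-years), maps substrate complexity from its three ordinal
#' levels to centered values (low = -1, intermediate = 0, high = +1), and
#' records the scaling constants so raw values can be recovered. Missing
#' complexity is imputed at the neutral centered value 0 and flagged in
#' `complexity_missing`. The operation is idempotent: applying it to an
#' already-standardized dataset leaves the values unchanged.
#'
#' Pairwise absolute correlations among the retained quantitative
#' covariates are computed over site-years and attached as the
#' `correlations` element; any pair above `cor_threshold` triggers a
#' warning, since strongly collinear covariates should not enter the same
#' linear predictor.
#'
#' @param data A `pika_survey` object with raw covariates.
#' @param cor_threshold Absolute-correlation warning threshold
#'   (default 0.75).
#'
#' @return The same object with standardized covariates, a `scaling`
#'   tibble (covariate, center, scale), `complexity_missing` flags and a
#'   `correlations` matrix; `preprocessed` is set to `TRUE`.
#' @export
preprocess_covariates <- function(data, cor_threshold = 0.75) {
  stopifnot(inherits(data, "pika_survey"))
  sites <- data$sites
  climate <- data$climate

  scale_col <- function(x, name) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      abort(paste0("covariate '", name, "' has zero variance"),
            class = "pika_zero_variance_error")
    }
    list(z = (x - mean(x)) / s, center = mean(x), scale = s)
  }

  scaling <- list()
  for (cv in c("forb", "rock", "shrub")) {
    sc <- scale_col(sites[[cv]], cv)
    sites[[cv]] <- sc$z
    scaling[[cv]] <- c(center = sc$center, scale = sc$scale)
  }

  # complexity: ordinal labels -> centered {-1, 0, +1}; numeric input must
  # already be centered (idempotent path)
  cx <- sites$complexity
  if (is.character(cx) || is.factor(cx)) {
    cx <- tolower(as.character(cx))
    known <- c(low = -1, intermediate = 0, high = 1)
    bad <- setdiff(unique(cx[!is.na(cx)]), names(known))
    if (length(bad) > 0) {
      abort(paste0("unknown complexity level(s): ", paste(bad, collapse = ", ")),
            class = "pika_parse_error")
    }
    cx <- unname(known[cx])
  } else {
    if (!all(cx[!is.na(cx)] %in% c(-1, 0, 1))) {
      abort("numeric complexity must take values in {-1, 0, +1} or NA",
            class = "pika_parse_error")
    }
  }
  prev_missing <- if ("complexity_missing" %in% names(sites))
    sites$complexity_missing else rep(FALSE, nrow(sites))
  sites$complexity_missing <- is.na(cx) | prev_missing
  cx[is.na(cx)] <- 0
  sites$complexity <- as.numeric(cx)

  # climate standardized over all modeled site-years
  climate <- climate[climate$year %in% data$years |
                       length(data$years) == 0, , drop = FALSE]
  for (cv in c("tmaxmean", "precip")) {
    sc <- scale_col(climate[[cv]], cv)
    climate[[cv]] <- sc$z
    scaling[[cv]] <- c(center = sc$center, scale = sc$scale)
  }

  # collinearity screen over site-years (cover values repeat across years)
  merged <- left_join(climate, sites[, c("site_id", "forb", "rock", "shrub")],
                      by = "site_id")
  quant <- merged[, c("forb", "rock", "shrub", "tmaxmean", "precip")]
  quant <- quant[complete.cases(quant), , drop = FALSE]
  cors <- if (nrow(quant) > 2) cor(as.matrix(quant)) else
    matrix(NA_real_, 5, 5, dimnames = list(names(quant), names(quant)))
  high <- which(abs(cors) > cor_threshold & upper.tri(cors), arr.ind = TRUE)
  if (nrow(high) > 0) {
    pairs <- apply(high, 1, function(ij) {
      paste0(rownames(cors)[ij[1]], "~", colnames(cors)[ij[2]], " (r=",
             round(cors[ij[1], ij[2]], 2), ")")
    })
    warn(paste0("covariate pair(s) correlated above ", cor_threshold, ": ",
                paste(pairs, collapse = ", ")),
         class = "pika_collinearity_warning")
  }

  data$sites <- sites
  data$climate <- climate
  data$scaling <- dplyr::bind_rows(
    lapply(names(scaling), function(nm) {
      tibble::tibble(covariate = nm, center = scaling[[nm]]["center"],
                     scale = scaling[[nm]]["scale"])
    })
  )
  data$correlations <- cors
  data$preprocessed <- TRUE
  data
}
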