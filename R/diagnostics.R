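#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain R-hat: each chain is split in half, and the classic
#' between/within variance ratio is computed over the resulting
#' half-chains. Values near 1 indicate the chains have mixed; values above
#' about 1.1 indicate non-convergence. Parameters whose draws are constant
#' across all chains are defined to have R-hat 1 (the zero-variance
#' convention).
#'
#' @param draws Matrix of posterior draws (rows = iterations, stacked
#'   chains) or a numeric vector for a single parameter.
#' @param chain Integer vector assigning each row to a chain (>= 2 chains
#'   required).
#' @return Named numeric vector of R-hat values (scalar for vector input).
#' @export
rhat <- function(draws, chain) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (length(unique(chain)) < 2) {
    abort("R-hat requires at least 2 chains")
  }
  rhat_matrix(draws, chain)
}

rhat_matrix <- function(draws, chain) {
  chains <- unique(chain)
  halves <- list()
  for (c in chains) {
    idx <- which(chain == c)
    n <- length(idx)
    if (n < 4) abort("R-hat requires at least 2 retained draws per half-chain")
    halves[[length(halves) + 1]] <- idx[seq_len(n %/% 2)]
    halves[[length(halves) + 1]] <- idx[(n %/% 2 + 1):n]
  }
  m <- length(halves)
  n <- min(lengths(halves))
  out <- vapply(seq_len(ncol(draws)), function(k) {
    x <- vapply(halves, function(h) draws[h[seq_len(n)], k], numeric(n))
    mns <- colMeans(x)
    vrs <- apply(x, 2, var)
    W <- mean(vrs)
    B <- n * var(mns)
    if (W == 0) return(1)  # constant chains: defined as converged
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  names(out) <- colnames(draws)
  out
}

#' Posterior predictive p-value for a sign type
#'
#' Goodness-of-fit check based on the sum of squared errors of the binary
#' detections: for each retained draw with a stored latent state, the
#' discrepancy `T = sum_j (y_j - pd_j)^2` is computed for the observed
#' detections and for a replicate dataset simulated from that draw, where
#' `pd_j` is the sign's detection probability given the drawn occupancy
#' state of survey j's site-year. The p-value is the fraction of draws
#' whose replicate discrepancy is at least the observed one; values near
#' 0.5 indicate that the dispersion of the observed data matches what the
#' model reproduces, values near 0 or 1 indicate misfit.
#'
#' @param fit A `pika_fit` (variants with an observation model only).
#' @param sign Sign code; `"ANY"` for the standard variant.
#' @return Scalar p-value in (0, 1).
#' @export
ppc_pvalue <- function(fit, sign = "FS") {
  stopifnot(inherits(fit, "pika_fit"))
  if (fit$variant == "perfect") {
    abort("the perfect-detection variant has no observation model to check")
  }
  detection <- fit$detection
  if (!sign %in% names(detection$beta)) {
    abort(paste0("sign '", sign, "' is not part of this fit's observation model"))
  }
  arr <- fit$arr
  if (fit$variant == "standard") arr <- collapse_any_sign(arr)
  k <- match(sign, colnames(arr$y))
  if (nrow(arr$surveys) == 0 || sum(!is.na(arr$y[, k])) == 0) {
    abort(paste0("no observed surveys for sign ", sign))
  }
  Xp <- obs_design_matrix(arr, detection$designs$p[[sign]])
  cols_fp <- if (fit$variant == "full") detection$designs$fp[[sign]] else
    character(0)
  Xfp <- obs_design_matrix(arr, cols_fp)
  bnm <- paste0("beta_", tolower(sign), "_", detection$designs$p[[sign]])
  fnm <- if (length(cols_fp)) paste0("beta_", tolower(sign), "_xi_", cols_fp)
  y <- arr$y[, k]
  u <- arr$u[, k]
  sv <- arr$surveys
  nz <- nrow(fit$z_draws)
  tobs <- numeric(nz)
  trep <- numeric(nz)
  nsite <- fit$arr$nsite
  for (d in seq_len(nz)) {
    di <- which(fit$chain == fit$z_chain[d])[fit$z_index[d]]
    beta <- fit$draws[di, bnm]
    p1 <- plogis(as.vector(Xp %*% beta))
    p0 <- if (length(cols_fp)) {
      pp <- plogis(as.vector(Xfp %*% fit$draws[di, fnm]))
      pp[u == 1] <- 0
      pp
    } else rep(0, length(y))
    zz <- fit$z_draws[d, sv$site + nsite * (sv$year_idx - 1)]
    pd <- ifelse(zz == 1, p1, p0)
    yrep <- rbinom(length(y), 1, pd)
    tobs[d] <- sum((y - pd)^2)
    trep[d] <- sum((yrep - pd)^2)
  }
  mean(trep >= tobs)
}

#' Weight of evidence that a coefficient is above/below zero
#'
#' The posterior mass of a parameter above and below zero. Draws exactly
#' equal to zero are counted to neither side and the two fractions are
#' renormalized to sum to one.
#'
#' @param fit A `pika_fit`.
#' @param parameter Parameter name (a column of `fit$draws`).
#' @return Named numeric vector `c(omega_plus, omega_minus)`.
#' @export
weight_of_evidence <- function(fit, parameter) {
  stopifnot(inherits(fit, "pika_fit"))
  if (!parameter %in% colnames(fit$draws)) {
    abort(paste0("unknown parameter '", parameter, "'"))
  }
  x <- fit$draws[, parameter]
  np <- sum(x > 0)
  nm <- sum(x < 0)
  tot <- np + nm
  if (tot == 0) return(c(omega_plus = 0.5, omega_minus = 0.5))
  c(omega_plus = np / tot, omega_minus = nm / tot)
}
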