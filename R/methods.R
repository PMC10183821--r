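#' Tidy posterior summaries of a fitted model
#'
#' One row per parameter: posterior mean, standard deviation, equal-tailed
#' credible interval, weight of evidence above/below zero and R-hat.
#' Coefficients are summarized with 95% intervals by default; pass
#' `conf_level = 0.9` for the convention used for derived occupancy rates.
#'
#' @param x A `pika_fit`.
#' @param conf_level Credible-interval level (default 0.95).
#' @param structural_only Drop individual random-effect levels and keep
#'   coefficients and scale parameters (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `omega_plus`, `omega_minus`, `rhat`.
#' @method tidy pika_fit
#' @export
tidy.pika_fit <- function(x, conf_level = 0.95, structural_only = TRUE, ...) {
  nms <- colnames(x$draws)
  keep <- if (structural_only) nms[is_structural(nms)] else nms
  a <- (1 - conf_level) / 2
  purrr::map_dfr(keep, function(nm) {
    d <- x$draws[, nm]
    w <- weight_of_evidence(x, nm)
    tibble::tibble(
      term = nm, estimate = mean(d), std.error = sd(d),
      conf.low = unname(quantile(d, a)),
      conf.high = unname(quantile(d, 1 - a)),
      omega_plus = w[["omega_plus"]], omega_minus = w[["omega_minus"]],
      rhat = unname(x$rhat[nm])
    )
  })
}

#' One-line fit summary
#'
#' @param x A `pika_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variant, chains, retained draws, number of
#'   parameters, maximum structural R-hat, convergence flag, whether the
#'   automatic rerun fired, and mean marginal log-likelihood.
#' @method glance pika_fit
#' @export
glance.pika_fit <- function(x, ...) {
  ns <- is_structural(colnames(x$draws))
  mr <- max(x$rhat[ns], na.rm = TRUE)
  tibble::tibble(
    variant = x$variant,
    n_chains = length(unique(x$chain)),
    n_draws = nrow(x$draws),
    n_params = ncol(x$draws),
    max_rhat = mr,
    converged = mr <= x$config$rhat_threshold,
    reran = x$reran,
    mean_loglik = mean(x$loglik)
  )
}

#' Coefficient interval plot for a fitted model
#'
#' Posterior means and credible intervals for the structural parameters,
#' grouped by model block (detection, false-positive, state process,
#' scales).
#'
#' @param object A `pika_fit`.
#' @param conf_level Interval level (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pika_fit
#' @export
autoplot.pika_fit <- function(object, conf_level = 0.95, ...) {
  td <- tidy(object, conf_level = conf_level)
  td$block <- dplyr::case_when(
    grepl("_xi_", td$term) ~ "false positive",
    grepl("^beta_", td$term) ~ "detection",
    grepl("^sigma_", td$term) ~ "scales",
    TRUE ~ "state process"
  )
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_wrap(~block, scales = "free") +
    ggplot2::labs(x = "posterior mean and credible interval", y = NULL)
}

#' Park-level occupancy trajectories with credible ribbons
#'
#' @param object An occupancy series as returned by [occupancy_rates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pika_occupancy
#' @export
autoplot.pika_occupancy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~park_id) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "occupancy rate (posterior mean, 90% CRI)")
}
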