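#' Default observation-model designs per sign type
#'
#' Each sign type's true-detection probability and (for ambiguous signs)
#' false-positive probability is a logit-linear function of per-survey
#' covariates. The default designs reflect the covariates that plausibly
#' drive each process: scat detectability differs between the two survey
#' periods; haypile detectability depends on substrate complexity and forb
#' cover; calls and sightings depend on season and complexity. Sightings
#' have no false-positive design at all (an always-unambiguous sign type
#' has false-detection probability identically zero).
#'
#' @return List with elements `p` and `fp`, each a named list of character
#'   vectors over `{intercept, season, period, complexity, forb}`.
#' @export
default_obs_designs <- function() {
  list(
    p = list(
      FS = c("intercept", "period"),
      FH = c("intercept", "complexity", "forb"),
      PC = c("intercept", "season", "complexity"),
      PS = c("intercept", "season", "complexity")
    ),
    fp = list(
      FS = c("intercept", "period"),
      FH = c("intercept", "forb"),
      PC = c("intercept", "season", "complexity"),
      PS = character(0)
    )
  )
}

#' Default state-process (dynamics) designs
#'
#' Initial occupancy is a logit-linear function of substrate complexity
#' with park-level random intercepts and random complexity slopes;
#' colonization and extinction are logit-linear in vegetation covariates
#' with park-by-year random intercepts.
#'
#' @return List with character-vector elements `lambda`, `gamma`, `eps`.
#' @export
default_dyn_designs <- function() {
  list(
    lambda = c("intercept", "complexity"),
    gamma = c("intercept", "forb", "shrub"),
    eps = c("intercept", "forb")
  )
}

#' Construct per-sign detection parameters
#'
#' @param beta Named list of numeric coefficient vectors for true
#'   detection, one per sign, each named by its design columns.
#' @param beta_fp Same for false-positive detection (PS omitted or empty).
#' @param designs Observation designs, see [default_obs_designs()].
#' @return Object of class `pika_detection_params`.
#' @export
detection_params <- function(beta, beta_fp = NULL,
                             designs = default_obs_designs()) {
  for (s in names(beta)) {
    if (length(beta[[s]]) != length(designs$p[[s]])) {
      abort(paste0("beta[['", s, "']] has length ", length(beta[[s]]),
                   " but its design has ", length(designs$p[[s]]),
                   " column(s)"))
    }
    names(beta[[s]]) <- designs$p[[s]]
  }
  if (is.null(beta_fp)) {
    beta_fp <- lapply(designs$fp, function(cols) setNames(numeric(length(cols)), cols))
  }
  for (s in names(beta_fp)) {
    if (length(beta_fp[[s]]) != length(designs$fp[[s]])) {
      abort(paste0("beta_fp[['", s, "']] has length ", length(beta_fp[[s]]),
                   " but its design has ", length(designs$fp[[s]]),
                   " column(s)"))
    }
    names(beta_fp[[s]]) <- designs$fp[[s]]
  }
  structure(list(beta = beta, beta_fp = beta_fp, designs = designs),
            class = "pika_detection_params")
}

#' Default generating values for the detection process
#'
#' Coefficient values centered on the posterior operating point of a
#' multi-park pika monitoring program: high scat detectability (around
#' 0.8), moderate haypile and call detectability (around 0.29 and 0.41),
#' low sighting rates (around 0.13), and small false-positive rates (2-4%)
#' that vary with season, period, complexity and forb cover.
#'
#' @return A `pika_detection_params` object.
#' @export
default_detection_params <- function() {
  detection_params(
    beta = list(
      FS = c(1.70, -0.684),
      FH = c(-0.90, -0.262, 0.336),
      PC = c(-0.10, -0.544, -0.273),
      PS = c(-1.60, -0.584, -0.306)
    ),
    beta_fp = list(
      FS = c(-2.80, -1.139),
      FH = c(-3.90, 0.333),
      PC = c(-2.70, -1.069, -0.228),
      PS = numeric(0)
    )
  )
}

#' Construct state-process parameters
#'
#' @param lambda Named coefficients of the initial-occupancy design.
#' @param gamma Named coefficients of the colonization design.
#' @param eps Named coefficients of the extinction design.
#' @param sigma Named numeric vector of random-effect scales:
#'   `lambda_int`, `lambda_slope` (park level), `gamma`, `eps` (park-year
#'   level). All must be positive.
#' @param designs Dynamics designs, see [default_dyn_designs()].
#' @return Object of class `pika_dynamics_params`.
#' @export
dynamics_params <- function(lambda, gamma, eps,
                            sigma = c(lambda_int = 1.13, lambda_slope = 0.5,
                                      gamma = 0.65, eps = 0.65),
                            designs = default_dyn_designs()) {
  if (any(sigma <= 0)) abort("all random-effect scales must be > 0")
  stopifnot(length(lambda) == length(designs$lambda),
            length(gamma) == length(designs$gamma),
            length(eps) == length(designs$eps))
  names(lambda) <- designs$lambda
  names(gamma) <- designs$gamma
  names(eps) <- designs$eps
  structure(list(lambda = lambda, gamma = gamma, eps = eps,
                 sigma = sigma, designs = designs),
            class = "pika_dynamics_params")
}

#' Default generating values for the state process
#'
#' Initial occupancy near 28% rising with substrate complexity, annual
#' colonization near 6% increasing with shrub cover, annual extinction
#' near 6% dropping steeply with forb cover, and park/park-year random
#' effect scales around the magnitudes typical of multi-park pika
#' monitoring (about 1.1 on initial occupancy, 0.65 on the annual
#' processes).
#'
#' @return A `pika_dynamics_params` object.
#' @export
default_dynamics_params <- function() {
  dynamics_params(
    lambda = c(-0.92, 1.325),
    gamma = c(-2.79, 0.033, 0.255),
    eps = c(-2.72, -2.70)
  )
}
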