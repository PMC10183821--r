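#' The four observation-model variants
#'
#' The observation process can be represented at four levels of realism:
#'
#' * `full` — multi-sign with per-sign true and false-positive detection
#'   probabilities and the unambiguous-observation constraint;
#' * `nofp` — multi-sign with no false positives (every detection implies
#'   occupancy);
#' * `standard` — a single any-sign detection process with no false
#'   positives;
#' * `perfect` — no observation model: a surveyed site-year is occupied
#'   exactly when any sign was detected, and latent otherwise.
#'
#' @return Character vector of variant codes.
#' @export
model_variants <- function() c("full", "nofp", "standard", "perfect")

#' Reduce detection parameters to a simpler observation-model variant
#'
#' * `full` returns the parameters unchanged.
#' * `nofp` drops all false-positive coefficient blocks (false-positive
#'   probabilities become structural zeros).
#' * `standard` collapses the per-sign processes to a single any-sign
#'   binary detection process with one coefficient vector (design given by
#'   `standard_design`), again with no false positives.
#' * `perfect` removes the observation layer entirely (returns an empty
#'   parameter set).
#'
#' @param params A `pika_detection_params` for the full model.
#' @param variant One of [model_variants()].
#' @param standard_design Observation design of the collapsed any-sign
#'   process (used only for `variant = "standard"`).
#' @return A reduced `pika_detection_params`.
#' @export
apply_variant <- function(params, variant,
                          standard_design = c("intercept", "season",
                                              "period")) {
  if (!variant %in% model_variants()) {
    abort(paste0("unknown model variant '", variant, "'"))
  }
  switch(variant,
    full = params,
    nofp = {
      params$beta_fp <- lapply(params$beta_fp, function(b) numeric(0))
      params$designs$fp <- lapply(params$designs$fp, function(d) character(0))
      params
    },
    standard = detection_params(
      beta = list(ANY = setNames(numeric(length(standard_design)),
                                 standard_design)),
      designs = list(p = list(ANY = standard_design),
                     fp = list(ANY = character(0)))
    ),
    perfect = detection_params(beta = list(),
                               designs = list(p = list(), fp = list()))
  )
}

# Collapse a pika_array's per-sign detections to the single any-sign
# process used by the standard variant (u has no role without false
# positives).
collapse_any_sign <- function(arr) {
  yany <- if (nrow(arr$y) > 0) as.integer(rowSums(arr$y) > 0) else integer(0)
  arr$y <- matrix(yany, ncol = 1, dimnames = list(NULL, "ANY"))
  storage.mode(arr$y) <- "integer"
  arr$u <- matrix(0L, nrow(arr$y), 1, dimnames = list(NULL, "ANY"))
  arr
}
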