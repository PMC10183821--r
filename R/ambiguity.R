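# Keywords whose presence in a fresh-scat note marks the observation as
# unambiguous: all describe scat held together by fresh mucous. Matched
# case-insensitively on word stems so that e.g. "stacked" and "stack" both
# qualify.
FS_UNAMBIGUOUS_STEMS <- c("stuck", "pyramid", "tower", "perch", "stack",
                          "teepee", "tepee", "cluster")

fs_notes_unambiguous <- function(notes) {
  notes <- ifelse(is.na(notes), "", as.character(notes))
  pattern <- paste0("\\b(", paste(FS_UNAMBIGUOUS_STEMS, collapse = "|"),
                    ")\\w*\\b")
  grepl(pattern, notes, ignore.case = TRUE, perl = TRUE)
}

#' Classify survey observations as ambiguous or unambiguous
#'
#' Unambiguous observations are those for which a false positive is
#' essentially impossible; the model pins their false-detection probability
#' to zero, which anchors the identifiability of the false-positive rates
#' of the remaining, ambiguous observations. The rules are:
#'
#' * Pika sightings (`PS`) are always unambiguous when detected.
#' * Fresh haypiles (`FH`) and calls (`PC`) are never unambiguous.
#' * A fresh-scat (`FS`) detection is unambiguous if any of its
#'   observation notes mentions a form of scat held together by fresh
#'   mucous (stems: stuck, pyramid, tower, perch(ed), stack(ed),
#'   teepee/tepee, cluster), or if a fresh haypile was detected during the
#'   same survey.
#'
#' Absent or empty notes are treated as ambiguous (the keyword rule simply
#' never fires), which matches datasets whose early survey years lack
#' consistent note-taking.
#'
#' @param detected Named integer/logical vector of per-survey detections
#'   with names `FS`, `FH`, `PC`, `PS` (or a tibble row with `det_*`
#'   columns).
#' @param notes Character vector of free-text notes attached to the FS
#'   observations of the survey (may be empty or `NA`).
#'
#' @return Named integer vector of unambiguous flags (`FS`, `FH`, `PC`,
#'   `PS`).
#' @export
#' @examples
#' classify_ambiguity(c(FS = 1, FH = 0, PC = 0, PS = 0),
#'                    notes = "scat stacked in small tower")
classify_ambiguity <- function(detected, notes = character()) {
  if (is.data.frame(detected)) {
    detected <- c(FS = detected$det_fs[1], FH = detected$det_fh[1],
                  PC = detected$det_pc[1], PS = detected$det_ps[1])
  }
  detected <- as.integer(detected[SIGN_CODES])
  names(detected) <- SIGN_CODES
  note_hit <- length(notes) > 0 && any(fs_notes_unambiguous(notes))
  c(
    FS = as.integer(detected[["FS"]] == 1L &&
                      (note_hit || detected[["FH"]] == 1L)),
    FH = 0L,
    PC = 0L,
    PS = detected[["PS"]]
  )
}
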