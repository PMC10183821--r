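#' Assemble a validated multi-sign survey dataset
#'
#' Bundles survey-level detection records, site covariates and annual
#' climate covariates into a single validated object. Records are one row
#' per (site, year, survey) with binary detection and ambiguity columns for
#' each sign type; sites carry vegetation-cover and substrate-complexity
#' covariates; climate carries one row per modeled site-year. The modeled
#' year grid spans every calendar year from the first to the last year in
#' `years` (or in the records), so that a single annual transition kernel
#' applies uniformly and unsurveyed gap years are carried as latent-only
#' years.
#'
#' @param records Tibble with columns `site_id`, `park_id`, `year`,
#'   `survey_index`, `season` (0 = summer, 1 = fall), `survey_period`
#'   (0 = pre-2017, 1 = post-2017), `det_fs`, `det_fh`, `det_pc`, `det_ps`,
#'   `unamb_fs`, `unamb_fh`, `unamb_pc`, `unamb_ps`.
#' @param sites Tibble with columns `site_id`, `park_id`, `forb`, `rock`,
#'   `shrub`, `complexity` (either labels low/intermediate/high or centered
#'   values -1/0/+1; `NA` allowed and flagged as missing).
#' @param climate Tibble with columns `site_id`, `year`, `tmaxmean`,
#'   `precip`. Must cover every modeled site-year.
#' @param years Optional integer vector of modeled years; defaults to the
#'   full consecutive span of years present in `records`.
#'
#' @return An object of class `pika_survey` (a list with elements
#'   `records`, `sites`, `climate`, `years` and a `preprocessed` flag).
#' @export
survey_data <- function(records, sites, climate, years = NULL) {
  records <- tibble::as_tibble(records)
  sites <- tibble::as_tibble(sites)
  climate <- tibble::as_tibble(climate)

  req_rec <- c(
    "site_id", "park_id", "year", "survey_index", "season", "survey_period",
    paste0("det_", tolower(SIGN_CODES)), "unamb_fs", "unamb_fh", "unamb_pc",
    "unamb_ps"
  )
  miss <- setdiff(req_rec, names(records))
  if (length(miss) > 0) {
    abort(paste0("records is missing required column(s): ",
                 paste(miss, collapse = ", ")), class = "pika_schema_error")
  }
  req_site <- c("site_id", "park_id", "forb", "rock", "shrub", "complexity")
  miss <- setdiff(req_site, names(sites))
  if (length(miss) > 0) {
    abort(paste0("sites is missing required column(s): ",
                 paste(miss, collapse = ", ")), class = "pika_schema_error")
  }
  req_clim <- c("site_id", "year", "tmaxmean", "precip")
  miss <- setdiff(req_clim, names(climate))
  if (length(miss) > 0) {
    abort(paste0("climate is missing required column(s): ",
                 paste(miss, collapse = ", ")), class = "pika_schema_error")
  }

  if (anyDuplicated(records[, c("site_id", "year", "survey_index")]) > 0) {
    dup <- records[duplicated(records[, c("site_id", "year", "survey_index")]), ]
    abort(paste0("duplicate (site_id, year, survey_index): ",
                 paste(utils::head(paste(dup$site_id, dup$year,
                                         dup$survey_index, sep = "/"), 3),
                       collapse = ", ")),
          class = "pika_integrity_error")
  }
  if (nrow(records) > 0) {
    unknown <- setdiff(unique(records$site_id), sites$site_id)
    if (length(unknown) > 0) {
      abort(paste0("records reference unknown site_id(s): ",
                   paste(utils::head(unknown, 5), collapse = ", ")),
            class = "pika_integrity_error")
    }
    # survey_index consecutive from 1 within each site-year
    chk <- records %>%
      group_by(.data$site_id, .data$year) %>%
      summarise(ok = all(sort(.data$survey_index) == seq_len(dplyr::n())),
                .groups = "drop")
    if (!all(chk$ok)) {
      bad <- chk[!chk$ok, ]
      abort(paste0("survey_index not consecutive from 1 for site-year(s): ",
                   paste(utils::head(paste(bad$site_id, bad$year, sep = "/"), 3),
                         collapse = ", ")),
            class = "pika_integrity_error")
    }
    # unambiguous implies detected; FH/PC never unambiguous
    for (s in tolower(SIGN_CODES)) {
      y <- records[[paste0("det_", s)]]
      u <- records[[paste0("unamb_", s)]]
      if (any(u > y)) {
        abort(paste0("unambiguous flag without detection for sign ", toupper(s)),
              class = "pika_integrity_error")
      }
    }
    if (any(records$unamb_fh != 0) || any(records$unamb_pc != 0)) {
      abort("FH and PC are never-unambiguous sign types; their flags must be 0",
            class = "pika_integrity_error")
    }
  }

  if (is.null(years)) {
    if (nrow(records) > 0) {
      years <- seq(min(records$year), max(records$year))
    } else {
      years <- sort(unique(climate$year))
      if (length(years) == 0) years <- integer(0)
    }
  }
  years <- as.integer(years)
  if (length(years) > 1 && !all(diff(years) == 1L)) {
    abort("modeled years must be consecutive calendar years",
          class = "pika_integrity_error")
  }
  if (nrow(records) > 0 && !all(records$year %in% years)) {
    abort("records contain years outside the modeled year grid",
          class = "pika_integrity_error")
  }

  # climate must cover every modeled site-year
  if (nrow(sites) > 0 && length(years) > 0) {
    grid <- tidyr::expand_grid(site_id = sites$site_id, year = years)
    have <- paste(climate$site_id, climate$year)
    lack <- grid[!(paste(grid$site_id, grid$year) %in% have), ]
    if (nrow(lack) > 0) {
      abort(paste0("climate covariates missing for ", nrow(lack),
                   " modeled site-year(s), e.g. ",
                   paste(utils::head(paste(lack$site_id, lack$year, sep = "/"), 3),
                         collapse = ", ")),
            class = "pika_integrity_error")
    }
  }

  structure(
    list(records = records, sites = sites, climate = climate, years = years,
         preprocessed = FALSE, scaling = NULL),
    class = "pika_survey"
  )
}

#' @export
print.pika_survey <- function(x, ...) {
  cat("<pika_survey> ", nrow(x$sites), " sites, ",
      length(unique(x$sites$park_id)), " parks, years ",
      if (length(x$years)) paste0(min(x$years), "-", max(x$years)) else "none",
      ", ", nrow(x$records), " surveys\n", sep = "")
  if (isTRUE(x$preprocessed)) cat("  covariates: standardized\n")
  invisible(x)
}

#' Column schema for the survey CSV formats
#'
#' Returns the default mapping from the package's internal column names to
#' the column names expected in input CSVs, as shipped in
#' `inst/extdata/survey_schema.json`. Pass a modified copy to
#' [read_survey_table()] to read files with different headers.
#'
#' @return Nested named list with elements `observations`, `surveys`,
#'   `sites`, `climate`, each a named character vector (internal name ->
#'   file column name).
#' @export
survey_schema <- function() {
  path <- system.file("extdata", "survey_schema.json", package = "pikasign")
  sch <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(sch, unlist)
}

read_csv_quiet <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

rename_by_schema <- function(df, map, what, required, path) {
  missing_cols <- setdiff(unname(map[required]), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(what, " file '", path, "' is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pika_schema_error")
  }
  present <- map[unname(map) %in% names(df)]
  df <- df[, unname(present), drop = FALSE]
  names(df) <- names(present)
  tibble::as_tibble(df)
}

#' Read a multi-sign survey dataset from CSV files
#'
#' Reads detection records together with site and climate covariates and
#' returns a validated [survey_data()] object. Two record layouts are
#' supported and auto-detected from the header: a long observation format
#' (one row per individual sign observation, with a free-text `notes`
#' column used to classify fresh-scat ambiguity) and a survey-level format
#' (one row per survey with pre-computed binary `detected_*` /
#' `unambiguous_*` columns). Observation rows are collapsed to binary
#' survey-level detections: one or more observations of a sign type within
#' a survey yields a 1, otherwise 0.
#'
#' @param observations Path to the records CSV.
#' @param sites Path to the site-covariate CSV (`site_id`, `park_id`,
#'   `forb_pct`, `rock_pct`, `shrub_pct`, `complexity`).
#' @param climate Path to the climate CSV (`site_id`, `year`, `tmaxmean_c`,
#'   `precip_mm`).
#' @param schema Column-name mapping as returned by [survey_schema()].
#' @param years Optional modeled year grid (passed to [survey_data()]).
#'
#' @return A `pika_survey` object with raw (unstandardized) covariates.
#' @export
read_survey_table <- function(observations, sites, climate,
                              schema = survey_schema(), years = NULL) {
  obs_raw <- read_csv_quiet(observations)

  surv_map <- schema$surveys
  obs_map <- schema$observations
  is_survey_level <- all(unname(surv_map[c("det_fs", "det_fh")]) %in%
                           names(obs_raw))

  if (is_survey_level) {
    req <- c("site_id", "park_id", "year", "survey_index",
             "det_fs", "det_fh", "det_pc", "det_ps", "unamb_fs", "unamb_ps")
    rec <- rename_by_schema(obs_raw, surv_map, "survey", req, observations)
    if (!"season" %in% names(rec)) rec$season <- 0L
    if (!"survey_period" %in% names(rec)) {
      rec$survey_period <- as.integer(rec$year >= 2017)
    }
    rec$unamb_fh <- 0L
    rec$unamb_pc <- 0L
    rec$unamb_ps <- as.integer(rec$det_ps) # PS unambiguous iff detected
  } else {
    req <- c("site_id", "park_id", "year", "survey_index", "sign_code")
    obs <- rename_by_schema(obs_raw, obs_map, "observation", req, observations)
    bad <- setdiff(unique(obs$sign_code), SIGN_CODES)
    if (length(bad) > 0) {
      abort(paste0("unknown sign code(s): ", paste(bad, collapse = ", ")),
            class = "pika_parse_error")
    }
    if (!"notes" %in% names(obs)) obs$notes <- ""
    if (!"season" %in% names(obs)) obs$season <- 0L
    if (!"survey_period" %in% names(obs)) {
      obs$survey_period <- as.integer(obs$year >= 2017)
    }
    rec <- collapse_observations(obs)
  }

  rec <- rec %>%
    mutate(across(c("year", "survey_index", "season", "survey_period",
                    dplyr::starts_with("det_"), dplyr::starts_with("unamb_")),
                  as.integer)) %>%
    arrange(.data$site_id, .data$year, .data$survey_index)

  site_map <- schema$sites
  site_df <- read_csv_quiet(sites)
  site_df <- rename_by_schema(site_df, site_map, "site",
                              c("site_id", "park_id", "forb", "rock", "shrub",
                                "complexity"), sites)

  clim_map <- schema$climate
  clim_df <- read_csv_quiet(climate)
  clim_df <- rename_by_schema(clim_df, clim_map, "climate",
                              c("site_id", "year", "tmaxmean", "precip"),
                              climate)

  survey_data(rec, site_df, clim_df, years = years)
}

# Collapse long observation rows (one per sign observation) to one row per
# survey with binary per-sign detections and classified ambiguity flags.
collapse_observations <- function(obs) {
  if (nrow(obs) == 0) {
    return(tibble::tibble(
      site_id = character(), park_id = character(), year = integer(),
      survey_index = integer(), season = integer(), survey_period = integer(),
      det_fs = integer(), det_fh = integer(), det_pc = integer(),
      det_ps = integer(), unamb_fs = integer(), unamb_fh = integer(),
      unamb_pc = integer(), unamb_ps = integer()
    ))
  }
  obs %>%
    group_by(.data$site_id, .data$park_id, .data$year, .data$survey_index) %>%
    summarise(
      season = .data$season[1],
      survey_period = .data$survey_period[1],
      det_fs = as.integer(any(.data$sign_code == "FS")),
      det_fh = as.integer(any(.data$sign_code == "FH")),
      det_pc = as.integer(any(.data$sign_code == "PC")),
      det_ps = as.integer(any(.data$sign_code == "PS")),
      fs_note_unamb = any(.data$sign_code == "FS" &
                            fs_notes_unambiguous(.data$notes)),
      .groups = "drop"
    ) %>%
    mutate(
      unamb_fs = as.integer(.data$det_fs == 1L &
                              (.data$fs_note_unamb | .data$det_fh == 1L)),
      unamb_fh = 0L,
      unamb_pc = 0L,
      unamb_ps = .data$det_ps
    ) %>%
    select(-"fs_note_unamb")
}

#' Write a survey dataset back to survey-level CSV files
#'
#' Inverse of [read_survey_table()] for the survey-level layout: writes
#' `surveys.csv`, `sites.csv` and `climate.csv` into `dir` using the
#' default schema column names, so that reading them back reproduces the
#' same detection and ambiguity arrays.
#'
#' @param data A `pika_survey` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_survey_table <- function(data, dir) {
  stopifnot(inherits(data, "pika_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sch <- survey_schema()
  rec <- data$records
  out <- rec[, names(sch$surveys)[names(sch$surveys) %in% names(rec)]]
  names(out) <- unname(sch$surveys[names(out)])
  f1 <- file.path(dir, "surveys.csv")
  readr::write_csv(out, f1)

  st <- data$sites
  keep <- names(sch$sites)[names(sch$sites) %in% names(st)]
  out <- st[, keep]
  names(out) <- unname(sch$sites[keep])
  f2 <- file.path(dir, "sites.csv")
  readr::write_csv(out, f2)

  cl <- data$climate[, names(sch$climate)]
  names(cl) <- unname(sch$climate)
  f3 <- file.path(dir, "climate.csv")
  readr::write_csv(cl, f3)
  invisible(c(f1, f2, f3))
}
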