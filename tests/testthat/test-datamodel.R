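test_that("sign type table encodes the ambiguity structure", {
  st <- sign_types()
  expect_equal(st$code, c("FS", "FH", "PC", "PS"))
  expect_true(st$always_unambiguous[st$code == "PS"])
  expect_true(all(st$never_unambiguous[st$code %in% c("FH", "PC")]))
  expect_false(any(st$always_unambiguous[st$code == "FS"],
                   st$never_unambiguous[st$code == "FS"]))
})

test_that("observation rows collapse to binary survey-level detections", {
  fx <- write_obs_fixture()
  sd <- read_survey_table(fx$obs, fx$sites, fx$climate)
  a1 <- sd$records[sd$records$site_id == "A1" & sd$records$year == 2018, ]
  # three FS observation rows -> one record with det_fs = 1
  expect_equal(nrow(a1), 1)
  expect_equal(a1$det_fs, 1L)
  expect_equal(a1$det_fh, 0L)
  # keyword note ("stacked", "tower") marks FS unambiguous
  expect_equal(a1$unamb_fs, 1L)
  # two rows of different signs in the same survey merge into one record
  b1 <- sd$records[sd$records$site_id == "B1", ]
  expect_equal(nrow(b1), 1)
  expect_equal(b1$det_fs + b1$det_fh, 2L)
  # FS upgraded to unambiguous by FH co-occurrence despite empty note
  expect_equal(b1$unamb_fs, 1L)
  # FH itself never unambiguous
  expect_equal(b1$unamb_fh, 0L)
  # PS unambiguous iff detected
  a2 <- sd$records[sd$records$site_id == "A2", ]
  expect_equal(a2$unamb_ps, a2$det_ps)
})

test_that("empty records file with valid header reads cleanly", {
  fx <- write_obs_fixture()
  empty <- readr::read_csv(fx$obs, show_col_types = FALSE)[0, ]
  fe <- file.path(fx$dir, "empty.csv")
  readr::write_csv(empty, fe)
  sd <- read_survey_table(fe, fx$sites, fx$climate, years = 2018:2020)
  expect_s3_class(sd, "pika_survey")
  expect_equal(nrow(sd$records), 0)
})

test_that("schema and integrity violations raise typed errors", {
  fx <- write_obs_fixture()
  obs <- readr::read_csv(fx$obs, show_col_types = FALSE)
  # missing required column named in the error
  fb <- file.path(fx$dir, "bad.csv")
  readr::write_csv(obs[, setdiff(names(obs), "sign_code")], fb)
  expect_error(read_survey_table(fb, fx$sites, fx$climate),
               "sign_code", class = "pika_schema_error")
  # unknown sign code
  obs2 <- obs
  obs2$sign_code[1] <- "XX"
  readr::write_csv(obs2, fb)
  expect_error(read_survey_table(fb, fx$sites, fx$climate),
               "XX", class = "pika_parse_error")
  # duplicate survey rows in the survey-level constructor
  rec <- tiny_records()
  expect_error(survey_data(rbind(rec, rec[1, ]), tiny_sites(),
                           tiny_climate(), years = 2018:2020),
               class = "pika_integrity_error")
  # unambiguous flag without detection
  rec2 <- tiny_records()
  rec2$unamb_fs[3] <- 1L
  expect_error(survey_data(rec2, tiny_sites(), tiny_climate(),
                           years = 2018:2020),
               class = "pika_integrity_error")
})

test_that("ambiguity classification follows the keyword and co-occurrence rules", {
  expect_equal(
    classify_ambiguity(c(FS = 1, FH = 0, PC = 0, PS = 0),
                       "scat stacked in small tower")[["FS"]], 1L)
  # stems match inflected forms, case-insensitively
  expect_equal(
    classify_ambiguity(c(FS = 1, FH = 0, PC = 0, PS = 0),
                       "Perched pellets on boulder")[["FS"]], 1L)
  # no keyword, no co-occurrence: ambiguous
  expect_equal(
    classify_ambiguity(c(FS = 1, FH = 0, PC = 0, PS = 0),
                       "loose pellets")[["FS"]], 0L)
  # FH in the same survey upgrades FS even with no notes
  expect_equal(
    classify_ambiguity(c(FS = 1, FH = 1, PC = 0, PS = 0))[["FS"]], 1L)
  # haypile notes never make FH unambiguous
  expect_equal(
    classify_ambiguity(c(FS = 0, FH = 1, PC = 0, PS = 0),
                       "large fresh haypile")[["FH"]], 0L)
  # word-boundary: "towering cliff" matches the stem, "stower" must not
  expect_equal(
    classify_ambiguity(c(FS = 1, FH = 0, PC = 0, PS = 0),
                       "stower xyz")[["FS"]], 0L)
  expect_equal(
    classify_ambiguity(c(FS = 0, FH = 0, PC = 0, PS = 1))[["PS"]], 1L)
  # absent notes treated as ambiguous, no error
  expect_equal(
    classify_ambiguity(c(FS = 1, FH = 0, PC = 0, PS = 0), NA)[["FS"]], 0L)
})

test_that("covariate preprocessing standardizes, centers and records scaling", {
  sd <- preprocess_covariates(tiny_survey())
  # forb (10, 20, 30) -> exactly (-1, 0, 1): sd is 10
  expect_equal(sd$sites$forb, c(-1, 0, 1))
  expect_equal(mean(sd$sites$rock), 0, tolerance = 1e-8)
  expect_equal(stats::sd(sd$sites$rock), 1, tolerance = 1e-8)
  # complexity labels (low, high, intermediate) -> (-1, +1, 0)
  expect_equal(sd$sites$complexity, c(-1, 1, 0))
  # climate standardized over site-years
  expect_equal(mean(sd$climate$tmaxmean), 0, tolerance = 1e-8)
  expect_equal(stats::sd(sd$climate$precip), 1, tolerance = 1e-8)
  expect_true(all(c("forb", "tmaxmean") %in% sd$scaling$covariate))
})

test_that("preprocessing is idempotent and flags degenerate covariates", {
  sd1 <- preprocess_covariates(tiny_survey())
  sd2 <- preprocess_covariates(sd1)
  expect_equal(sd2$sites$forb, sd1$sites$forb, tolerance = 1e-10)
  expect_equal(sd2$climate$precip, sd1$climate$precip, tolerance = 1e-10)
  expect_equal(sd2$sites$complexity, sd1$sites$complexity)

  raw <- tiny_survey()
  raw$sites$shrub <- rep(40, 3)
  expect_error(preprocess_covariates(raw), "shrub",
               class = "pika_zero_variance_error")
})

test_that("missing complexity is imputed at the neutral level and flagged", {
  raw <- tiny_survey()
  raw$sites$complexity[2] <- NA
  sd <- preprocess_covariates(raw)
  expect_equal(sd$sites$complexity[2], 0)
  expect_true(sd$sites$complexity_missing[2])
  expect_false(any(sd$sites$complexity_missing[-2]))
  # flag survives a second preprocessing pass
  sd2 <- preprocess_covariates(sd)
  expect_true(sd2$sites$complexity_missing[2])
})

test_that("collinear covariate pairs trigger a warning naming the pair", {
  raw <- tiny_survey()
  raw$sites$rock <- raw$sites$forb * 1.01 + 0.2
  expect_warning(preprocess_covariates(raw), "forb~rock",
                 class = "pika_collinearity_warning")
})

test_that("encoding produces aligned arrays with latent-only gap years", {
  arr <- suppressWarnings(encode_surveys(tiny_survey()))
  expect_equal(arr$nsite, 3)
  expect_equal(arr$nyear, 3)
  # A1 surveyed 2018 and 2020 only: no survey rows for 2019
  a1 <- which(arr$site_id == "A1")
  expect_equal(sort(arr$years[arr$surveys$year_idx[arr$surveys$site == a1]]),
               c(2018L, 2018L, 2020L))
  # per-sign detection totals equal the record totals
  rec <- tiny_records()
  expect_equal(unname(colSums(arr$y)),
               unname(colSums(as.matrix(rec[, c("det_fs", "det_fh",
                                                "det_pc", "det_ps")]))))
  # u <= y everywhere, FH and PC columns identically zero
  expect_true(all(arr$u <= arr$y))
  expect_true(all(arr$u[, c("FH", "PC")] == 0))
})

test_that("encoding an empty table yields zero-size arrays without error", {
  empty <- survey_data(tiny_records()[0, ], tiny_sites(), tiny_climate(),
                       years = 2018:2020)
  arr <- suppressWarnings(encode_surveys(empty))
  expect_equal(nrow(arr$surveys), 0)
  expect_equal(nrow(arr$y), 0)
  expect_equal(arr$nsite, 3)
})

test_that("write/read round-trip reproduces detection and ambiguity arrays", {
  sd <- tiny_survey()
  dir <- withr::local_tempdir()
  write_survey_table(sd, dir)
  back <- read_survey_table(file.path(dir, "surveys.csv"),
                            file.path(dir, "sites.csv"),
                            file.path(dir, "climate.csv"),
                            years = 2018:2020)
  a1 <- suppressWarnings(encode_surveys(sd))
  a2 <- suppressWarnings(encode_surveys(back))
  expect_equal(a2$y, a1$y)
  expect_equal(a2$u, a1$u)
  expect_equal(a2$surveys, a1$surveys)
  # decode reproduces the record tibble's modeled fields
  dec <- decode_surveys(a1)
  expect_equal(dec$det_fs, sd$records$det_fs[order(sd$records$site_id,
                                                   sd$records$year,
                                                   sd$records$survey_index)])
})
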