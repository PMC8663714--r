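# Interchange schemas: validated readers and writers for the three input
# tables (daily campaign schedule, participant table, cost ledger) and the
# result tables produced by the modelling and metrics layers. Validation is
# total -- every malformed cell is reported with row/column coordinates,
# nothing is silently coerced.

.schema_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("recruitlag_schema_error", "recruitlag_error"))
}

.check_columns <- function(x, required, what) {
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    .schema_error("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", "))
  }
}

.check_nonneg_numeric <- function(x, cols, what) {
  for (col in cols) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      .schema_error("%s column '%s' must be numeric", what, col)
    }
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      .schema_error("%s has a missing or non-finite value at row %d, column '%s'",
                    what, bad[1], col)
    }
    neg <- which(v < 0)
    if (length(neg) > 0) {
      .schema_error("%s has a negative value (%g) at row %d, column '%s'",
                    what, v[neg[1]], neg[1], col)
    }
  }
  invisible(x)
}

#' Validate (and optionally zero-fill) a daily campaign schedule
#'
#' A campaign schedule has one row per study day and one column per campaign
#' channel; `day_index` is 0-based and must be contiguous `0..T-1`. All
#' intensities must be finite and nonnegative: `paid_fb_reach` is persons
#' reached that day (0 on days with no paid campaign), the other eight
#' channels are event counts.
#'
#' @param x A data frame with columns `day_index` and the nine channels of
#'   [recruit_channels()].
#' @param expected_days Optional total number of study days `T`. Days absent
#'   from `x` are filled with all-zero rows so sparse event logs can be read
#'   directly.
#' @return A validated tibble ordered by `day_index`.
#' @export
#' @examples
#' validate_campaign_schedule(empty_campaign_schedule(5))
validate_campaign_schedule <- function(x, expected_days = NULL) {
  what <- "campaign schedule"
  x <- as_tibble(x)
  .check_columns(x, c("day_index", .CHANNELS), what)
  x <- x[, c("day_index", .CHANNELS)]
  if (nrow(x) > 0) {
    .check_nonneg_numeric(x, c("day_index", .CHANNELS), what)
    if (any(x$day_index != floor(x$day_index))) {
      .schema_error("%s day_index must be integer-valued", what)
    }
  }
  dup <- x$day_index[duplicated(x$day_index)]
  if (length(dup) > 0) {
    .schema_error("%s has duplicate day_index %d", what, as.integer(dup[1]))
  }
  if (!is.null(expected_days)) {
    expected_days <- as.integer(expected_days)
    if (nrow(x) > 0 && any(x$day_index >= expected_days)) {
      .schema_error("%s day_index exceeds expected_days - 1 = %d", what,
                    expected_days - 1L)
    }
    missing_days <- setdiff(seq_len(expected_days) - 1L, x$day_index)
    if (length(missing_days) > 0) {
      fill <- empty_campaign_schedule(expected_days)
      fill <- fill[fill$day_index %in% missing_days, ]
      x <- bind_rows(x, fill)
    }
  } else if (nrow(x) > 0 &&
             !identical(as.integer(sort(x$day_index)),
                        seq_len(nrow(x)) - 1L)) {
    .schema_error("%s day_index must be contiguous 0..T-1", what)
  }
  x$day_index <- as.integer(x$day_index)
  arrange(x, .data$day_index)
}

#' An all-zero campaign schedule
#'
#' @param days Number of study days.
#' @return A tibble with `days` rows, `day_index = 0..days-1`, every channel 0.
#' @export
empty_campaign_schedule <- function(days) {
  days <- as.integer(days)
  out <- tibble(day_index = seq_len(days) - 1L)
  for (ch in .CHANNELS) out[[ch]] <- 0
  out
}

#' Read a daily campaign schedule from CSV
#'
#' @inheritParams validate_campaign_schedule
#' @param path Path to a CSV file with a header row naming `day_index` and
#'   the nine channel columns.
#' @return A validated schedule tibble (see [validate_campaign_schedule()]).
#' @export
read_campaign_schedule <- function(path, expected_days = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "recruitlag_error")
  }
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  validate_campaign_schedule(x, expected_days = expected_days)
}

.PARTICIPANT_COLS <- c(
  "participant_id", "city", "method", "eligibility_date", "health_date",
  "eligible", "participation_option", "age_years", "gender", "income_band",
  "education", "ethnicity", "mail_group"
)

.check_levels <- function(x, col, levels, what) {
  v <- x[[col]]
  bad <- which(!is.na(v) & !(v %in% levels))
  if (length(bad) > 0) {
    .schema_error("%s has unknown %s '%s' at row %d", what, col,
                  as.character(v[bad[1]]), bad[1])
  }
  invisible(x)
}

#' Validate a participant-level recruitment table
#'
#' Enforces the participant schema: known city/method/demographic labels,
#' ISO calendar dates, `health_date >= eligibility_date`, and the rule that a
#' completed health questionnaire implies eligibility. A *completer* is a row
#' with a non-missing `health_date`.
#'
#' @param x A data frame with columns `participant_id`, `city`, `method`,
#'   `eligibility_date`, `health_date`, `eligible`, `participation_option`,
#'   and the optional demographics `age_years`, `gender`, `income_band`,
#'   `education`, `ethnicity`, `mail_group`.
#' @return A validated tibble with dates as `Date` columns.
#' @export
validate_participants <- function(x) {
  what <- "participant table"
  x <- as_tibble(x)
  .check_columns(x, setdiff(.PARTICIPANT_COLS, "mail_group"), what)
  if (!"mail_group" %in% names(x)) x$mail_group <- NA_character_
  x <- x[, .PARTICIPANT_COLS]
  for (col in c("eligibility_date", "health_date")) {
    if (is.character(x[[col]])) {
      parsed <- as.Date(x[[col]], format = "%Y-%m-%d")
      bad <- which(!is.na(x[[col]]) & x[[col]] != "" & is.na(parsed))
      if (length(bad) > 0) {
        .schema_error("%s has unparseable date '%s' at row %d, column '%s'",
                      what, x[[col]][bad[1]], bad[1], col)
      }
      x[[col]] <- parsed
    }
    if (nrow(x) > 0 && !inherits(x[[col]], "Date")) {
      .schema_error("%s column '%s' must hold calendar dates", what, col)
    }
  }
  bad <- which(is.na(x$eligibility_date))
  if (length(bad) > 0) {
    .schema_error("%s is missing eligibility_date at row %d", what, bad[1])
  }
  .check_levels(x, "city", .CITIES, what)
  .check_levels(x, "method", .METHODS, what)
  .check_levels(x, "participation_option", .PARTICIPATION, what)
  .check_levels(x, "gender", .GENDERS, what)
  .check_levels(x, "income_band", .INCOME_BANDS, what)
  .check_levels(x, "education", .EDUCATION, what)
  .check_levels(x, "ethnicity", .ETHNICITY, what)
  .check_levels(x, "mail_group", .MAIL_GROUPS, what)
  bad <- which(is.na(x$method))
  if (length(bad) > 0) {
    .schema_error("%s is missing method at row %d", what, bad[1])
  }
  if (!is.logical(x$eligible)) {
    .schema_error("%s column 'eligible' must be logical", what)
  }
  bad_age <- which(!is.na(x$age_years) &
                     (x$age_years < 18 | x$age_years > 120 |
                        x$age_years != floor(x$age_years)))
  if (length(bad_age) > 0) {
    .schema_error("%s has invalid age_years (%s) at row %d", what,
                  as.character(x$age_years[bad_age[1]]), bad_age[1])
  }
  bad <- which(!is.na(x$health_date) & x$health_date < x$eligibility_date)
  if (length(bad) > 0) {
    .schema_error(
      "participant '%s': health_date precedes eligibility_date",
      x$participant_id[bad[1]]
    )
  }
  bad <- which(!is.na(x$health_date) & !x$eligible)
  if (length(bad) > 0) {
    .schema_error(
      "participant '%s': completed health questionnaire but not flagged eligible",
      x$participant_id[bad[1]]
    )
  }
  x$age_years <- as.integer(x$age_years)
  x
}

#' Read a participant table from CSV
#'
#' @param path Path to a CSV file; dates are ISO-8601 (`YYYY-MM-DD`), a blank
#'   `health_date` marks a non-completer.
#' @return A validated participant tibble (see [validate_participants()]).
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "recruitlag_error")
  }
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    city = readr::col_character(),
    method = readr::col_character(),
    eligibility_date = readr::col_date(format = "%Y-%m-%d"),
    health_date = readr::col_date(format = "%Y-%m-%d"),
    eligible = readr::col_logical(),
    participation_option = readr::col_character(),
    age_years = readr::col_integer(),
    gender = readr::col_character(),
    income_band = readr::col_character(),
    education = readr::col_character(),
    ethnicity = readr::col_character(),
    mail_group = readr::col_character()
  ))
  validate_participants(x)
}

.ACTIVITY_KINDS <- c("fb_post", "in_person_event", "media_publication",
                     "partner_post", "letter_campaign", "snowball_campaign")

#' Read a recruitment cost ledger from CSV
#'
#' One row per (city, method): material cost, transmission cost and counted
#' staff activities. Activity columns absent from the file default to 0.
#'
#' @param path Path to a CSV with columns `city`, `method`, `material_cost`,
#'   `transmission_cost` and optionally the activity kinds
#'   `fb_post`, `in_person_event`, `media_publication`, `partner_post`,
#'   `letter_campaign`, `snowball_campaign`.
#' @return A validated ledger tibble.
#' @export
read_cost_ledger <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "recruitlag_error")
  }
  x <- readr::read_csv(path, col_types = readr::cols(
    city = readr::col_character(),
    method = readr::col_character(),
    .default = readr::col_double()
  ))
  validate_cost_ledger(x)
}

#' @rdname read_cost_ledger
#' @param x A data frame to validate in place of reading a file.
#' @export
validate_cost_ledger <- function(x) {
  what <- "cost ledger"
  x <- as_tibble(x)
  .check_columns(x, c("city", "method", "material_cost", "transmission_cost"), what)
  .check_levels(x, "city", .CITIES, what)
  .check_levels(x, "method", .METHODS, what)
  for (kind in .ACTIVITY_KINDS) {
    if (!kind %in% names(x)) x[[kind]] <- 0
  }
  x <- x[, c("city", "method", "material_cost", "transmission_cost", .ACTIVITY_KINDS)]
  .check_nonneg_numeric(x, c("material_cost", "transmission_cost", .ACTIVITY_KINDS), what)
  dup <- duplicated(x[, c("city", "method")])
  if (any(dup)) {
    i <- which(dup)[1]
    .schema_error("%s has duplicate entry for (%s, %s)", what, x$city[i], x$method[i])
  }
  x
}

#' Read an analysis configuration file
#'
#' YAML (or JSON) configuration holding the accounting and calendar settings
#' that are study choices rather than package constants: the staff
#' `hourly_rate` (CAD/h, required by costing, no default), the `cad_to_usd`
#' conversion factor (default 0.7692) and `recruitment_start_date`, which
#' anchors `day_index = 0` to a calendar date.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `hourly_rate`, `cad_to_usd`,
#'   `recruitment_start_date`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "recruitlag_error")
  }
  cfg <- yaml::read_yaml(path)
  out <- list(
    hourly_rate = cfg$hourly_rate %||% NULL,
    cad_to_usd = cfg$cad_to_usd %||% 0.7692,
    recruitment_start_date =
      if (!is.null(cfg$recruitment_start_date)) as.Date(cfg$recruitment_start_date) else NULL
  )
  if (!is.null(out$hourly_rate) && (!is.numeric(out$hourly_rate) || out$hourly_rate < 0)) {
    .schema_error("config hourly_rate must be a nonnegative number")
  }
  out
}

#' Write result tables as deterministic CSV files
#'
#' Writes each table in `tables` to `<out_dir>/<name>.csv` with stable column
#' order and fixed 6-decimal formatting for floating-point columns, so that
#' repeated runs over identical inputs are byte-identical and diffable.
#'
#' @param tables A named list of data frames (the names become file names).
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, the vector of written file paths.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(names(tables) != ""))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory: %s", out_dir),
                   class = "recruitlag_error")
  }
  paths <- character(0)
  for (name in names(tables)) {
    tab <- as_tibble(tables[[name]])
    for (col in names(tab)) {
      if (is.double(tab[[col]])) {
        v <- tab[[col]]
        tab[[col]] <- ifelse(is.na(v), NA_character_,
                             ifelse(is.infinite(v), ifelse(v > 0, "Inf", "-Inf"),
                                    sprintf("%.6f", v)))
      }
    }
    path <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tab, path, na = "")
    paths <- c(paths, path)
  }
  invisible(paths)
}
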