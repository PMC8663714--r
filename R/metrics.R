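# Recruitment-effectiveness indicators: completion rates, completion delays,
# cost per completer with staff-time accounting, and demographic composition
# by recruitment method. A "completer" is an eligible recruit with a
# completed health questionnaire (non-missing health_date).

.group_cols <- function(by) {
  allowed <- c("method", "city", "mail_group", "participation_option")
  bad <- setdiff(by, allowed)
  if (length(bad) > 0) {
    abort(sprintf("cannot group by: %s", paste(bad, collapse = ", ")),
          class = "recruitlag_error")
  }
  by
}

#' Health-questionnaire completion rate by group
#'
#' Completers divided by eligible recruits, as a percentage. Groups are
#' formed from the rows present in the data; a group with eligible recruits
#' but no completers gets rate 0, while a rate over zero eligible recruits is
#' reported as missing rather than 0.
#'
#' @param participants A validated participant table.
#' @param by Grouping columns: any of `"method"`, `"city"`, `"mail_group"`,
#'   `"participation_option"`, or a combination such as
#'   `c("city", "method")`. Use `by = character(0)` for the overall rate.
#' @return A tibble with the grouping columns plus `n_recruited`,
#'   `n_completers`, `completion_rate` (percent, unrounded).
#' @export
completion_rate <- function(participants, by = "method") {
  by <- .group_cols(by)
  eligible <- filter(participants, .data$eligible)
  out <- eligible |>
    group_by(across(all_of(by))) |>
    summarise(
      n_recruited = n(),
      n_completers = sum(!is.na(.data$health_date)),
      .groups = "drop"
    ) |>
    mutate(completion_rate = if_else(.data$n_recruited > 0,
                                     100 * .data$n_completers / .data$n_recruited,
                                     NA_real_))
  out
}

#' Completion delay by group
#'
#' Whole days between eligibility- and health-questionnaire completion,
#' among completers only; same-day completion counts as 0 days. The SD is
#' the sample standard deviation (n - 1) and is missing for groups with a
#' single completer.
#'
#' @inheritParams completion_rate
#' @return A tibble with the grouping columns plus `n_completers`,
#'   `delay_mean`, `delay_sd` (days).
#' @export
completion_delay <- function(participants, by = "method") {
  by <- .group_cols(by)
  completers <- filter(participants, !is.na(.data$health_date))
  completers |>
    mutate(delay = as.numeric(.data$health_date - .data$eligibility_date)) |>
    group_by(across(all_of(by))) |>
    summarise(
      n_completers = n(),
      delay_mean = mean(.data$delay),
      delay_sd = sd(.data$delay),
      .groups = "drop"
    )
}

#' Staff-time schedule (hours per activity)
#'
#' The default accounting constants: 0.5 h per Facebook post, 4 h per
#' in-person event, 2 h per media publication, 2 h per partner post, 50 h for
#' a mailed-letter campaign and 35 h for a snowball campaign. Override any
#' entry to reflect a different staffing model.
#'
#' @param ... Named overrides, e.g. `fb_post = 1`.
#' @return Named numeric vector of hours per activity kind.
#' @export
#' @examples
#' staff_time_schedule()
staff_time_schedule <- function(...) {
  hours <- c(
    fb_post = 0.5, in_person_event = 4, media_publication = 2,
    partner_post = 2, letter_campaign = 50, snowball_campaign = 35
  )
  overrides <- c(...)
  if (length(overrides) > 0) {
    unknown <- setdiff(names(overrides), names(hours))
    if (length(unknown) > 0) {
      abort(sprintf("unknown activity kind(s): %s", paste(unknown, collapse = ", ")),
            class = "recruitlag_error")
    }
    hours[names(overrides)] <- overrides
  }
  if (any(hours < 0)) abort("staff hours must be nonnegative", class = "recruitlag_error")
  hours
}

#' Staff hours implied by counted activities
#'
#' @param activities Named numeric vector of activity counts (names from
#'   `staff_time_schedule()`).
#' @param hours A staff-time schedule.
#' @return Total hours (numeric scalar).
#' @export
#' @examples
#' staff_hours(c(fb_post = 44)) # 22 hours
staff_hours <- function(activities, hours = staff_time_schedule()) {
  if (length(activities) == 0) return(0)
  unknown <- setdiff(names(activities), names(hours))
  if (is.null(names(activities)) || length(unknown) > 0) {
    abort(sprintf("unknown activity kind(s): %s",
                  paste(if (is.null(names(activities))) "<unnamed>" else unknown,
                        collapse = ", ")),
          class = "recruitlag_error")
  }
  if (any(activities < 0)) {
    abort("activity counts must be nonnegative", class = "recruitlag_error")
  }
  sum(activities * hours[names(activities)])
}

#' Cost per completer by city and method
#'
#' Per (city, method) cell: material cost + transmission cost + staff time
#' valued at `hourly_rate`, divided by the cell's completer count.
#' Compensation and prize expenses are deliberately out of scope of the
#' ledger. Cells with completers but zero cost are 0; cells with nonzero
#' cost and zero completers are reported as infinite and `flagged`, and are
#' excluded from pooled summaries; zero cost over zero completers is
#' missing.
#'
#' @param ledger A validated cost ledger (see [read_cost_ledger()]).
#' @param completers Completer counts per (city, method): a tibble with
#'   columns `city`, `method`, `n_completers` — e.g.
#'   `completion_rate(participants, by = c("city", "method"))`.
#' @param hourly_rate Staff hourly rate in CAD/h. Required: the package
#'   ships no default wage.
#' @param hours A staff-time schedule, see [staff_time_schedule()].
#' @param cad_to_usd CAD to USD conversion factor (default 0.7692).
#' @return A tibble with `city`, `method`, `n_completers`, `staff_hours_total`,
#'   `cost_total`, `cost_per_completer`, `cost_per_completer_usd`, `flagged`.
#' @export
cost_per_completer <- function(ledger, completers, hourly_rate,
                               hours = staff_time_schedule(),
                               cad_to_usd = 0.7692) {
  ledger <- validate_cost_ledger(ledger)
  .check_columns(completers, c("city", "method", "n_completers"), "completer counts")
  if (!is.numeric(hourly_rate) || length(hourly_rate) != 1 || hourly_rate < 0) {
    abort("hourly_rate must be a single nonnegative number (CAD/h)",
          class = "recruitlag_error")
  }
  act <- as.matrix(ledger[, .ACTIVITY_KINDS])
  ledger$staff_hours_total <- drop(act %*% hours[.ACTIVITY_KINDS])
  out <- ledger |>
    left_join(completers[, c("city", "method", "n_completers")],
              by = c("city", "method")) |>
    mutate(
      n_completers = if_else(is.na(.data$n_completers), 0L,
                             as.integer(.data$n_completers)),
      cost_total = .data$material_cost + .data$transmission_cost +
        .data$staff_hours_total * hourly_rate,
      cost_per_completer = dplyr::case_when(
        n_completers > 0 ~ cost_total / n_completers,
        cost_total > 0 ~ Inf,
        TRUE ~ NA_real_
      ),
      flagged = .data$n_completers == 0 & .data$cost_total > 0,
      cost_per_completer_usd = .data$cost_per_completer * cad_to_usd
    ) |>
    select("city", "method", "n_completers", "staff_hours_total", "cost_total",
           "cost_per_completer", "cost_per_completer_usd", "flagged")
  out
}

#' Completer-weighted pooling of per-cell costs
#'
#' The pooled cost per completer over a set of cells is the completer-
#' weighted mean of the cell values, so that pooled value times total
#' completers equals the summed cell costs exactly.
#'
#' @param values Per-cell cost-per-completer values.
#' @param n_completers Per-cell completer counts (the weights).
#' @return Pooled cost per completer.
#' @export
#' @examples
#' pool_cost_per_completer(c(26.52, 10.85, 23.80), c(1158, 315, 318))
pool_cost_per_completer <- function(values, n_completers) {
  keep <- !is.na(values) & is.finite(values) & n_completers > 0
  if (!any(keep)) return(NA_real_)
  sum(values[keep] * n_completers[keep]) / sum(n_completers[keep])
}

#' Pool a per-(city, method) cost table over cities
#'
#' @param cost A table from [cost_per_completer()].
#' @return One row per method: pooled `cost_per_completer` (and USD),
#'   `n_completers`. Flagged (infinite) cells are excluded.
#' @export
cost_by_method <- function(cost) {
  .check_columns(cost, c("method", "n_completers", "cost_per_completer", "flagged"),
                 "cost table")
  cost |>
    filter(!.data$flagged) |>
    group_by(.data$method) |>
    summarise(
      cost_per_completer = pool_cost_per_completer(.data$cost_per_completer,
                                                   .data$n_completers),
      n_completers = sum(.data$n_completers),
      .groups = "drop"
    ) |>
    select("method", "n_completers", "cost_per_completer") |>
    mutate(cost_per_completer_usd = .data$cost_per_completer * 0.7692)
}

#' Demographic composition of completers by recruitment method
#'
#' Counts and column percentages of completers by method for age bands
#' (18-34, 35-54, 55-64, 65-88 derived from `age_years`), gender, income
#' band, education and ethnicity, plus a pooled `total` column. Percentages
#' use the method's full completer count as denominator; missing responses
#' are tallied separately per variable as level `"(missing)"`.
#'
#' @param participants A validated participant table.
#' @return A long tibble: `variable`, `level`, `method` (including
#'   `"total"`), `n`, `pct`.
#' @export
demographic_crosstab <- function(participants) {
  completers <- filter(participants, !is.na(.data$health_date))
  vars <- list(
    age = list(values = as.character(.age_band(completers$age_years)),
               levels = .AGE_BANDS),
    gender = list(values = completers$gender, levels = .GENDERS),
    income = list(values = completers$income_band, levels = .INCOME_BANDS),
    education = list(values = completers$education, levels = .EDUCATION),
    ethnicity = list(values = completers$ethnicity, levels = .ETHNICITY)
  )
  methods <- c(.METHODS, "total")
  totals <- c(table(factor(completers$method, levels = .METHODS)))
  totals <- c(totals, total = nrow(completers))
  rows <- list()
  for (vn in names(vars)) {
    v <- vars[[vn]]
    lv <- factor(ifelse(is.na(v$values), "(missing)", v$values),
                 levels = c(v$levels, "(missing)"))
    for (m in methods) {
      inm <- if (m == "total") rep(TRUE, nrow(completers)) else completers$method == m
      counts <- c(table(lv[inm]))
      denom <- totals[[m]]
      rows[[length(rows) + 1L]] <- tibble(
        variable = vn, level = names(counts), method = m,
        n = as.integer(counts),
        pct = if (denom > 0) 100 * as.integer(counts) / denom else NA_real_
      )
    }
  }
  bind_rows(rows)
}
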