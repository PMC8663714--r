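# Deterministic fixture: a participant table and cost ledger whose marginal
# counts equal the published study tables cell by cell, so the metric suite
# can be exercised (and checked against the printed values) without any
# participant-level data. Everything is enumerated; no randomness.

#' Fixture specification
#'
#' The cell-level counts the deterministic fixture reproduces: recruited and
#' completer counts per (city, method), completer demographics per method,
#' per-cell cost-per-completer values, per-city average costs, mailed-letter
#' arm group sizes and participation-option counts. Defaults are the
#' published study tables; any component can be overridden for testing.
#'
#' @param recruited,completers 3 x 6 integer matrices (cities x methods).
#' @param demographics Named list of level-by-method count matrices (levels
#'   include a `"(missing)"` row).
#' @param cost_cells 3 x 6 matrix of cost-per-completer (CAD), `NA` where a
#'   cell has no completers.
#' @param city_cost Named per-city average cost per completer (CAD). Part of
#'   the study's own accounting; not derivable from `cost_cells` (the
#'   city-level books included uncategorised items).
#' @param mail_groups Named sizes of the Montreal mailed-letter arms A/B/C,
#'   allocated over that cell's recruits.
#' @param participation 3 x 4 matrix of recruited counts by participation
#'   option.
#' @param completer_delay_days Constant whole-day delay given to every
#'   fixture completer (an arbitrary valid value; the fixture serves
#'   count-based checks, not delay estimation).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(recruited = NULL, completers = NULL,
                         demographics = NULL, cost_cells = NULL,
                         city_cost = NULL, mail_groups = NULL,
                         participation = NULL, completer_delay_days = 7L) {
  structure(list(
    recruited = recruited %||% .RECRUITED,
    completers = completers %||% .COMPLETERS,
    demographics = demographics %||% .DEMOGRAPHICS,
    cost_cells = cost_cells %||% .COST_CELLS,
    city_cost = city_cost %||% .CITY_COST,
    mail_groups = mail_groups %||% .MAIL_GROUPS_N,
    participation = participation %||% .PARTICIPATION_N,
    completer_delay_days = as.integer(completer_delay_days)
  ), class = "fixture_spec")
}

.fixture_check <- function(cond, identity) {
  if (!cond) {
    abort(sprintf("fixture spec is internally inconsistent: %s", identity),
          class = c("recruitlag_fixture_error", "recruitlag_error"))
  }
}

# block-allocate level labels (incl. NA for "(missing)") over n slots
.alloc_levels <- function(counts) {
  labels <- rep(names(counts), counts)
  ifelse(labels == "(missing)", NA_character_, labels)
}

#' Build the deterministic participant fixture and cost ledger
#'
#' Enumerates one participant row per recruited count cell (completers
#' first), assigns demographics per method in blocks so every published
#' count is matched exactly, allocates the Montreal mailed-letter arm groups
#' over that cell's recruits, and back-solves the cost ledger so that
#' [cost_per_completer()] with the configured staff rate reproduces every
#' per-cell cost exactly (with the default rate of 0, the full amount sits
#' in `material_cost`, so no wage has to be invented).
#'
#' @param spec A [fixture_spec()].
#' @param hourly_rate Staff rate (CAD/h) the ledger is calibrated against.
#' @return A list of class `recruit_fixture`: `participants` (validated
#'   tibble), `cost_ledger`, `city_cost_summary` (tibble with `city`,
#'   `n_completers`, `cost_per_completer`), `hourly_rate`.
#' @export
#' @examples
#' fx <- build_fixture()
#' sum(!is.na(fx$participants$health_date)) # 1791 completers
build_fixture <- function(spec = fixture_spec(), hourly_rate = 0) {
  stopifnot(inherits(spec, "fixture_spec"))
  R <- spec$recruited
  C <- spec$completers
  .fixture_check(identical(dim(R), dim(C)),
                 "recruited and completer matrices differ in shape")
  .fixture_check(all(C <= R), "completers exceed recruited in some cell")
  for (vn in names(spec$demographics)) {
    tab <- spec$demographics[[vn]]
    ok <- all(colSums(tab) == colSums(C)[colnames(tab)])
    .fixture_check(ok, sprintf(
      "demographic table '%s' column sums do not equal per-method completers", vn))
  }
  .fixture_check(all(is.na(spec$cost_cells) == (C == 0)),
                 "cost cells must be NA exactly where a cell has no completers")
  .fixture_check(sum(spec$mail_groups) == R["Montreal", "mailed_letters"],
                 "mail-group sizes must sum to Montreal mailed-letter recruits")
  .fixture_check(all(rowSums(spec$participation) == rowSums(R)),
                 "participation-option rows must sum to city recruited totals")

  cities <- rownames(R)
  methods <- colnames(R)
  rows <- list()
  for (city in cities) {
    for (m in methods) {
      n_r <- R[city, m]
      if (n_r == 0) next
      n_c <- C[city, m]
      completer <- c(rep(TRUE, n_c), rep(FALSE, n_r - n_c))
      start <- as.Date(.START_DATES[[city]])
      elig <- start + (seq_len(n_r) - 1L) %% 199L
      rows[[length(rows) + 1L]] <- tibble(
        city = city, method = m,
        eligibility_date = elig,
        health_date = as.Date(ifelse(completer,
                                     elig + spec$completer_delay_days, NA),
                              origin = "1970-01-01"),
        eligible = TRUE
      )
    }
  }
  participants <- bind_rows(rows)
  participants$participant_id <- sprintf("F%04d", seq_len(nrow(participants)))

  # demographics: per method, over that method's completers in enumeration
  # order (cities in matrix order), block-allocated to match every count
  is_completer <- !is.na(participants$health_date)
  for (vn in names(spec$demographics)) {
    col <- rep(NA_character_, nrow(participants))
    tab <- spec$demographics[[vn]]
    for (m in methods) {
      idx <- which(participants$method == m & is_completer)
      col[idx] <- .alloc_levels(tab[, m])
    }
    participants[[paste0(".", vn)]] <- col
  }
  participants$age_years <-
    as.integer(.AGE_BAND_REP[participants$.age])
  participants$gender <- participants$.gender
  participants$income_band <- participants$.income
  participants$education <- participants$.education
  participants$ethnicity <- participants$.ethnicity
  participants <- select(participants, -dplyr::starts_with("."))

  # participation options: block-allocated per city over all recruits
  participants$participation_option <- NA_character_
  for (city in cities) {
    idx <- which(participants$city == city)
    counts <- spec$participation[city, ]
    participants$participation_option[idx] <- rep(colnames(spec$participation), counts)
  }

  # mailed-letter arm groups over Montreal letter recruits, completers first
  participants$mail_group <- NA_character_
  idx <- which(participants$city == "Montreal" &
                 participants$method == "mailed_letters")
  participants$mail_group[idx] <- rep(names(spec$mail_groups), spec$mail_groups)

  participants <- validate_participants(
    participants[, .PARTICIPANT_COLS]
  )

  # ledger calibrated so cost/completer reproduces every printed cell:
  # material + transmission = cell * completers - staff_hours * rate; with
  # the default rate of 0 everything is material cost and no activity counts
  # are asserted
  ledger_rows <- list()
  for (city in cities) {
    for (m in methods) {
      cell <- spec$cost_cells[city, m]
      n_c <- C[city, m]
      material <- if (is.na(cell)) 0 else cell * n_c
      ledger_rows[[length(ledger_rows) + 1L]] <- tibble(
        city = city, method = m,
        material_cost = material, transmission_cost = 0
      )
    }
  }
  ledger <- validate_cost_ledger(bind_rows(ledger_rows))

  city_cost_summary <- tibble(
    city = cities,
    n_completers = unname(rowSums(C)),
    cost_per_completer = unname(spec$city_cost[cities])
  )

  structure(
    list(participants = participants, cost_ledger = ledger,
         city_cost_summary = city_cost_summary, hourly_rate = hourly_rate),
    class = "recruit_fixture"
  )
}

#' @export
print.recruit_fixture <- function(x, ...) {
  n <- nrow(x$participants)
  nc <- sum(!is.na(x$participants$health_date))
  cat(sprintf("<recruit_fixture: %d recruits, %d completers, %d ledger cells>\n",
              n, nc, nrow(x$cost_ledger)))
  invisible(x)
}
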