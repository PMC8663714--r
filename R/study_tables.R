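# Published marginal tables of the emulated three-city Canadian cohort
# recruitment effort. These are the study conditions the synthetic generator
# and the deterministic fixture reproduce: recruited/completer counts by
# city and method, completer demographics by method, per-method completion
# delays, per-cell cost-per-completer accounting, and the fitted
# distributed-lag coefficients used as simulation truth.

# recruited (completed eligibility, eligible and willing) by city x method.
# Only the method totals, city totals and per-(city,method) completers are
# published; this integer matrix is the deterministic allocation consistent
# with all of those marginals and the reported per-city letter completion
# rates (see the methods vignette).
.RECRUITED <- matrix(
  c(171, 691, 279, 129, 112, 154,
    10, 121, 5, 134, 25, 107,
    138, 132, 0, 1, 30, 79),
  nrow = 3, byrow = TRUE,
  dimnames = list(.CITIES, .METHODS)
)

# completers (health questionnaire done) by city x method
.COMPLETERS <- matrix(
  c(148, 503, 226, 91, 81, 109,
    0, 88, 4, 126, 18, 79,
    134, 96, 0, 1, 22, 65),
  nrow = 3, byrow = TRUE,
  dimnames = list(.CITIES, .METHODS)
)

# completer demographics by method: counts per level plus missing, columns in
# .METHODS order
.DEMOGRAPHICS <- list(
  age = rbind(
    `18-34` = c(10, 238, 44, 108, 58, 56),
    `35-54` = c(91, 273, 74, 47, 34, 75),
    `55-64` = c(89, 95, 62, 17, 11, 29),
    `65-88` = c(92, 48, 46, 13, 12, 39),
    `(missing)` = c(0, 33, 4, 33, 6, 54)
  ),
  gender = rbind(
    man = c(120, 144, 84, 67, 45, 81),
    woman = c(161, 537, 144, 149, 75, 170),
    other = c(0, 3, 2, 2, 0, 2),
    `(missing)` = c(1, 3, 0, 0, 1, 0)
  ),
  income = rbind(
    cad_0_49999 = c(50, 200, 36, 87, 31, 82),
    cad_50000_99999 = c(79, 212, 91, 38, 41, 56),
    cad_100000_149999 = c(49, 122, 49, 33, 20, 45),
    cad_150000_199999 = c(29, 53, 19, 14, 9, 22),
    cad_200000_plus = c(33, 40, 15, 15, 10, 13),
    `(missing)` = c(42, 60, 20, 31, 10, 35)
  ),
  education = rbind(
    less_than_university = c(94, 142, 26, 63, 21, 74),
    university_degree = c(85, 259, 90, 79, 51, 82),
    graduate_degree = c(100, 282, 113, 70, 49, 94),
    `(missing)` = c(3, 4, 1, 6, 0, 3)
  ),
  ethnicity = rbind(
    white = c(246, 591, 217, 155, 93, 195),
    indigenous = c(2, 10, 0, 5, 1, 11),
    visible_minority = c(31, 81, 11, 55, 23, 42),
    `(missing)` = c(3, 5, 2, 3, 4, 5)
  )
)
for (nm in names(.DEMOGRAPHICS)) colnames(.DEMOGRAPHICS[[nm]]) <- .METHODS
rm(nm)

# representative integer age per band, used when only a band is simulated
.AGE_BAND_REP <- c(`18-34` = 27L, `35-54` = 45L, `55-64` = 60L, `65-88` = 71L)

# per-method completion delay mean/SD in days
.DELAY_STATS <- tibble::tibble(
  method = .METHODS,
  delay_mean = c(9.1, 14.3, 11.8, 13.8, 9.6, 10.6),
  delay_sd = c(29.9, 37.7, 34.6, 31.4, 28.6, 25.8)
)

# cost per completer (CAD) by city x method; NA where the cell has no
# completers
.COST_CELLS <- matrix(
  c(130.80, 13.35, 6.17, 7.32, 16.40, 18.05,
    NA, 16.13, 74.04, 0.88, 0.00, 21.60,
    83.56, 22.91, NA, 347.10, 59.80, 72.70),
  nrow = 3, byrow = TRUE,
  dimnames = list(.CITIES, .METHODS)
)

# published per-city average cost per completer (CAD). These city averages
# are part of the study's own accounting and are NOT the completer-weighted
# means of the per-method cells above (the city-level books included
# uncategorised items); they are carried as their own summary table.
.CITY_COST <- c(Montreal = 26.52, Saskatoon = 10.85, Vancouver = 23.80)

# mailed-letter arm groups (Montreal): A personalised letter + card +
# reminder, B personalised letter + card, C plain postcard
.MAIL_GROUPS_N <- c(A = 75, B = 88, C = 8)

# recruited participants per participation option by city
.PARTICIPATION_N <- matrix(
  c(937, 277, 0, 322,
    225, 67, 13, 97,
    161, 68, 72, 79),
  nrow = 3, byrow = TRUE,
  dimnames = list(.CITIES, .PARTICIPATION)
)

# per-variable missingness rates among completers
.MISSING_RATES <- c(age = 0.0725, gender = 0.0028, income = 0.1105,
                    education = 0.0095, ethnicity = 0.0123)

# city recruitment start dates (calendar anchor for day_index = 0)
.START_DATES <- c(Montreal = "2018-06-06", Saskatoon = "2018-09-19",
                  Vancouver = "2018-04-20")

#' Fitted study coefficients used as simulation truth
#'
#' Intercept 4.3 recruits/day; per-event effects for the identity channels;
#' recruits per log-unit of reach/1000 for `paid_fb_reach`.
#'
#' @return Named numeric vector over [recruit_channels()].
#' @export
default_betas <- function() {
  c(
    letters = 106.5, paid_fb_reach = 1.4, unpaid_fb_posts = 3.2,
    reminders = 16.9, partner_comms = 3.5, snowball = 2.5,
    wide_media = 163.6, small_media = 10.4, other = -1.3
  )
}
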