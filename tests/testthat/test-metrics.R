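test_that("completion rates are completers over eligible recruits", {
  p <- toy_participants(
    rep(c("mailed_letters", "snowball"), c(319, 167)),
    completed = c(rep(TRUE, 282), rep(FALSE, 37), rep(TRUE, 121), rep(FALSE, 46))
  )
  cr <- completion_rate(validate_participants(p))
  letters <- cr[cr$method == "mailed_letters", ]
  expect_equal(round(letters$completion_rate, 1), 88.4)
  expect_equal(round(cr$completion_rate[cr$method == "snowball"], 1), 72.5)
  # ineligible rows are excluded from the denominator
  p$eligible[319 + 167] <- FALSE
  p$health_date[319 + 167] <- NA
  cr2 <- completion_rate(validate_participants(p))
  expect_equal(cr2$n_recruited[cr2$method == "snowball"], 166L)
  # weighted mean of per-method rates recovers the overall rate
  overall <- completion_rate(validate_participants(p), by = character(0))
  expect_equal(
    weighted.mean(cr2$completion_rate, cr2$n_recruited),
    overall$completion_rate
  )
  expect_true(all(cr$completion_rate >= 0 & cr$completion_rate <= 100))
})

test_that("completion delays use whole days with sample SD", {
  elig <- as.Date("2018-06-06")
  p <- validate_participants(toy_participants(rep("other", 3), completed = TRUE))
  p$health_date <- p$eligibility_date + c(0, 10, 20)
  d <- completion_delay(p)
  expect_equal(d$delay_mean, 10)
  expect_equal(d$delay_sd, 10)
  # single completer: SD is absent, not zero
  d1 <- completion_delay(p[2, ])
  expect_equal(d1$delay_mean, 10)
  expect_true(is.na(d1$delay_sd))
  # same-day completion is 0 days
  p0 <- p
  p0$health_date <- p0$eligibility_date
  expect_equal(completion_delay(p0)$delay_mean, 0)
})

test_that("staff hours are a dot product over the activity schedule", {
  expect_equal(staff_hours(c(fb_post = 44)), 22)
  expect_equal(staff_hours(c(letter_campaign = 1)), 50)
  expect_equal(staff_hours(c(snowball_campaign = 1, in_person_event = 2)), 43)
  expect_equal(staff_hours(numeric(0)), 0)
  expect_error(staff_hours(c(skywriting = 1)), "unknown activity")
  # overridable schedule
  expect_equal(staff_hours(c(fb_post = 10), staff_time_schedule(fb_post = 1)), 10)
})

test_that("cost per completer combines materials, transmission and staff time", {
  ledger <- tibble::tibble(
    city = c("Montreal", "Saskatoon"),
    method = "social_media",
    material_cost = c(100, 0),
    transmission_cost = c(50, 0),
    fb_post = c(10, 0)
  )
  completers <- tibble::tibble(
    city = c("Montreal", "Saskatoon"),
    method = "social_media",
    n_completers = c(30L, 5L)
  )
  cost <- cost_per_completer(ledger, completers, hourly_rate = 20)
  mtl <- cost[cost$city == "Montreal", ]
  expect_equal(mtl$staff_hours_total, 5)
  expect_equal(mtl$cost_per_completer, (100 + 50 + 5 * 20) / 30)
  expect_equal(mtl$cost_per_completer_usd, mtl$cost_per_completer * 0.7692)
  # zero cost over completers is zero
  expect_equal(cost$cost_per_completer[cost$city == "Saskatoon"], 0)
  # nonzero cost over zero completers is flagged infinite
  completers$n_completers[1] <- 0L
  cost2 <- cost_per_completer(ledger, completers, hourly_rate = 20)
  expect_true(is.infinite(cost2$cost_per_completer[cost2$city == "Montreal"]))
  expect_true(cost2$flagged[cost2$city == "Montreal"])
})

test_that("pooling is the completer-weighted mean and satisfies the identity", {
  expect_equal(round(pool_cost_per_completer(c(26.52, 10.85, 23.80),
                                             c(1158, 315, 318)), 2), 23.28)
  expect_equal(round(pool_cost_per_completer(c(7.32, 0.88, 347.10),
                                             c(91, 126, 1)), 2), 5.16)
  # pooled value times total completers equals summed cell costs exactly
  v <- c(12.5, 3.25, 88)
  n <- c(7, 19, 2)
  expect_equal(pool_cost_per_completer(v, n) * sum(n), sum(v * n))
  expect_true(is.na(pool_cost_per_completer(c(Inf, NA), c(0, 3))))
})

test_that("the demographic crosstab matches hand-tallied counts", {
  p <- toy_participants(rep(c("social_media", "other"), c(4, 2)),
                        completed = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  p$gender <- c("woman", "woman", "man", "woman", NA, "woman")
  p$age_years <- c(20L, 40L, 60L, 30L, 70L, NA)
  ct <- demographic_crosstab(validate_participants(p))
  sm_women <- ct[ct$variable == "gender" & ct$level == "woman" &
                   ct$method == "social_media", ]
  # completers only: the 4th row never completed
  expect_equal(sm_women$n, 2L)
  expect_equal(sm_women$pct, 100 * 2 / 3)
  # missing tallied separately; column sums equal completers minus missing
  for (m in c("social_media", "other")) {
    g <- ct[ct$variable == "gender" & ct$method == m, ]
    n_comp <- sum(!is.na(p$health_date) & p$method == m)
    expect_equal(sum(g$n[g$level != "(missing)"]),
                 n_comp - g$n[g$level == "(missing)"])
    expect_equal(sum(g$n), n_comp)
  }
  # age bands derived from integer age
  expect_equal(ct$n[ct$variable == "age" & ct$level == "65-88" &
                      ct$method == "other"], 1L)
  # empty input: all-zero crosstab
  ct0 <- demographic_crosstab(validate_participants(p[0, ]))
  expect_true(all(ct0$n == 0))
})
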