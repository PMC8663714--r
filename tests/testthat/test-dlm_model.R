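random_instance <- function(days = NULL, n_channels = NULL) {
  days <- days %||% sample(20:50, 1)
  channels <- sample(setdiff(recruit_channels(), "paid_fb_reach"),
                     n_channels %||% sample(2:4, 1))
  sched <- empty_campaign_schedule(days)
  for (ch in channels) {
    ev <- sample(seq_len(days - 5) - 1L, sample(2:4, 1))
    sched[[ch]][ev + 1L] <- sample(1:3, length(ev), replace = TRUE)
  }
  spec <- lag_spec(setNames(sample(1:4, length(channels), replace = TRUE), channels))
  design <- build_design(sched, spec)
  y <- rpois(days, 5) + drop(as.matrix(design) %*% runif(length(channels), 0, 10))
  list(design = design, y = y, channels = channels)
}

test_that("fit_dlm matches the normal-equations oracle on random instances", {
  set.seed(303)
  for (rep in 1:30) {
    inst <- random_instance()
    fit <- fit_dlm(inst$design, inst$y)
    X <- cbind(1, as.matrix(inst$design))
    oracle <- oracle_ols(X, inst$y)
    expect_equal(fit$coefficients$estimate, unname(oracle$beta), tolerance = 1e-8)
    expect_equal(fit$coefficients$se, unname(oracle$se), tolerance = 1e-8)
    expect_equal(fit$aic, oracle$aic, tolerance = 1e-8)
    expect_equal(fit$bic, oracle$bic, tolerance = 1e-8)
    expect_equal(fit$r_squared, oracle$r2, tolerance = 1e-8)
    # residuals sum to zero and are orthogonal to every design column
    expect_lt(abs(sum(fit$residuals)) / sum(abs(inst$y)), 1e-8)
    expect_true(all(abs(crossprod(X, fit$residuals)) / sum(abs(inst$y)) < 1e-8))
  }
})

test_that("noiseless data are interpolated exactly", {
  set.seed(404)
  sched <- generate_schedule(seed = 11)
  spec <- default_lag_spec()
  design <- build_design(sched, spec)
  truth <- default_betas()
  # baseline high enough that the noiseless series stays nonnegative
  y <- 20 + drop(as.matrix(design) %*% truth[design$channels])
  expect_true(all(y >= 0))
  # lm warns about the (intended) perfect fit
  fit <- suppressWarnings(fit_dlm(design, y))
  expect_equal(fit$coefficients$estimate[1], 20, tolerance = 1e-8)
  expect_equal(setNames(fit$coefficients$estimate[-1], fit$coefficients$term[-1]),
               truth[design$channels], tolerance = 1e-8)
})

test_that("an intercept-only fit returns the mean with R2 = 0", {
  spec <- lag_spec(c(letters = 2))
  sched <- toy_schedule(20, list(letters = list(day = 3, value = 1)))
  design <- build_design(empty_campaign_schedule(20), lag_spec(c(snowball = 1)))
  # snowball column is all zero -> rank deficient, named in the error
  expect_error(fit_dlm(design, rpois(20, 3)), "snowball")
  # a genuinely intercept-only model via lm on the design with no channels
  y <- c(2, 4, 6, 8)
  d <- structure(list(data = tibble::tibble(day_index = 0:3),
                      lag_spec = lag_spec(c(letters = 1))[0, ],
                      channels = character(0)),
                 class = "dlm_design")
  fit <- fit_dlm(d, y)
  expect_equal(fit$coefficients$estimate, mean(y))
  expect_equal(fit$r_squared, 0)
})

test_that("more observations than parameters are required", {
  sched <- toy_schedule(3, list(letters = list(day = 0, value = 1),
                                snowball = list(day = 1, value = 1)))
  design <- build_design(sched, lag_spec(c(letters = 1, snowball = 1)))
  expect_error(fit_dlm(design, c(1, 2, 3)), "observations")
  expect_error(fit_dlm(design, c(1, 2)), "length")
})

test_that("adding a regressor never lowers R-squared", {
  set.seed(505)
  sched1 <- toy_schedule(40, list(letters = list(day = c(3, 20), value = 1)))
  sched2 <- sched1
  sched2$wide_media[c(11, 29)] <- 1
  y <- rpois(40, 4)
  f1 <- fit_dlm(build_design(sched1, lag_spec(c(letters = 2))), y)
  f2 <- fit_dlm(build_design(sched2, lag_spec(c(letters = 2, wide_media = 2))), y)
  expect_gte(f2$r_squared, f1$r_squared)
  expect_lte(f1$adj_r_squared, f1$r_squared)
})

test_that("predict_daily reproduces fitted values and the oracle product", {
  set.seed(606)
  inst <- random_instance()
  fit <- fit_dlm(inst$design, inst$y)
  pred <- predict_daily(fit, inst$design)
  expect_equal(pred$predicted, fit$fitted, tolerance = 1e-10)
  # OLS with intercept: mean of predictions equals mean of observations
  expect_equal(mean(pred$predicted), mean(inst$y), tolerance = 1e-10)
  # held-out schedule restricted to the fitted channels: plain matrix product
  sched2 <- generate_schedule(seed = 12)
  spec <- inst$design$lag_spec
  for (ch in setdiff(recruit_channels(), spec$channel)) sched2[[ch]] <- 0
  d2 <- build_design(sched2, spec)
  p2 <- predict_daily(fit, d2)
  beta <- fit$coefficients$estimate
  expect_equal(p2$predicted,
               unname(beta[1] + drop(as.matrix(d2) %*% beta[-1])))
  # column mismatch errors
  d3 <- build_design(sched2, default_lag_spec())
  expect_error(predict_daily(fit, d3), "do not match")
})

test_that("campaign effects equal beta split over the kernel profile", {
  sched <- toy_schedule(40, list(
    letters = list(day = 2, value = 1),
    wide_media = list(day = c(20, 30), value = 1),
    paid_fb_reach = list(day = c(5, 6), value = 2000)
  ))
  spec <- lag_spec(c(letters = 15, wide_media = 2, paid_fb_reach = 2))
  design <- build_design(sched, spec)
  truth <- c(letters = 106.5, wide_media = 163.6, paid_fb_reach = 1.4)
  y <- 4.3 + drop(as.matrix(design) %*% truth[design$channels])
  fit <- suppressWarnings(fit_dlm(design, y)) # intended perfect fit

  eff <- campaign_effect(fit, "letters")
  expect_equal(eff$total, 106.5, tolerance = 1e-6)
  expect_equal(eff$per_day, rep(106.5 / 15, 15), tolerance = 1e-6)
  expect_equal(sum(eff$per_day), eff$total)  # effect conservation, exact

  eff2 <- campaign_effect(fit, "wide_media")
  expect_equal(eff2$per_day, c(81.8, 81.8), tolerance = 1e-6)

  # the semilog channel has no additive contract
  expect_error(campaign_effect(fit, "paid_fb_reach"), "semilog")
  eff3 <- campaign_effect(fit, "paid_fb_reach", reach_increase = 0.1)
  expect_true(eff3$approximate)
  expect_equal(eff3$total, 1.4 * log(1.1), tolerance = 1e-6)

  # zero coefficient gives zero effect
  fit0 <- fit
  fit0$coefficients$estimate[fit0$coefficients$term == "letters"] <- 0
  expect_equal(campaign_effect(fit0, "letters")$total, 0)
})

test_that("select_lags recovers a single-channel truth by brute force", {
  set.seed(707)
  for (true_lag in c(1L, 3L)) {
    sched <- toy_schedule(60, list(letters = list(day = c(5, 25, 40), value = 1)))
    design <- build_design(sched, lag_spec(c(letters = true_lag)))
    y <- 4 + drop(as.matrix(design)) * 30 + rnorm(60, 0, 0.5)
    res <- select_lags(sched, pmax(y, 0))
    expect_equal(res$lag_spec$lag[res$lag_spec$channel == "letters"], true_lag)
    expect_true(res$converged)
    # winning row of the criteria table matches the final fit
    cand <- res$candidates
    best <- cand[cand$channel == "letters" & cand$lag == true_lag, ]
    expect_equal(min(best$aic), res$fit$aic, tolerance = 1e-8)
  }
})

test_that("constant outcomes tie every lag and the smallest wins", {
  sched <- toy_schedule(30, list(letters = list(day = 5, value = 1)))
  res <- suppressWarnings(select_lags(sched, rep(3, 30))) # perfect-fit warning
  expect_equal(res$lag_spec$lag, 1L)
})

test_that("exhaustive_capped profiles only the supplied candidates", {
  set.seed(808)
  sched <- toy_schedule(50, list(letters = list(day = c(4, 30), value = 1)))
  design <- build_design(sched, lag_spec(c(letters = 4)))
  y <- pmax(4 + drop(as.matrix(design)) * 40 + rnorm(50, 0, 0.5), 0)
  res <- select_lags(sched, y, strategy = "exhaustive_capped",
                     candidates = list(letters = c(2, 4, 8)))
  expect_true(all(res$candidates$lag %in% c(2, 4, 8)))
  expect_equal(res$lag_spec$lag, 4L)
})
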