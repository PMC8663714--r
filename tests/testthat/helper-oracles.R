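# Independent oracles and small fixture builders shared across tests.

# Direct O(T*s) double loop for the lag distribution (independent of the
# convolution-based implementation).
oracle_distribute <- function(intensity, w) {
  n <- length(intensity)
  s <- length(w)
  out <- numeric(n)
  for (d in seq_len(n)) {
    for (j in seq_len(s)) {
      src <- d - j + 1L
      if (src >= 1L) out[d] <- out[d] + w[j] * intensity[src]
    }
  }
  out
}

# Normal-equations OLS oracle: (X'X)^-1 X'y with an explicit Gaussian
# log-likelihood for AIC/BIC.
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  fitted <- drop(X %*% beta)
  res <- y - fitted
  n <- length(y)
  p <- ncol(X)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  ll <- -n / 2 * (log(2 * pi) + 1 + log(rss / n))
  list(
    beta = drop(beta), se = se, fitted = fitted, residuals = res,
    aic = -2 * ll + 2 * (p + 1), bic = -2 * ll + (p + 1) * log(n),
    r2 = 1 - rss / sum((y - mean(y))^2)
  )
}

# A small schedule with events on given days for one or more channels.
toy_schedule <- function(days, events = list()) {
  sched <- empty_campaign_schedule(days)
  for (ch in names(events)) {
    ev <- events[[ch]]
    sched[[ch]][ev$day + 1L] <- ev$value
  }
  sched
}

# A minimal valid participant tibble builder.
toy_participants <- function(method, completed, city = "Montreal",
                             delay = 5L, ...) {
  n <- length(method)
  elig <- as.Date("2018-06-06") + seq_len(n)
  tibble::tibble(
    participant_id = sprintf("T%03d", seq_len(n)),
    city = city,
    method = method,
    eligibility_date = elig,
    health_date = as.Date(ifelse(completed, elig + delay, NA),
                          origin = "1970-01-01"),
    eligible = TRUE,
    participation_option = "full",
    age_years = NA_integer_,
    gender = NA_character_,
    income_band = NA_character_,
    education = NA_character_,
    ethnicity = NA_character_,
    mail_group = NA_character_,
    ...
  )
}
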