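# Stochastic synthetic data with the structure the analysis assumes: a
# 199-day campaign schedule (151 paid-reach days with truncated-lognormal
# reach, 44 unpaid posts over 34 days, single letter/reminder/snowball
# campaigns, 18 partner communications, 2 + 6 media events, 16 other
# events), a daily recruit series generated from the distributed-lag model,
# and participant-level records whose method shares, completion rates,
# delays and demographics follow the published marginals.

#' Simulation configuration
#'
#' Defaults are the emulated study's conditions: a 199-day recruitment
#' period, the published campaign-event counts, paid reach drawn from a
#' lognormal moment-matched to mean 2770 / SD 3558 and truncated to
#' \[144, 20156\], the fitted coefficients as truth ([default_betas()]), the
#' fitted lag spec ([default_lag_spec()]), and Poisson daily counts.
#'
#' @param days Study length T in days.
#' @param n_paid_days,paid_reach_mean,paid_reach_sd,paid_reach_min,paid_reach_max
#'   Paid-Facebook channel: number of active days and the reach
#'   distribution's target moments and truncation bounds (persons).
#' @param n_unpaid_posts,n_unpaid_days Unpaid posts: total posts spread over
#'   that many distinct days.
#' @param n_letters,n_reminders,n_partner_comms,n_wide_media,n_small_media,n_snowball,n_other
#'   Event counts for the remaining channels (each event occupies one day).
#' @param alpha,beta True intercept (recruits/day) and channel coefficients.
#' @param true_lag_spec The generating [lag_spec()].
#' @param noise `"poisson"` for `y ~ Poisson(max(eta, 0.01))`, or
#'   `"gaussian"` for `y = round(max(N(eta, sigma), 0))`.
#' @param sigma Gaussian noise SD (ignored for Poisson).
#' @param city,recruitment_start_date Calendar context for simulated
#'   participant records.
#' @param recalibrate_reach If `TRUE`, iteratively recalibrate the lognormal
#'   parameters so the *truncated* distribution matches the target moments
#'   (by default moment matching is done before truncation and the small
#'   truncation shift is accepted).
#' @return A `sim_config` list.
#' @export
sim_config <- function(days = 199L,
                       n_paid_days = 151L, paid_reach_mean = 2770,
                       paid_reach_sd = 3558, paid_reach_min = 144,
                       paid_reach_max = 20156,
                       n_unpaid_posts = 44L, n_unpaid_days = 34L,
                       n_letters = 1L, n_reminders = 1L,
                       n_partner_comms = 18L, n_wide_media = 2L,
                       n_small_media = 6L, n_snowball = 1L, n_other = 16L,
                       alpha = 4.3, beta = default_betas(),
                       true_lag_spec = default_lag_spec(),
                       noise = c("poisson", "gaussian"), sigma = 2,
                       city = "Montreal",
                       recruitment_start_date = NULL,
                       recalibrate_reach = FALSE) {
  noise <- match.arg(noise)
  days <- as.integer(days)
  counts <- c(n_paid_days, n_unpaid_days, n_letters, n_reminders,
              n_partner_comms, n_wide_media, n_small_media, n_snowball, n_other)
  if (any(counts < 0) || any(counts > days)) {
    abort("each channel's event-day count must be between 0 and `days`",
          class = "recruitlag_error")
  }
  if (n_unpaid_posts < n_unpaid_days) {
    abort("n_unpaid_posts must be at least n_unpaid_days", class = "recruitlag_error")
  }
  if (!city %in% .CITIES) {
    abort(sprintf("unknown city '%s'", city), class = "recruitlag_error")
  }
  if (is.null(recruitment_start_date)) {
    recruitment_start_date <- as.Date(.START_DATES[[city]])
  }
  structure(list(
    days = days, n_paid_days = as.integer(n_paid_days),
    paid_reach_mean = paid_reach_mean, paid_reach_sd = paid_reach_sd,
    paid_reach_min = paid_reach_min, paid_reach_max = paid_reach_max,
    n_unpaid_posts = as.integer(n_unpaid_posts),
    n_unpaid_days = as.integer(n_unpaid_days),
    n_letters = as.integer(n_letters), n_reminders = as.integer(n_reminders),
    n_partner_comms = as.integer(n_partner_comms),
    n_wide_media = as.integer(n_wide_media),
    n_small_media = as.integer(n_small_media),
    n_snowball = as.integer(n_snowball), n_other = as.integer(n_other),
    alpha = alpha, beta = beta, true_lag_spec = true_lag_spec,
    noise = noise, sigma = sigma, city = city,
    recruitment_start_date = as.Date(recruitment_start_date),
    recalibrate_reach = recalibrate_reach
  ), class = "sim_config")
}

# mean and sd of a lognormal(mu, s) truncated to [a, b] (closed form)
.trunc_lnorm_moments <- function(mu, s, a, b) {
  za <- (log(a) - mu) / s
  zb <- (log(b) - mu) / s
  denom <- pnorm(zb) - pnorm(za)
  mk <- function(k) {
    exp(k * mu + k^2 * s^2 / 2) *
      (pnorm(zb - k * s) - pnorm(za - k * s)) / denom
  }
  m1 <- mk(1)
  m2 <- mk(2)
  c(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)))
}

.lnorm_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(mu = log(mean) - s2 / 2, s = sqrt(s2))
}

#' Truncated-lognormal sampler for daily paid reach
#'
#' Parameters are moment-matched to the target mean/SD before truncation;
#' sampling is by rejection within `[lower, upper]`. With
#' `recalibrate = TRUE` the parameters are instead tuned (Nelder-Mead on the
#' closed-form truncated moments) so the truncated distribution itself
#' matches the targets.
#'
#' @param n Number of draws.
#' @param mean,sd Target moments.
#' @param lower,upper Truncation bounds.
#' @param recalibrate See above.
#' @return Numeric vector of `n` draws, all within `[lower, upper]`.
#' @export
rtrunclnorm <- function(n, mean = 2770, sd = 3558, lower = 144, upper = 20156,
                        recalibrate = FALSE) {
  stopifnot(lower < upper, mean > 0, sd > 0)
  par <- .lnorm_params(mean, sd)
  if (recalibrate) {
    obj <- function(p) {
      m <- .trunc_lnorm_moments(p[1], exp(p[2]), lower, upper)
      (m[["mean"]] / mean - 1)^2 + (m[["sd"]] / sd - 1)^2
    }
    opt <- stats::optim(c(par[["mu"]], log(par[["s"]])), obj,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    par <- c(mu = opt$par[1], s = exp(opt$par[2]))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rlnorm(2L * (n - length(out)) + 10L, par[["mu"]], par[["s"]])
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

# Draw a size-n subset of days 0..T-1 biased toward contiguous runs: random
# geometric-length runs are unioned until n days are covered, then trimmed.
.sample_run_days <- function(days, n, mean_run = 8) {
  if (n == 0) return(integer(0))
  if (n >= days) return(seq_len(days) - 1L)
  covered <- integer(0)
  while (length(covered) < n) {
    start <- sample.int(days, 1L) - 1L
    len <- 1L + rgeom(1L, prob = 1 / mean_run)
    run <- start:min(start + len - 1L, days - 1L)
    covered <- union(covered, run)
  }
  sort(sample(covered, n))
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Generate a synthetic campaign schedule
#'
#' Event days are drawn uniformly without replacement per channel, except
#' paid-reach days, which are drawn as a contiguous-biased subset (paid
#' campaigns run in multi-day bursts). Unpaid posts are spread over
#' `n_unpaid_days` distinct days, each getting at least one post. Paid reach
#' values are i.i.d. truncated lognormal. The same seed always reproduces
#' the same schedule.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A validated campaign schedule tibble.
#' @export
#' @examples
#' sched <- generate_schedule(seed = 1)
#' sum(sched$paid_fb_reach > 0) # 151 paid days
generate_schedule <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    days <- config$days
    out <- empty_campaign_schedule(days)
    paid_days <- .sample_run_days(days, config$n_paid_days)
    if (length(paid_days) > 0) {
      out$paid_fb_reach[paid_days + 1L] <- rtrunclnorm(
        length(paid_days), config$paid_reach_mean, config$paid_reach_sd,
        config$paid_reach_min, config$paid_reach_max,
        recalibrate = config$recalibrate_reach
      )
    }
    if (config$n_unpaid_days > 0) {
      unpaid_days <- sort(sample.int(days, config$n_unpaid_days)) - 1L
      posts <- rep(1L, config$n_unpaid_days)
      extra <- config$n_unpaid_posts - config$n_unpaid_days
      if (extra > 0) {
        add <- table(sample.int(config$n_unpaid_days, extra, replace = TRUE))
        posts[as.integer(names(add))] <- posts[as.integer(names(add))] + as.integer(add)
      }
      out$unpaid_fb_posts[unpaid_days + 1L] <- posts
    }
    singles <- c(letters = config$n_letters, reminders = config$n_reminders,
                 partner_comms = config$n_partner_comms,
                 wide_media = config$n_wide_media,
                 small_media = config$n_small_media,
                 snowball = config$n_snowball, other = config$n_other)
    for (ch in names(singles)) {
      k <- singles[[ch]]
      if (k > 0) {
        ev <- sample.int(days, k) - 1L
        out[[ch]][ev + 1L] <- 1
      }
    }
    validate_campaign_schedule(out)
  })
}

#' Simulate the daily recruit series from a schedule
#'
#' Builds the linear predictor `eta_d = alpha + sum_k beta_k * z_k(d)` using
#' the configuration's true lag spec, then draws
#' `y_d ~ Poisson(max(eta_d, 0.01))` or
#' `y_d = round(max(N(eta_d, sigma), 0))`.
#'
#' @inheritParams generate_schedule
#' @param schedule A campaign schedule.
#' @return A tibble with `day_index` and integer `recruits`.
#' @export
simulate_recruits <- function(schedule, config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  design <- build_design(schedule, config$true_lag_spec)
  channels <- design$channels
  beta <- config$beta[channels]
  if (any(is.na(beta))) {
    abort("config beta does not cover every lag-spec channel",
          class = "recruitlag_error")
  }
  eta <- config$alpha + drop(as.matrix(design) %*% beta)
  .with_seed(seed, {
    y <- switch(config$noise,
      poisson = rpois(length(eta), pmax(eta, 0.01)),
      gaussian = as.integer(round(pmax(rnorm(length(eta), eta, config$sigma), 0)))
    )
    tibble(day_index = design$data$day_index, recruits = as.integer(y))
  })
}

# lognormal delay in whole days matched to a target mean/SD
.r_delay <- function(n, mean, sd) {
  par <- .lnorm_params(mean, sd)
  round(rlnorm(n, par[["mu"]], par[["s"]]))
}

.sample_levels <- function(n, levels, weights, missing_rate) {
  probs <- weights / sum(weights)
  out <- sample(levels, n, replace = TRUE, prob = probs)
  if (missing_rate > 0) {
    out[runif(n) < missing_rate] <- NA
  }
  out
}

#' Simulate a participant-level table from a daily recruit series
#'
#' Each daily recruit becomes one record: recruitment method drawn from the
#' published recruited shares, completer flag Bernoulli with the method's
#' completion rate, delay from a lognormal matched to the method's delay
#' mean/SD (whole days), demographics multinomial per method from the
#' published completer composition with uniform per-variable missingness,
#' and a participation option drawn from the city's published mix.
#'
#' @inheritParams generate_schedule
#' @param daily A tibble with `day_index` and `recruits`.
#' @return A validated participant tibble.
#' @export
simulate_participants <- function(daily, config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .check_columns(daily, c("day_index", "recruits"), "daily recruits")
  n <- sum(daily$recruits)
  if (n == 0) {
    return(validate_participants(tibble(
      participant_id = character(0), city = character(0), method = character(0),
      eligibility_date = as.Date(character(0)), health_date = as.Date(character(0)),
      eligible = logical(0), participation_option = character(0),
      age_years = integer(0), gender = character(0), income_band = character(0),
      education = character(0), ethnicity = character(0), mail_group = character(0)
    )))
  }
  method_shares <- colSums(.RECRUITED)
  completion_rates <- colSums(.COMPLETERS) / colSums(.RECRUITED)
  .with_seed(seed, {
    day <- rep(daily$day_index, daily$recruits)
    method <- sample(.METHODS, n, replace = TRUE,
                     prob = method_shares / sum(method_shares))
    completer <- runif(n) < completion_rates[method]
    delay <- rep(NA_real_, n)
    for (m in .METHODS) {
      idx <- which(method == m & completer)
      if (length(idx) > 0) {
        st <- .DELAY_STATS[.DELAY_STATS$method == m, ]
        delay[idx] <- .r_delay(length(idx), st$delay_mean, st$delay_sd)
      }
    }
    demo <- list()
    for (vn in names(.DEMOGRAPHICS)) {
      tab <- .DEMOGRAPHICS[[vn]]
      lev <- setdiff(rownames(tab), "(missing)")
      vals <- rep(NA_character_, n)
      for (m in .METHODS) {
        idx <- which(method == m)
        if (length(idx) > 0) {
          vals[idx] <- .sample_levels(length(idx), lev, tab[lev, m],
                                      .MISSING_RATES[[vn]])
        }
      }
      demo[[vn]] <- vals
    }
    age_band <- demo$age
    age <- ifelse(is.na(age_band), NA_integer_, .AGE_BAND_REP[age_band])
    popt <- .PARTICIPATION_N[config$city, ]
    elig_date <- config$recruitment_start_date + day
    out <- tibble(
      participant_id = sprintf("S%06d", seq_len(n)),
      city = config$city,
      method = method,
      eligibility_date = elig_date,
      health_date = as.Date(ifelse(completer, elig_date + delay, NA),
                            origin = "1970-01-01"),
      eligible = TRUE,
      participation_option = sample(.PARTICIPATION, n, replace = TRUE,
                                    prob = popt / sum(popt)),
      age_years = as.integer(age),
      gender = demo$gender,
      income_band = demo$income,
      education = demo$education,
      ethnicity = demo$ethnicity,
      mail_group = ifelse(method == "mailed_letters" & config$city == "Montreal",
                          sample(.MAIL_GROUPS, n, replace = TRUE), NA_character_)
    )
    validate_participants(out)
  })
}
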