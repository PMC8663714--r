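# Fitting and summarising the daily-recruitment distributed-lag model:
#   y_d = alpha + sum_k beta_k * z_k(d) + mu_d
# where z_k is channel k's lag-distributed (and possibly semilog-transformed)
# intensity. Estimation is ordinary least squares with Gaussian-likelihood
# AIC/BIC; because lag-kernel weights sum to 1, each identity-channel beta is
# the total number of recruits attributable to one campaign-event unit.

.recruits_vector <- function(y, n_expected = NULL, day_index = NULL) {
  if (is.data.frame(y)) {
    .check_columns(y, c("day_index", "recruits"), "daily recruits")
    if (!is.null(day_index) && !identical(as.integer(y$day_index), as.integer(day_index))) {
      abort("recruit series and design cover different day_index ranges",
            class = "recruitlag_error")
    }
    y <- y$recruits
  }
  if (any(!is.finite(y)) || any(y < 0)) {
    abort("recruit counts must be finite and nonnegative", class = "recruitlag_error")
  }
  if (!is.null(n_expected) && length(y) != n_expected) {
    abort(sprintf("recruit series has length %d but design has %d days",
                  length(y), n_expected), class = "recruitlag_error")
  }
  as.numeric(y)
}

#' Fit the distributed-lag daily-recruitment model
#'
#' Ordinary least squares of daily recruit counts on the lag-distributed
#' campaign regressors plus an intercept. The intercept is the baseline
#' recruitment rate (recruits/day); each identity-channel coefficient is
#' recruits per campaign-event unit; the semilog channel's coefficient is
#' recruits per log-unit of reach/1000. AIC and BIC use the full Gaussian
#' log-likelihood with `k = n_params + 1` (the error variance counts as a
#' parameter); 95% CIs use the t distribution on `n - p` degrees of freedom.
#'
#' @param design A `dlm_design` from [build_design()].
#' @param y Daily recruits: a tibble with `day_index` and `recruits`, or a
#'   bare numeric vector aligned with the design.
#' @param conf_level Confidence level for the coefficient intervals.
#' @return A `dlm_fit` object: coefficient table (`term`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p`), `fitted`, `residuals`, `r_squared`,
#'   `adj_r_squared`, `aic`, `bic`, `sigma`, `n_obs`, `n_params`, and the
#'   `lag_spec` the design was built with.
#' @export
fit_dlm <- function(design, y, conf_level = 0.95) {
  stopifnot(inherits(design, "dlm_design"))
  yv <- .recruits_vector(y, nrow(design$data), design$data$day_index)
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    abort(sprintf("need more observations (%d) than parameters (%d)", n, p),
          class = "recruitlag_error")
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, p)]]
    abort(sprintf("design is rank deficient; collinear column(s): %s",
                  paste(aliased, collapse = ", ")), class = "recruitlag_error")
  }
  df <- as.data.frame(design$data[, design$channels, drop = FALSE])
  df$.y <- yv
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  cf <- sm$coefficients
  terms <- rownames(cf)
  # restore original channel names (lm backticks non-syntactic ones)
  terms <- gsub("`", "", terms)
  coefficients <- tibble(
    term = terms,
    estimate = unname(cf[, "Estimate"]),
    se = unname(cf[, "Std. Error"]),
    ci_low = unname(ci[, 1]),
    ci_high = unname(ci[, 2]),
    p = unname(cf[, "Pr(>|t|)"])
  )
  structure(
    list(
      coefficients = coefficients,
      fitted = unname(stats::fitted(fit)),
      residuals = unname(stats::residuals(fit)),
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      aic = stats::AIC(fit),
      bic = stats::BIC(fit),
      sigma = sm$sigma,
      n_obs = n,
      n_params = p,
      conf_level = conf_level,
      lag_spec = design$lag_spec,
      channels = design$channels,
      day_index = design$data$day_index,
      lm = fit
    ),
    class = "dlm_fit"
  )
}

#' @export
print.dlm_fit <- function(x, ...) {
  cat(sprintf(
    "Distributed-lag recruitment model (OLS)\n  n = %d days, %d parameters\n  R2 = %.3f (adj %.3f), AIC = %.1f, BIC = %.1f\n",
    x$n_obs, x$n_params, x$r_squared, x$adj_r_squared, x$aic, x$bic
  ))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Coefficient table of a fitted model
#'
#' @param fit A `dlm_fit`.
#' @return The coefficient tibble (`term`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`).
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "dlm_fit"))
  fit$coefficients
}

#' Predict the daily recruitment series
#'
#' `yhat_d = alpha + sum_k beta_k * design[d, k]`. Predictions from a linear
#' model may be negative on quiet days and are reported unclipped.
#'
#' @param fit A `dlm_fit`.
#' @param design A `dlm_design` whose channels match the fit's terms.
#' @return Tibble with `day_index` and `predicted`.
#' @export
predict_daily <- function(fit, design) {
  stopifnot(inherits(fit, "dlm_fit"), inherits(design, "dlm_design"))
  if (!identical(design$channels, fit$channels)) {
    abort("design columns do not match the fitted model's terms",
          class = "recruitlag_error")
  }
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  X <- as.matrix(design)
  pred <- beta[["(Intercept)"]] + drop(X %*% beta[fit$channels])
  tibble(day_index = design$data$day_index, predicted = unname(pred))
}

#' Total and per-day effect of one campaign event
#'
#' For an identity-transformed channel the kernel weights sum to 1, so the
#' total incremental recruits per unit event equal the channel's coefficient,
#' and the per-day profile is `beta * w_j` over the lag window. The semilog
#' channel has no additive per-event contract: supply `reach_increase` to get
#' the approximate effect of a proportional reach increase,
#' `beta * log(1 + delta)`, flagged as approximate.
#'
#' @param fit A `dlm_fit`.
#' @param channel Channel id.
#' @param reach_increase For the semilog channel only: fractional reach
#'   increase `delta` (e.g. `0.1` for +10%).
#' @return A `campaign_effect` list: `channel`, `total`, `per_day`, `lag`,
#'   `approximate`.
#' @export
#' @examples
#' sched <- empty_campaign_schedule(30)
#' sched$wide_media[5] <- 1
#' spec <- lag_spec(c(wide_media = 2))
#' fit <- fit_dlm(build_design(sched, spec), rpois(30, 4) + 80 * (sched$wide_media > 0))
#' campaign_effect(fit, "wide_media")
campaign_effect <- function(fit, channel, reach_increase = NULL) {
  stopifnot(inherits(fit, "dlm_fit"))
  spec <- fit$lag_spec
  i <- match(channel, spec$channel)
  if (is.na(i)) {
    abort(sprintf("channel '%s' is not in the fitted model", channel),
          class = "recruitlag_error")
  }
  beta <- fit$coefficients$estimate[match(channel, fit$coefficients$term)]
  w <- kernel_weights(spec$lag[i], spec$kernel[i])
  if (spec$transform[i] == "log_per_1000") {
    if (is.null(reach_increase)) {
      abort(paste0(
        "channel '", channel, "' enters the model through a semilog transform; ",
        "its coefficient is not an additive per-event effect. Supply ",
        "reach_increase = delta to get the approximate effect of a ",
        "proportional reach increase, beta * log(1 + delta)."
      ), class = "recruitlag_error")
    }
    total <- beta * log(1 + reach_increase)
    out <- list(channel = channel, total = total, per_day = total * w,
                lag = spec$lag[i], approximate = TRUE)
  } else {
    if (!is.null(reach_increase)) {
      abort("reach_increase only applies to the semilog channel",
            class = "recruitlag_error")
    }
    out <- list(channel = channel, total = beta, per_day = beta * w,
                lag = spec$lag[i], approximate = FALSE)
  }
  structure(out, class = "campaign_effect")
}

#' @export
print.campaign_effect <- function(x, ...) {
  cat(sprintf("Channel '%s': %s%.2f recruits over %d day(s)%s\n",
              x$channel, if (x$approximate) "~" else "", x$total, x$lag,
              if (x$approximate) " (proportional-increase approximation)" else ""))
  cat("per-day profile:", paste(sprintf("%.2f", x$per_day), collapse = " "), "\n")
  invisible(x)
}

# Fast OLS criteria from a plain matrix (used by the lag search, where the
# same fit is recomputed hundreds of times). Matches stats::AIC/BIC on lm
# exactly: loglik = -n/2 * (log(2*pi) + 1 + log(RSS/n)), k = p + 1.
.ols_criteria <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p || n <= p) {
    return(list(aic = Inf, bic = Inf, adj_r_squared = -Inf, feasible = FALSE))
  }
  res <- qr.resid(qrX, y)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  # an exact interpolation leaves only numerical dust in the residuals;
  # treat it as a perfect fit so ties break on the lag, not on noise
  if (rss < .Machine$double.eps^0.75 * max(sum(y^2), 1)) rss <- 0
  ll <- if (rss <= 0) Inf else -n / 2 * (log(2 * pi) + 1 + log(rss / n))
  k <- p + 1
  r2 <- if (tss > 0) 1 - rss / tss else 0
  adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  list(aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
       adj_r_squared = adj, feasible = TRUE)
}

#' Select per-channel lag lengths by information criteria
#'
#' Searches lag lengths 1..15 per channel for the model that best explains
#' the daily recruit series. The default `"profile_then_descend"` strategy is
#' coordinate descent: all channels start at lag 2; each channel in turn is
#' scanned over the candidate lags with the others held fixed and set to the
#' AIC-minimising lag (ties broken by lower BIC, then the smaller lag);
#' passes repeat until no channel changes or `max_passes` is reached. A full
#' grid over all channels jointly is combinatorially infeasible (15^9
#' models); `"exhaustive_capped"` instead takes a user-supplied candidate set
#' per channel and profiles over exactly those. Channels with no events in
#' the schedule are excluded from the search. Statistical significance is
#' reported in the final fit but never used as a selection rule.
#'
#' @param schedule A validated campaign schedule.
#' @param y Daily recruits aligned with `schedule`.
#' @param lags Candidate lag lengths (default `1:15`).
#' @param strategy `"profile_then_descend"` (default) or
#'   `"exhaustive_capped"`.
#' @param candidates For `"exhaustive_capped"`: named list of candidate lag
#'   vectors per channel.
#' @param kernel Kernel id used for every channel.
#' @param max_passes Maximum coordinate-descent passes (default 5). If the
#'   search is still changing after `max_passes`, the best configuration so
#'   far is returned with `converged = FALSE` and a warning.
#' @param init_lag Starting lag for every channel (default 2).
#' @return A `lag_search` object: selected `lag_spec`, the per-candidate
#'   criteria table (`pass`, `channel`, `lag`, `aic`, `bic`,
#'   `adj_r_squared`), the final `dlm_fit`, `converged`, `passes`.
#' @export
select_lags <- function(schedule, y, lags = 1:15,
                        strategy = c("profile_then_descend", "exhaustive_capped"),
                        candidates = NULL, kernel = "uniform",
                        max_passes = 5, init_lag = 2L) {
  strategy <- match.arg(strategy)
  schedule <- validate_campaign_schedule(schedule)
  yv <- .recruits_vector(y, nrow(schedule), schedule$day_index)
  active <- .CHANNELS[vapply(.CHANNELS, function(ch) any(schedule[[ch]] > 0), logical(1))]
  if (length(active) == 0) {
    abort("schedule has no campaign events; nothing to select lags for",
          class = "recruitlag_error")
  }
  cand <- if (strategy == "exhaustive_capped") {
    if (is.null(candidates)) {
      abort("strategy 'exhaustive_capped' needs a named `candidates` list",
            class = "recruitlag_error")
    }
    missing <- setdiff(active, names(candidates))
    if (length(missing) > 0) {
      abort(sprintf("candidates missing for channel(s): %s",
                    paste(missing, collapse = ", ")), class = "recruitlag_error")
    }
    lapply(setNames(active, active), function(ch) sort(as.integer(candidates[[ch]])))
  } else {
    lapply(setNames(active, active), function(ch) sort(as.integer(lags)))
  }
  transform_of <- function(ch) if (ch == "paid_fb_reach") "log_per_1000" else "identity"
  # cache every (channel, lag) design column once
  cache <- lapply(setNames(active, active), function(ch) {
    cols <- lapply(cand[[ch]], function(s) {
      .design_column(schedule[[ch]], s, kernel, transform_of(ch))
    })
    names(cols) <- as.character(cand[[ch]])
    cols
  })
  current <- vapply(active, function(ch) {
    cs <- cand[[ch]]
    if (init_lag %in% cs) as.integer(init_lag) else cs[1]
  }, integer(1))
  design_cols <- function(lag_assign) {
    m <- vapply(active, function(ch) cache[[ch]][[as.character(lag_assign[[ch]])]],
                numeric(length(yv)))
    cbind(`(Intercept)` = 1, m)
  }
  records <- list()
  pass <- 0L
  changed <- TRUE
  while (changed && pass < max_passes) {
    pass <- pass + 1L
    changed <- FALSE
    for (ch in active) {
      cs <- cand[[ch]]
      crit <- lapply(cs, function(s) {
        trial <- current
        trial[[ch]] <- s
        .ols_criteria(design_cols(trial), yv)
      })
      tab <- tibble(
        pass = pass, channel = ch, lag = cs,
        aic = vapply(crit, `[[`, numeric(1), "aic"),
        bic = vapply(crit, `[[`, numeric(1), "bic"),
        adj_r_squared = vapply(crit, `[[`, numeric(1), "adj_r_squared")
      )
      records[[length(records) + 1L]] <- tab
      # ties: AIC, then BIC, then smaller lag (rows are lag-ascending)
      best <- cs[order(tab$aic, tab$bic, tab$lag)[1]]
      if (best != current[[ch]]) {
        current[[ch]] <- best
        changed <- TRUE
      }
    }
  }
  converged <- !changed
  if (!converged) {
    warn(sprintf("lag search still changing after %d passes; returning best so far",
                 max_passes))
  }
  spec <- lag_spec(current,
                   kernel = kernel,
                   transforms = vapply(active, transform_of, character(1)))
  fit <- fit_dlm(build_design(schedule, spec), yv)
  structure(
    list(lag_spec = spec, candidates = bind_rows(records), fit = fit,
         converged = converged, passes = pass),
    class = "lag_search"
  )
}

#' @export
print.lag_search <- function(x, ...) {
  cat(sprintf("Lag search (%s passes, %sconverged)\n", x$passes,
              if (x$converged) "" else "NOT "))
  print(x$lag_spec)
  cat(sprintf("final fit: AIC %.1f, BIC %.1f, adj R2 %.3f\n",
              x$fit$aic, x$fit$bic, x$fit$adj_r_squared))
  invisible(x)
}
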