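# Finite distributed-lag features: turn a daily campaign schedule into the
# regression design of the daily-recruitment model. One campaign event on day
# d contributes w_0, ..., w_{s-1} (weights summing to 1) to days d..d+s-1, so
# a channel's coefficient reads directly as recruits per campaign-event unit.
# Paid reach enters through a semilog transform of the *lagged* series.

.KERNELS <- c("uniform", "linear_decay")
.TRANSFORMS <- c("identity", "log_per_1000")

#' Distributed-lag kernel weights
#'
#' Weights `w_0..w_{s-1}` spreading one event-day unit over a lag window of
#' `s` days (the event day is day 0 of its own window). Weights are
#' nonnegative and sum to 1, so the total effect of one event equals the
#' channel coefficient regardless of the lag length. `"uniform"` gives
#' `1/s` each; `"linear_decay"` gives weights proportional to
#' `s, s-1, ..., 1`.
#'
#' @param s Lag length in days (integer, `s >= 1`).
#' @param kernel `"uniform"` (default) or `"linear_decay"`.
#' @return Numeric vector of length `s` summing to 1.
#' @export
#' @examples
#' kernel_weights(3)
#' kernel_weights(3, "linear_decay")
kernel_weights <- function(s, kernel = c("uniform", "linear_decay")) {
  kernel <- match.arg(kernel)
  if (length(s) != 1 || !is.finite(s) || s < 1 || s != floor(s)) {
    abort("lag length s must be a single integer >= 1", class = "recruitlag_error")
  }
  s <- as.integer(s)
  w <- switch(kernel,
    uniform = rep(1 / s, s),
    linear_decay = (s:1) / sum(s:1)
  )
  w
}

#' Distribute a daily intensity series over its lag window
#'
#' Computes `out[d] = sum_j w_j * intensity[d - j]` for `j = 0..s-1`, with
#' out-of-range terms dropped: mass is conserved except for truncation at the
#' end of the series. With `s = 1` the series is returned unchanged.
#'
#' @param intensity Nonnegative daily series (length `T`).
#' @param s Lag length in days.
#' @param kernel Kernel id, see [kernel_weights()].
#' @return Numeric series of length `T`.
#' @export
#' @examples
#' distribute_lags(c(0, 0, 1, 0, 0), s = 2)
distribute_lags <- function(intensity, s, kernel = "uniform") {
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    abort("intensity must be finite and nonnegative", class = "recruitlag_error")
  }
  w <- kernel_weights(s, kernel)
  s <- length(w)
  if (s == 1L) return(as.numeric(intensity))
  n <- length(intensity)
  padded <- c(rep(0, s - 1L), as.numeric(intensity))
  out <- as.numeric(stats::filter(padded, w, method = "convolution", sides = 1))
  out[seq.int(s, s + n - 1L)]
}

#' Semilog transform of a lagged exposure series
#'
#' `z[d] = log(x[d] / scale)` on days with positive lagged exposure and 0 on
#' zero-exposure days, so that days with no campaign contribute nothing to
#' the linear predictor. The default scale of 1000 persons means the
#' coefficient of the transformed paid-reach channel is recruits per log-unit
#' of reach/1000; for a proportional reach increase of `delta` the implied
#' effect is `beta * log(1 + delta)`.
#'
#' @param x Nonnegative lagged daily series.
#' @param scale Persons per unit (default 1000).
#' @param zero `"zero"` (default) maps zero-exposure days to 0;
#'   `"log1p"` instead uses `log1p(x / scale)` everywhere.
#' @return Transformed series, same length as `x`.
#' @export
#' @examples
#' semilog_transform(c(0, 1000, 2770))
semilog_transform <- function(x, scale = 1000, zero = c("zero", "log1p")) {
  zero <- match.arg(zero)
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("lagged reach must be finite and nonnegative", class = "recruitlag_error")
  }
  if (zero == "log1p") return(log1p(x / scale))
  ifelse(x > 0, log(x / scale), 0)
}

#' Per-channel lag specification
#'
#' A lag spec assigns every campaign channel a lag length (1..15 days), a
#' kernel and a transform. In the study configuration exactly one channel --
#' `paid_fb_reach` -- uses the `log_per_1000` transform; all others enter
#' untransformed so their coefficients are recruits per campaign event.
#'
#' @param lags Named integer vector of lag lengths (names = channels).
#' @param kernel Kernel id applied to every channel, or a named character
#'   vector per channel.
#' @param transforms Named character vector of transforms; defaults to
#'   `log_per_1000` for `paid_fb_reach` and `identity` elsewhere.
#' @return A `lag_spec` tibble with columns `channel`, `lag`, `kernel`,
#'   `transform`.
#' @export
#' @examples
#' default_lag_spec()
lag_spec <- function(lags, kernel = "uniform", transforms = NULL) {
  channels <- names(lags)
  if (is.null(channels) || any(channels == "") || anyDuplicated(channels)) {
    abort("lags must be a uniquely named vector of channels", class = "recruitlag_error")
  }
  unknown <- setdiff(channels, .CHANNELS)
  if (length(unknown) > 0) {
    abort(sprintf("unknown channel(s): %s", paste(unknown, collapse = ", ")),
          class = "recruitlag_error")
  }
  if (any(lags < 1 | lags > 15 | lags != floor(lags))) {
    abort("every lag length must be an integer in 1..15", class = "recruitlag_error")
  }
  if (length(kernel) == 1) kernel <- setNames(rep(kernel, length(channels)), channels)
  if (is.null(transforms)) {
    transforms <- setNames(
      ifelse(channels == "paid_fb_reach", "log_per_1000", "identity"), channels
    )
  }
  if (!all(kernel[channels] %in% .KERNELS)) {
    abort("unknown kernel id", class = "recruitlag_error")
  }
  if (!all(transforms[channels] %in% .TRANSFORMS)) {
    abort("unknown transform id", class = "recruitlag_error")
  }
  out <- tibble(
    channel = channels,
    lag = as.integer(lags[channels]),
    kernel = unname(kernel[channels]),
    transform = unname(transforms[channels])
  )
  class(out) <- c("lag_spec", class(out))
  out
}

#' @rdname lag_spec
#' @details `default_lag_spec()` returns the fitted study configuration:
#'   letters 15 days, reminders 5, snowball 4, other 4, and 2 days for paid
#'   reach, unpaid posts, partner communications and both news channels, all
#'   with uniform kernels.
#' @export
default_lag_spec <- function() {
  lag_spec(c(
    letters = 15L, paid_fb_reach = 2L, unpaid_fb_posts = 2L, reminders = 5L,
    partner_comms = 2L, snowball = 4L, wide_media = 2L, small_media = 2L,
    other = 4L
  ))
}

#' Serialize a lag spec to / from YAML
#'
#' @param spec A [lag_spec()].
#' @param path File path.
#' @return `write_lag_spec()` returns `path` invisibly; `read_lag_spec()`
#'   returns a `lag_spec`.
#' @export
write_lag_spec <- function(spec, path) {
  stopifnot(inherits(spec, "lag_spec"))
  out <- lapply(seq_len(nrow(spec)), function(i) {
    list(lag = spec$lag[i], kernel = spec$kernel[i], transform = spec$transform[i])
  })
  names(out) <- spec$channel
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_lag_spec
#' @export
read_lag_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  lags <- vapply(raw, function(x) as.integer(x$lag), integer(1))
  kernel <- vapply(raw, function(x) x$kernel %||% "uniform", character(1))
  transforms <- vapply(raw, function(x) x$transform %||% "identity", character(1))
  lag_spec(lags, kernel = kernel, transforms = transforms)
}

# One design column: lag-distribute, then transform (the log is taken of the
# lagged variable, not the other way around).
.design_column <- function(intensity, lag, kernel, transform) {
  z <- distribute_lags(intensity, lag, kernel)
  if (transform == "log_per_1000") z <- semilog_transform(z) else z
}

#' Build the distributed-lag regression design
#'
#' One column per channel in `spec`: the channel's daily intensity
#' distributed over its lag window, then transformed (`log_per_1000` for paid
#' reach). The intercept is added at fitting time.
#'
#' @param schedule A validated campaign schedule.
#' @param spec A [lag_spec()] covering, at minimum, every channel with any
#'   nonzero intensity in `schedule`.
#' @return A `dlm_design` object: a list with `data` (tibble of `day_index`
#'   plus one column per spec channel), `lag_spec` and `channels`.
#' @export
#' @examples
#' sched <- empty_campaign_schedule(20)
#' sched$letters[3] <- 1
#' build_design(sched, default_lag_spec())
build_design <- function(schedule, spec) {
  stopifnot(inherits(spec, "lag_spec"))
  schedule <- validate_campaign_schedule(schedule)
  active <- .CHANNELS[vapply(.CHANNELS, function(ch) any(schedule[[ch]] > 0), logical(1))]
  missing <- setdiff(active, spec$channel)
  if (length(missing) > 0) {
    abort(sprintf("lag spec missing channel(s) with nonzero intensity: %s",
                  paste(missing, collapse = ", ")), class = "recruitlag_error")
  }
  data <- tibble(day_index = schedule$day_index)
  for (i in seq_len(nrow(spec))) {
    ch <- spec$channel[i]
    data[[ch]] <- .design_column(schedule[[ch]], spec$lag[i], spec$kernel[i],
                                 spec$transform[i])
  }
  structure(
    list(data = data, lag_spec = spec, channels = spec$channel),
    class = "dlm_design"
  )
}

#' @export
print.dlm_design <- function(x, ...) {
  cat(sprintf("<dlm_design: %d days x %d channels (+ intercept at fit time)>\n",
              nrow(x$data), length(x$channels)))
  print(x$lag_spec)
  invisible(x)
}

#' @export
as.matrix.dlm_design <- function(x, ...) {
  m <- as.matrix(x$data[, x$channels, drop = FALSE])
  rownames(m) <- x$data$day_index
  m
}

#' Export a design matrix to CSV
#'
#' @param design A `dlm_design`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "dlm_design"))
  readr::write_csv(design$data, path)
  invisible(path)
}
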