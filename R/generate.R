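#' Simulate ground-truth minute-level activity
#'
#' Generates one participant's true steps at 1-minute resolution over an
#' observation window. Bouts start as a Poisson process within each day's
#' waking window, last an exponential number of whole minutes (clipped at the
#' end of the waking window), and contribute a truncated-Normal cadence per
#' minute; overlapping bouts add. Every waking minute additionally accrues
#' Poisson incidental steps. Sleep minutes are zero.
#'
#' With a deterministic profile, bouts are instead laid on an evenly spaced
#' daily schedule with exact integer cadence and background, so the total is
#' exactly `n_days * (n_bouts * bout_duration * round(cadence_mean) +
#' remaining_waking_minutes * round(background_rate))`.
#'
#' @param profile An [activity_profile()].
#' @param window_hours Window length in hours (default 72).
#' @param seed Integer seed; fixed seed gives a reproducible stream.
#' @param participant_id,device_id Labels for the returned stream.
#' @param origin Window start (POSIXct, midnight recommended).
#' @return A minute-epoch [step_stream()] covering the window.
#' @export
generate_ground_truth <- function(profile, window_hours = 72, seed = 1L,
                                  participant_id = "p01",
                                  device_id = "truth",
                                  origin = .default_origin()) {
  stopifnot(inherits(profile, "activity_profile"), window_hours >= 1)
  n_min <- as.integer(round(window_hours * 60))
  minute_start <- origin + 60 * (seq_len(n_min) - 1L)
  hour_of_day <- as.numeric(format(minute_start, "%H", tz = "UTC")) +
    as.numeric(format(minute_start, "%M", tz = "UTC")) / 60
  waking <- hour_of_day >= profile$waking_window[1] &
    hour_of_day < profile$waking_window[2]
  steps <- numeric(n_min)
  day_index <- as.integer(as.Date(minute_start, tz = "UTC"))
  waking_hours <- diff(profile$waking_window)

  if (profile$deterministic) {
    n_bouts <- round(profile$bout_rate * waking_hours)
    cadence <- round(profile$cadence_mean)
    bg <- round(profile$background_rate)
    steps[waking] <- bg
    for (d in unique(day_index)) {
      wk <- which(waking & day_index == d)
      if (length(wk) == 0L || n_bouts == 0L) next
      dur <- round(profile$bout_duration)
      starts <- floor(seq(1, length(wk) - dur + 1, length.out = n_bouts))
      for (s in starts) {
        idx <- wk[s:min(s + dur - 1, length(wk))]
        steps[idx] <- bg + cadence
      }
    }
  } else {
    set.seed(seed)
    in_bout <- rep(0, n_min)
    for (d in unique(day_index)) {
      wk <- which(waking & day_index == d)
      if (length(wk) == 0L) next
      n_bouts <- rpois(1, profile$bout_rate * length(wk) / 60)
      if (n_bouts == 0L) next
      starts <- sample(seq_along(wk), n_bouts, replace = TRUE)
      durations <- pmax(1, round(rexp(n_bouts, rate = 1 / profile$bout_duration)))
      for (b in seq_len(n_bouts)) {
        idx <- wk[starts[b]:min(starts[b] + durations[b] - 1, length(wk))]
        # overlapping bouts superpose so the expectation stays closed-form
        in_bout[idx] <- in_bout[idx] + 1
      }
    }
    bout_min <- which(in_bout > 0)
    if (length(bout_min) > 0L) {
      cadence <- vapply(in_bout[bout_min], function(k) {
        sum(pmax(0, rnorm(k, profile$cadence_mean, profile$cadence_sd)))
      }, numeric(1))
      steps[bout_min] <- round(cadence)
    }
    if (profile$background_rate > 0) {
      steps[waking] <- steps[waking] +
        rpois(sum(waking), profile$background_rate)
    }
  }

  step_stream(participant_id, device_id,
              tibble(epoch_start = minute_start,
                     epoch_minutes = 1,
                     steps = as.integer(steps)))
}

#' Observe a true stream through a device error model
#'
#' Applies a [device_error_model()] to a minute-resolution truth stream.
#' Processing order: low-cadence minute misses, re-binning to the device's
#' update interval (fixed blocks, or exponential gaps quantised to whole
#' minutes for variable-rate devices), deterministic under-/over-count
#' scaling with rounding, additive Gaussian epoch noise (clamped at zero),
#' the overnight carryover artifact (phantom steps on the first epoch of each
#' calendar day), whole-day malfunction loss, and battery-death truncation.
#'
#' The identity model returns the truth re-binned only, conserving totals.
#'
#' @param truth A minute-resolution [step_stream()].
#' @param model A [device_error_model()].
#' @param seed Integer seed.
#' @param device_id Label for the observed stream (defaults to the truth's).
#' @return A [step_stream()] as the device would report it.
#' @export
observe <- function(truth, model, seed = 1L, device_id = truth$device_id) {
  stopifnot(inherits(truth, "step_stream"),
            inherits(model, "device_error_model"))
  if (!stream_is_minute_resolution(truth)) {
    stop("observe() requires a minute-resolution truth stream", call. = FALSE)
  }
  ep <- truth$epochs
  if (nrow(ep) == 0L) {
    return(step_stream(truth$participant_id, device_id, ep))
  }
  set.seed(seed)
  steps <- as.numeric(ep$steps)
  n_min <- length(steps)

  # 1. low-cadence misses on true minutes
  if (model$low_cadence_miss_prob > 0 && model$low_cadence_miss_threshold > 0) {
    slow <- which(steps > 0 & steps < model$low_cadence_miss_threshold)
    if (length(slow) > 0L) {
      missed <- runif(length(slow)) < model$low_cadence_miss_prob
      steps[slow[missed]] <- 0
    }
  }

  # 2. re-bin to the reporting interval
  if (identical(model$update_interval, "variable")) {
    gaps <- numeric(0)
    while (sum(gaps) < n_min) {
      gaps <- c(gaps, pmax(1, round(rexp(50, rate = 1 / model$mean_interval))))
    }
    bounds <- cumsum(gaps)
    bounds <- c(0, bounds[bounds < n_min], n_min)
  } else {
    k <- model$update_interval
    bounds <- unique(c(seq(0, n_min, by = k), n_min))
  }
  group <- findInterval(seq_len(n_min) - 1L, bounds, rightmost.closed = FALSE)
  binned <- as.numeric(tapply(steps, group, sum))
  epoch_start <- ep$epoch_start[bounds[-length(bounds)] + 1L]
  epoch_minutes <- diff(bounds)

  # 3. systematic under-/over-count (deterministic scaling)
  obs <- round((1 - model$undercount_fraction) * binned)

  # 4. per-epoch Gaussian miscount noise. Applied only where the epoch count
  # is at least twice the noise SD: an idle device reports zero rather than
  # inventing steps, and restricting to clearly active epochs keeps the
  # zero-clamp from biasing the expected total (clamp probability < 2.3%,
  # truncation bias below 0.01 SD per epoch)
  if (model$epoch_noise_sd > 0) {
    active <- obs >= 2 * model$epoch_noise_sd
    obs[active] <- obs[active] +
      round(rnorm(sum(active), 0, model$epoch_noise_sd))
  }
  obs <- pmax(0, obs)

  day <- as.Date(epoch_start, tz = "UTC")

  # 5. overnight carryover: phantom steps on each day's first epoch
  if (model$carryover_enabled) {
    first_of_day <- !duplicated(day)
    phantom <- round(runif(sum(first_of_day),
                           model$carryover_steps_range[1],
                           model$carryover_steps_range[2]))
    obs[first_of_day] <- obs[first_of_day] + phantom
  }

  keep <- rep(TRUE, length(obs))

  # 6. whole-day malfunction loss
  if (model$malfunction_day_prob > 0) {
    days <- unique(day)
    lost <- days[runif(length(days)) < model$malfunction_day_prob]
    keep[day %in% lost] <- FALSE
  }

  # 7. battery death: truncate at a uniform random time
  if (model$battery_death_prob > 0 && runif(1) < model$battery_death_prob) {
    death_min <- runif(1, 0, n_min)
    end_min <- (as.numeric(epoch_start - ep$epoch_start[1], units = "mins") +
                  epoch_minutes)
    keep[end_min > death_min] <- FALSE
  }

  step_stream(truth$participant_id, device_id,
              tibble(epoch_start = epoch_start[keep],
                     epoch_minutes = epoch_minutes[keep],
                     steps = as.integer(obs[keep])))
}
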