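#' Define a device observation-error model
#'
#' Describes how a wearable device turns true minute-level steps into its
#' reported stream. The observation chain, applied in order:
#' low-cadence miss (slow minutes dropped with some probability), re-binning
#' to the device's update interval, systematic under-/over-counting, per-epoch
#' Gaussian noise, an overnight carryover artifact (phantom steps added to the
#' first epoch of each calendar day), whole-day malfunction loss, and battery
#' death (stream truncation).
#'
#' The default arguments give the identity model: 1-minute epochs and no
#' error, so the observed stream reproduces the truth exactly.
#'
#' @param update_interval Reporting interval in minutes (>= 1) for a fixed
#'   update rate, or the string `"variable"` for exponentially distributed
#'   gaps with mean `mean_interval`.
#' @param mean_interval Mean gap in minutes when `update_interval` is
#'   `"variable"`.
#' @param undercount_fraction Fraction of true steps missed; negative values
#'   mean overcounting. Applied as a deterministic scaling of each epoch.
#' @param epoch_noise_sd SD of additive Gaussian noise per reported epoch.
#' @param low_cadence_miss_threshold Steps/minute below which a minute may be
#'   missed entirely.
#' @param low_cadence_miss_prob Probability in `[0, 1]` of missing such a
#'   minute.
#' @param carryover_enabled Add phantom steps at the start of each day.
#' @param carryover_steps_range Length-2 numeric, uniform range of phantom
#'   steps per day.
#' @param malfunction_day_prob Probability a whole device-day is lost.
#' @param battery_death_prob Probability the stream truncates at a uniform
#'   random time in the window.
#' @return An object of class `device_error_model`.
#' @seealso [observe()]
#' @export
device_error_model <- function(update_interval = 1,
                               mean_interval = NULL,
                               undercount_fraction = 0,
                               epoch_noise_sd = 0,
                               low_cadence_miss_threshold = 0,
                               low_cadence_miss_prob = 0,
                               carryover_enabled = FALSE,
                               carryover_steps_range = c(0, 0),
                               malfunction_day_prob = 0,
                               battery_death_prob = 0) {
  variable <- identical(update_interval, "variable")
  if (variable) {
    if (is.null(mean_interval) || !is.numeric(mean_interval) ||
        mean_interval < 1) {
      stop("a variable update interval requires mean_interval >= 1 minute",
           call. = FALSE)
    }
  } else {
    if (!is.numeric(update_interval) || length(update_interval) != 1L ||
        update_interval < 1) {
      stop("fixed update_interval must be >= 1 minute", call. = FALSE)
    }
  }
  check_prob <- function(p, name) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop(name, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  check_prob(low_cadence_miss_prob, "low_cadence_miss_prob")
  check_prob(malfunction_day_prob, "malfunction_day_prob")
  check_prob(battery_death_prob, "battery_death_prob")
  stopifnot(is.numeric(undercount_fraction), length(undercount_fraction) == 1L,
            is.numeric(epoch_noise_sd), epoch_noise_sd >= 0,
            is.numeric(carryover_steps_range),
            length(carryover_steps_range) == 2L,
            carryover_steps_range[1] <= carryover_steps_range[2],
            all(carryover_steps_range >= 0))
  structure(
    list(update_interval = update_interval,
         mean_interval = mean_interval,
         undercount_fraction = undercount_fraction,
         epoch_noise_sd = epoch_noise_sd,
         low_cadence_miss_threshold = low_cadence_miss_threshold,
         low_cadence_miss_prob = low_cadence_miss_prob,
         carryover_enabled = isTRUE(carryover_enabled),
         carryover_steps_range = carryover_steps_range,
         malfunction_day_prob = malfunction_day_prob,
         battery_death_prob = battery_death_prob),
    class = "device_error_model"
  )
}

is_identity_model <- function(m) {
  !identical(m$update_interval, "variable") &&
    m$undercount_fraction == 0 && m$epoch_noise_sd == 0 &&
    m$low_cadence_miss_prob == 0 && !m$carryover_enabled &&
    m$malfunction_day_prob == 0 && m$battery_death_prob == 0
}

#' Default device error models for a four-tracker validation study
#'
#' Parameters emulate the behaviour reported for hip/wrist consumer trackers
#' validated against a 1-minute research accelerometer over 72 hours:
#' a reference with no error; a smartwatch with a variable update interval
#' (mean ~9 min, i.e. ~470 data points per 72 h), mild undercount and
#' occasional battery death; a 5-minute-fixed-interval hip tracker with
#' systematic ~9% undercount and rare day loss; a sparse-syncing tracker
#' (mean interval ~130 min, ~33 points per 72 h) that overcounts, is noisy
#' and shows the overnight carryover artifact; and a once-daily diary
#' pedometer with large day-to-day noise and frequent lost days.
#'
#' @param reference_id Device id used for the reference stream.
#' @return A named list of [device_error_model()] objects; the reference is
#'   the identity model.
#' @export
default_device_models <- function(reference_id = "actigraph") {
  models <- list(
    device_error_model(), # reference: identity
    watch = device_error_model(
      update_interval = "variable", mean_interval = 9.25,
      undercount_fraction = 0.045, epoch_noise_sd = 40,
      battery_death_prob = 0.10),
    hip_tracker = device_error_model(
      update_interval = 5,
      undercount_fraction = 0.094, epoch_noise_sd = 20,
      malfunction_day_prob = 0.033),
    sparse_tracker = device_error_model(
      update_interval = "variable", mean_interval = 131,
      undercount_fraction = -0.12, epoch_noise_sd = 700,
      carryover_enabled = TRUE, carryover_steps_range = c(100, 600),
      malfunction_day_prob = 0.022),
    diary_pedometer = device_error_model(
      update_interval = 1440,
      undercount_fraction = 0.093, epoch_noise_sd = 2500,
      malfunction_day_prob = 0.078)
  )
  names(models)[1] <- reference_id
  models
}

#' @export
print.device_error_model <- function(x, ...) {
  cat("<device_error_model>\n")
  interval <- if (identical(x$update_interval, "variable")) {
    sprintf("variable (mean %.1f min)", x$mean_interval)
  } else {
    sprintf("fixed %g min", x$update_interval)
  }
  cat("  update interval:", interval, "\n")
  cat(sprintf("  undercount %.3f, epoch noise SD %g\n",
              x$undercount_fraction, x$epoch_noise_sd))
  if (x$carryover_enabled) {
    cat(sprintf("  carryover %g-%g steps/day\n",
                x$carryover_steps_range[1], x$carryover_steps_range[2]))
  }
  if (x$malfunction_day_prob > 0 || x$battery_death_prob > 0) {
    cat(sprintf("  P(day lost) %.3f, P(battery death) %.3f\n",
                x$malfunction_day_prob, x$battery_death_prob))
  }
  invisible(x)
}
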