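#' Bland-Altman agreement analysis for paired step totals
#'
#' Computes the mean difference (bias), its sample standard deviation and the
#' 95% limits of agreement for one tracker against the reference. The
#' difference is fixed as `reference - tracker`, so a positive bias means the
#' tracker undercounts on average. The SD uses the n-1 denominator and the
#' limits are `bias +/- multiplier * SD` with multiplier exactly 1.96 by
#' default (no t-quantile).
#'
#' @param pairs A `paired_totals` tibble with columns `reference_steps` and
#'   `tracker_steps` for a single device (see [device_pairs()]).
#' @param loa_multiplier Multiplier for the limits of agreement.
#' @return A list of class `bland_altman` with `device_id`, `n_pairs`,
#'   `bias`, `sd`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(pairs, loa_multiplier = 1.96) {
  check_pairs(pairs)
  n <- nrow(pairs)
  if (n < 2L) {
    stop("Bland-Altman analysis needs at least 2 pairs (got ", n, ")",
         call. = FALSE)
  }
  d <- pairs$reference_steps - pairs$tracker_steps
  bias <- mean(d)
  s <- stats::sd(d) # n - 1 denominator
  structure(
    list(device_id = pairs_device(pairs), n_pairs = n,
         bias = bias, sd = s,
         loa_low = bias - loa_multiplier * s,
         loa_high = bias + loa_multiplier * s,
         loa_multiplier = loa_multiplier),
    class = "bland_altman")
}

#' Median absolute percentage difference (MAD)
#'
#' The accuracy statistic `median(|tracker - reference| / reference) * 100`,
#' computed on per-participant totals over the analysis window. The median
#' uses the standard even-n mean of the two central values. Values at or
#' below 15% are conventionally considered clinically acceptable.
#'
#' @inheritParams bland_altman
#' @return The MAD as a percentage (numeric scalar).
#' @export
mad_percent <- function(pairs) {
  check_pairs(pairs)
  if (nrow(pairs) < 1L) {
    stop("MAD needs at least 1 pair", call. = FALSE)
  }
  if (any(pairs$reference_steps <= 0)) {
    stop("MAD is undefined for non-positive reference totals", call. = FALSE)
  }
  rel <- abs(pairs$tracker_steps - pairs$reference_steps) /
    pairs$reference_steps
  stats::median(rel) * 100
}

#' Leave-one-out cross-validated bias correction
#'
#' Estimates a per-device bias correction and validates it out-of-sample:
#' for each participant i, the bias is estimated on the other n-1 pairs and
#' applied to participant i's tracker total; the MAD of the corrected pairs
#' is the cross-validated accuracy after correction.
#'
#' The default correction is additive (`corrected = tracker + bias_fold`,
#' with `bias_fold = mean(reference - tracker)` over the training pairs),
#' matching the Bland-Altman bias definition. A proportional variant
#' (`corrected = tracker * mean(reference) / mean(tracker)` over the
#' training pairs) is available via `method = "proportional"`.
#'
#' @inheritParams bland_altman
#' @param method `"additive"` (default) or `"proportional"`.
#' @return A list of class `loocv_correction` with `mad_corrected_percent`,
#'   `per_fold_bias` (one training-set bias per held-out participant; for the
#'   proportional method, one ratio per fold), `corrected_pairs` and
#'   `method`.
#' @export
loocv_bias_correction <- function(pairs, method = c("additive", "proportional")) {
  check_pairs(pairs)
  method <- match.arg(method)
  n <- nrow(pairs)
  if (n < 3L) {
    stop("leave-one-out bias correction needs at least 3 pairs (got ", n, ")",
         call. = FALSE)
  }
  ref <- pairs$reference_steps
  trk <- pairs$tracker_steps
  per_fold <- numeric(n)
  corrected <- numeric(n)
  for (i in seq_len(n)) {
    if (method == "additive") {
      per_fold[i] <- mean(ref[-i] - trk[-i])
      corrected[i] <- trk[i] + per_fold[i]
    } else {
      per_fold[i] <- mean(ref[-i]) / mean(trk[-i])
      corrected[i] <- trk[i] * per_fold[i]
    }
  }
  corrected_pairs <- pairs
  corrected_pairs$tracker_steps <- corrected
  structure(
    list(mad_corrected_percent = mad_percent(corrected_pairs),
         per_fold_bias = per_fold,
         corrected_pairs = corrected_pairs,
         method = method),
    class = "loocv_correction")
}

#' Bland-Altman plot data
#'
#' One `(mean, difference)` point per retained pair plus the three horizontal
#' reference values (bias and both limits of agreement) used to draw a
#' Bland-Altman plot.
#'
#' @inheritParams bland_altman
#' @return A list with `points` — tibble
#'   `(participant_id, mean_steps, diff_steps)` — and `lines`, a named
#'   numeric vector `(bias, loa_low, loa_high)`.
#' @export
ba_plot_data <- function(pairs, loa_multiplier = 1.96) {
  ba <- bland_altman(pairs, loa_multiplier)
  points <- tibble(
    participant_id = pairs$participant_id,
    mean_steps = (pairs$reference_steps + pairs$tracker_steps) / 2,
    diff_steps = pairs$reference_steps - pairs$tracker_steps)
  list(points = points,
       lines = c(bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high))
}

#' Full agreement summary for one device
#'
#' Combines [bland_altman()], [mad_percent()] and [loocv_bias_correction()]
#' into one per-device summary.
#'
#' @inheritParams loocv_bias_correction
#' @param loa_multiplier Multiplier for the limits of agreement.
#' @return A list of class `agreement_summary` with fields `device_id`,
#'   `n_pairs`, `bias`, `sd`, `loa_low`, `loa_high`, `mad_percent`,
#'   `mad_corrected_percent`, `per_fold_bias` and `correction_method`.
#' @export
agreement_summary <- function(pairs, method = c("additive", "proportional"),
                              loa_multiplier = 1.96) {
  ba <- bland_altman(pairs, loa_multiplier)
  cv <- loocv_bias_correction(pairs, method)
  structure(
    list(device_id = ba$device_id, n_pairs = ba$n_pairs,
         bias = ba$bias, sd = ba$sd,
         loa_low = ba$loa_low, loa_high = ba$loa_high,
         mad_percent = mad_percent(pairs),
         mad_corrected_percent = cv$mad_corrected_percent,
         per_fold_bias = cv$per_fold_bias,
         correction_method = cv$method),
    class = "agreement_summary")
}

#' Summarise agreement for every device in a paired-totals table
#'
#' @param pairs A `paired_totals` tibble covering one or more devices.
#' @param method,loa_multiplier Passed to [agreement_summary()].
#' @param min_pairs Devices with fewer pairs are skipped (LOOCV needs 3).
#' @return A tibble with one row per device: `device_id, n_pairs,
#'   mad_percent, sd, bias, loa_low, loa_high, mad_corrected_percent`, plus
#'   a list of the underlying `agreement_summary` objects as attribute
#'   `summaries` and the skipped devices as attribute `skipped`.
#' @export
summarize_agreement <- function(pairs, method = c("additive", "proportional"),
                                loa_multiplier = 1.96, min_pairs = 3L) {
  devices <- unique(pairs$device_id)
  summaries <- list()
  skipped <- tibble(device_id = character(), n_pairs = integer())
  rows <- list()
  for (dev in devices) {
    dp <- device_pairs(pairs, dev)
    if (nrow(dp) < min_pairs) {
      skipped <- bind_rows(skipped,
                           tibble(device_id = dev, n_pairs = nrow(dp)))
      next
    }
    s <- agreement_summary(dp, method, loa_multiplier)
    summaries[[dev]] <- s
    rows[[dev]] <- tibble(
      device_id = dev, n_pairs = s$n_pairs,
      mad_percent = s$mad_percent, sd = s$sd, bias = s$bias,
      loa_low = s$loa_low, loa_high = s$loa_high,
      mad_corrected_percent = s$mad_corrected_percent)
  }
  out <- if (length(rows) > 0L) bind_rows(rows) else
    tibble(device_id = character(), n_pairs = integer(),
           mad_percent = numeric(), sd = numeric(), bias = numeric(),
           loa_low = numeric(), loa_high = numeric(),
           mad_corrected_percent = numeric())
  structure(out, summaries = summaries, skipped = skipped)
}

check_pairs <- function(pairs) {
  if (!all(c("reference_steps", "tracker_steps") %in% names(pairs))) {
    stop("pairs must have reference_steps and tracker_steps columns",
         call. = FALSE)
  }
  if (anyNA(pairs$reference_steps) || anyNA(pairs$tracker_steps)) {
    stop("pairs contain missing totals; drop them before analysis",
         call. = FALSE)
  }
  invisible(pairs)
}

pairs_device <- function(pairs) {
  if ("device_id" %in% names(pairs) && nrow(pairs) > 0L) {
    dev <- unique(pairs$device_id)
    if (length(dev) > 1L) {
      stop("pairs span multiple devices; use device_pairs() first",
           call. = FALSE)
    }
    dev
  } else {
    NA_character_
  }
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman>", if (!is.na(x$device_id)) x$device_id else "", "\n")
  cat(sprintf("  n = %d; bias %.0f, SD %.0f, %s%% LoA [%.0f, %.0f]\n",
              x$n_pairs, x$bias, x$sd,
              format(100 * (2 * stats::pnorm(x$loa_multiplier) - 1),
                     digits = 3),
              x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat("<agreement_summary>", x$device_id, "\n")
  cat(sprintf("  n = %d pairs\n", x$n_pairs))
  cat(sprintf("  bias %.0f steps (positive = tracker undercounts), SD %.0f\n",
              x$bias, x$sd))
  cat(sprintf("  95%% LoA [%.0f, %.0f] steps\n", x$loa_low, x$loa_high))
  cat(sprintf("  MAD %.1f%%; after %s LOOCV correction %.1f%%\n",
              x$mad_percent, x$correction_method, x$mad_corrected_percent))
  invisible(x)
}
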