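#' Run the full validation pipeline on a study manifest
#'
#' Chains the pipeline: read the manifest and streams, detect nonwear on each
#' participant's reference stream, excise it from all of that participant's
#' devices, aggregate to per-participant paired totals over the analysis
#' window, and compute per-device agreement summaries (Bland-Altman bias, SD
#' and limits of agreement; MAD%; leave-one-out cross-validated corrected
#' MAD%). The run is deterministic for fixed inputs and options.
#'
#' The analysis window is per participant: `window_hours` from that
#' participant's first reference epoch. Devices with fewer than 3 usable
#' pairs are reported in the exclusions table rather than summarised, so
#' every manifest device appears exactly once in summaries or exclusions.
#'
#' @param manifest_path Path to a manifest CSV (see [read_streams()]).
#' @param out_dir Optional output directory; when given, writes
#'   `summary.csv`, `summary.json`, `paired_totals.csv`, `exclusions.csv`,
#'   `wear_mask.csv` and one `ba_points_<device>.csv` per summarised device.
#' @param nonwear_min_run Minimum zero-run minutes flagged nonworn
#'   (default 60).
#' @param window_hours Analysis window length (default 72).
#' @param correction `"additive"` or `"proportional"` LOOCV bias correction.
#' @param loa_multiplier Limits-of-agreement multiplier (default 1.96).
#' @param mad_threshold Acceptability threshold on MAD% (default 15).
#' @return An object of class `validation_report`: list with `meta`
#'   (options, version, config hash), `summary` (Table-style tibble),
#'   `summaries` (per-device `agreement_summary`), `pairs`, `exclusions`,
#'   `masks` and `ba_points`.
#' @export
run_validate <- function(manifest_path, out_dir = NULL,
                         nonwear_min_run = 60, window_hours = 72,
                         correction = c("additive", "proportional"),
                         loa_multiplier = 1.96, mad_threshold = 15) {
  correction <- match.arg(correction)
  loaded <- read_streams(manifest_path)
  streams <- loaded$streams
  manifest <- loaded$manifest
  ref_ids <- unique(manifest$device_id[manifest$is_reference])
  if (length(ref_ids) != 1L) {
    stop("manifest must designate exactly one reference device", call. = FALSE)
  }
  reference_device <- ref_ids

  # per-participant nonwear masks from the reference, applied to all devices
  masks <- list()
  masked <- streams
  excl_pre <- list()
  for (pid in unique(manifest$participant_id)) {
    keys <- names(streams)[vapply(streams, function(s)
      s$participant_id == pid, logical(1))]
    ref_key <- keys[vapply(streams[keys], function(s)
      s$device_id == reference_device, logical(1))]
    if (length(ref_key) == 0L || nrow(streams[[ref_key[1]]]$epochs) == 0L) {
      for (k in keys) {
        excl_pre[[length(excl_pre) + 1L]] <- tibble(
          participant_id = pid, device_id = streams[[k]]$device_id,
          reason = "no usable reference data")
      }
      masked[keys] <- NULL
      next
    }
    ref <- streams[[ref_key[1]]]
    # per-participant analysis window: window_hours from the first
    # reference epoch
    w0 <- min(ref$epochs$epoch_start)
    w1 <- w0 + window_hours * 3600
    mask <- detect_nonwear(ref, nonwear_min_run)
    masks[[pid]] <- mask
    masked[keys] <- lapply(mask_streams(streams[keys], mask),
                           clip_stream, start = w0, end = w1)
  }
  if (length(masked) == 0L) {
    stop("no usable pairs: no participant has reference data", call. = FALSE)
  }

  agg <- aggregate_pairs(masked, reference_device)
  pairs <- agg$pairs
  exclusions <- bind_rows(c(excl_pre, list(agg$exclusions)))

  summary_tbl <- summarize_agreement(pairs, method = correction,
                                     loa_multiplier = loa_multiplier)
  skipped <- attr(summary_tbl, "skipped")
  if (nrow(skipped) > 0L) {
    exclusions <- bind_rows(exclusions, tibble(
      participant_id = NA_character_, device_id = skipped$device_id,
      reason = sprintf("insufficient pairs for analysis (n=%d)",
                       skipped$n_pairs)))
  }
  summary_tbl$acceptable <- summary_tbl$mad_percent <= mad_threshold
  summary_tbl$acceptable_after_correction <-
    summary_tbl$mad_corrected_percent <= mad_threshold

  ba_points <- lapply(setNames(summary_tbl$device_id, summary_tbl$device_id),
                      function(dev) {
                        ba_plot_data(device_pairs(pairs, dev), loa_multiplier)
                      })

  options <- list(nonwear_min_run = nonwear_min_run,
                  window_hours = window_hours,
                  correction = correction,
                  loa_multiplier = loa_multiplier,
                  mad_threshold = mad_threshold)
  meta <- list(
    n_participants = length(unique(manifest$participant_id)),
    reference_device = reference_device,
    options = options,
    package_version = as.character(utils::packageVersion("stepagree")),
    config_hash = config_hash(manifest_path, options))

  report <- structure(
    list(meta = meta, summary = summary_tbl,
         summaries = attr(summary_tbl, "summaries"),
         pairs = pairs, exclusions = exclusions, masks = masks,
         ba_points = ba_points),
    class = "validation_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# md5 over the manifest, every referenced stream file and the options, so
# identical inputs reproduce the hash
config_hash <- function(manifest_path, options) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  files <- c(manifest_path, file.path(dirname(manifest_path), manifest$path))
  files <- files[file.exists(files)]
  sums <- unname(tools::md5sum(files))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(list(files = sums, options = options), tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a validation report to disk
#'
#' Emits the documented CSV/JSON contract: `summary.csv` (device_id,
#' n_pairs, mad_percent, sd, bias, loa_low, loa_high,
#' mad_corrected_percent, acceptable, acceptable_after_correction; steps
#' rounded to integers and MAD to one decimal), `summary.json` (full
#' precision, stable key order), `paired_totals.csv`, `exclusions.csv`,
#' `wear_mask.csv` and `ba_points_<device>.csv`.
#'
#' @param report A `validation_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- report$summary
  rounded <- tibble(
    device_id = s$device_id, n_pairs = s$n_pairs,
    mad_percent = round(s$mad_percent, 1),
    sd = round(s$sd), bias = round(s$bias),
    loa_low = round(s$loa_low), loa_high = round(s$loa_high),
    mad_corrected_percent = round(s$mad_corrected_percent, 1),
    acceptable = s$acceptable,
    acceptable_after_correction = s$acceptable_after_correction)
  readr::write_csv(rounded, file.path(out_dir, "summary.csv"))

  json_obj <- list(
    meta = report$meta,
    summary = lapply(report$summaries, function(x) {
      list(device_id = x$device_id, n_pairs = x$n_pairs,
           bias = x$bias, sd = x$sd,
           loa_low = x$loa_low, loa_high = x$loa_high,
           mad_percent = x$mad_percent,
           mad_corrected_percent = x$mad_corrected_percent,
           per_fold_bias = x$per_fold_bias,
           correction_method = x$correction_method)
    }))
  jsonlite::write_json(json_obj, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  readr::write_csv(as_tibble(report$pairs)[, c("device_id", "participant_id",
                                               "reference_steps",
                                               "tracker_steps")],
                   file.path(out_dir, "paired_totals.csv"))
  readr::write_csv(report$exclusions, file.path(out_dir, "exclusions.csv"))
  mask_rows <- bind_rows(lapply(names(report$masks), function(pid) {
    m <- report$masks[[pid]]
    tibble(participant_id = pid,
           start = format(m$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
           end = format(m$end, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
           status = m$status)
  }))
  readr::write_csv(mask_rows, file.path(out_dir, "wear_mask.csv"))
  for (dev in names(report$ba_points)) {
    bp <- report$ba_points[[dev]]
    pts <- bp$points
    pts$bias <- bp$lines[["bias"]]
    pts$loa_low <- bp$lines[["loa_low"]]
    pts$loa_high <- bp$lines[["loa_high"]]
    readr::write_csv(pts, file.path(out_dir,
                                    paste0("ba_points_", dev, ".csv")))
  }
  invisible(out_dir)
}

#' Simulate a study and write it to disk
#'
#' @param config A [study_config()] or path to a `study_config.json`.
#' @param out_dir Output directory.
#' @param quiet Suppress the summary message.
#' @return The manifest path, invisibly.
#' @export
run_simulate <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  study <- generate_study(config)
  manifest_path <- write_study(study, out_dir)
  if (!quiet) {
    message(sprintf(
      "simulated %d participants x %d devices (%d streams) -> %s",
      config$n_participants, length(config$device_models),
      length(study$streams), out_dir))
  }
  invisible(manifest_path)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$meta$n_participants, "participants, reference",
      x$meta$reference_device, "\n")
  cat("  window", x$meta$options$window_hours, "h; nonwear run >=",
      x$meta$options$nonwear_min_run, "min;", x$meta$options$correction,
      "correction\n")
  s <- x$summary
  if (nrow(s) > 0L) {
    out <- data.frame(
      device = s$device_id, n = s$n_pairs,
      `MAD%` = sprintf("%.1f", s$mad_percent),
      bias = round(s$bias), SD = round(s$sd),
      LoA = sprintf("[%d, %d]", round(s$loa_low), round(s$loa_high)),
      `corrected MAD%` = sprintf("%.1f", s$mad_corrected_percent),
      check.names = FALSE)
    print(out, row.names = FALSE)
  }
  if (nrow(x$exclusions) > 0L) {
    cat("  exclusions:", nrow(x$exclusions), "(see $exclusions)\n")
  }
  invisible(x)
}

#' Draw a Bland-Altman plot for one device
#'
#' Convenience wrapper around [ba_plot_data()]; requires ggplot2.
#'
#' @param pairs Paired totals for one device.
#' @param loa_multiplier Limits-of-agreement multiplier.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pairs, loa_multiplier = 1.96) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  bp <- ba_plot_data(pairs, loa_multiplier)
  ggplot2::ggplot(bp$points,
                  ggplot2::aes(x = mean_steps, y = diff_steps)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = bp$lines, linetype = c(1, 2, 2)) +
    ggplot2::labs(x = "Mean of reference and tracker (steps)",
                  y = "Reference - tracker (steps)",
                  title = pairs_device(pairs)) +
    ggplot2::theme_minimal()
}
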