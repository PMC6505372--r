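#' Configure a simulated validation study
#'
#' Bundles everything needed to simulate a multi-device free-living study:
#' participant count, window length, per-participant activity profiles,
#' per-device error models and the reference device. Defaults reproduce a
#' 30-participant, 72-hour study with a 1-minute reference accelerometer and
#' four consumer trackers (see [default_device_models()]).
#'
#' @param n_participants Number of participants (>= 2; default 30).
#' @param window_hours Observation window in hours (default 72).
#' @param device_models Named list of [device_error_model()] objects; names
#'   are device ids and must be unique.
#' @param reference_device Device id of the reference; must be a name of
#'   `device_models`.
#' @param profiles Optional list of `n_participants` [activity_profile()]
#'   objects; when `NULL` they are drawn with [draw_profiles()].
#' @param median_daily_steps,profile_log_sd Parameters passed to
#'   [draw_profiles()] when `profiles` is `NULL`.
#' @param nonwear Optional data frame `(participant_id, start, end)` of
#'   device-off intervals (all devices read zero there); times as ISO-8601
#'   strings or POSIXct.
#' @param seed Integer master seed; every stream's seed derives from it.
#' @param origin Window start timestamp.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_participants = 30,
                         window_hours = 72,
                         device_models = default_device_models(),
                         reference_device = "actigraph",
                         profiles = NULL,
                         median_daily_steps = 21527 / 3,
                         profile_log_sd = 0.2,
                         nonwear = NULL,
                         seed = 1L,
                         origin = .default_origin()) {
  if (n_participants < 2) {
    stop("n_participants must be at least 2", call. = FALSE)
  }
  ids <- names(device_models)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids)) {
    stop("device_models must be uniquely named by device id", call. = FALSE)
  }
  if (!reference_device %in% ids) {
    stop("reference_device '", reference_device,
         "' is not among the device models", call. = FALSE)
  }
  for (m in device_models) stopifnot(inherits(m, "device_error_model"))
  if (!is.null(profiles)) {
    if (length(profiles) != n_participants) {
      stop("profiles must have one entry per participant", call. = FALSE)
    }
    for (p in profiles) stopifnot(inherits(p, "activity_profile"))
  }
  structure(
    list(n_participants = as.integer(n_participants),
         window_hours = window_hours,
         device_models = device_models,
         reference_device = reference_device,
         profiles = profiles,
         median_daily_steps = median_daily_steps,
         profile_log_sd = profile_log_sd,
         nonwear = nonwear,
         seed = as.integer(seed),
         origin = origin),
    class = "study_config"
  )
}

participant_ids <- function(config) {
  sprintf("p%02d", seq_len(config$n_participants))
}

#' Simulate a complete multi-device study
#'
#' Generates ground truth for each participant, observes it through every
#' device model (including the reference) and assembles a manifest. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [study_config()].
#' @return A list of class `simulated_study` with elements `streams` (list of
#'   [step_stream()]), `truth` (list of truth streams), `manifest` (tibble
#'   `participant_id, device_id, path, is_reference, n_epochs`; `path` is
#'   filled by [write_study()]) and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  pids <- participant_ids(config)
  profiles <- config$profiles
  if (is.null(profiles)) {
    profiles <- draw_profiles(config$n_participants,
                              median_daily_steps = config$median_daily_steps,
                              log_sd = config$profile_log_sd,
                              seed = derive_seed(config$seed, 0L))
  }
  nonwear <- normalise_nonwear(config$nonwear)
  device_ids <- names(config$device_models)
  streams <- list()
  truths <- list()
  rows <- list()
  for (i in seq_along(pids)) {
    truth <- generate_ground_truth(profiles[[i]], config$window_hours,
                                   seed = derive_seed(config$seed, i),
                                   participant_id = pids[i],
                                   origin = config$origin)
    if (!is.null(nonwear)) {
      truth <- zero_out_intervals(truth, nonwear[nonwear$participant_id == pids[i], ])
    }
    truths[[pids[i]]] <- truth
    for (j in seq_along(device_ids)) {
      dev <- device_ids[j]
      obs <- observe(truth, config$device_models[[dev]],
                     seed = derive_seed(config$seed, i, j),
                     device_id = dev)
      key <- paste(pids[i], dev, sep = "_")
      streams[[key]] <- obs
      rows[[key]] <- tibble(participant_id = pids[i], device_id = dev,
                            path = NA_character_,
                            is_reference = dev == config$reference_device,
                            n_epochs = nrow(obs$epochs))
    }
  }
  structure(list(streams = streams, truth = truths,
                 manifest = bind_rows(rows), config = config),
            class = "simulated_study")
}

# devices read zero while physically off the body
zero_out_intervals <- function(stream, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(stream)
  ep <- stream$epochs
  frac <- epoch_overlap_minutes(ep$epoch_start, ep$epoch_minutes,
                                iv_new(iv$start, iv$end)) / ep$epoch_minutes
  ep$steps <- as.integer(round(ep$steps * (1 - frac)))
  step_stream(stream$participant_id, stream$device_id, ep)
}

normalise_nonwear <- function(nw) {
  if (is.null(nw)) return(NULL)
  nw <- as_tibble(nw)
  stopifnot(all(c("participant_id", "start", "end") %in% names(nw)))
  if (!inherits(nw$start, "POSIXct")) {
    nw$start <- as.POSIXct(nw$start, tz = "UTC")
    nw$end <- as.POSIXct(nw$end, tz = "UTC")
  }
  nw
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study>", x$config$n_participants, "participants x",
      length(x$config$device_models), "devices,",
      x$config$window_hours, "h window\n")
  cat("  reference:", x$config$reference_device,
      " seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' One CSV per stream (`participant_id,device_id,epoch_start_iso8601,`
#' `epoch_minutes,steps`), a `manifest.csv`
#' (`participant_id,device_id,path,is_reference,n_epochs`) and the study
#' configuration as `study_config.json`.
#'
#' @param study A `simulated_study` from [generate_study()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- study$manifest
  paths <- character(nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    key <- paste(manifest$participant_id[k], manifest$device_id[k], sep = "_")
    fn <- paste0(key, ".csv")
    write_stream_csv(study$streams[[key]], file.path(out_dir, fn))
    paths[k] <- fn
  }
  manifest$path <- paths
  manifest_path <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  write_study_config(study$config, file.path(out_dir, "study_config.json"))
  invisible(manifest_path)
}

write_stream_csv <- function(stream, path) {
  df <- tibble(
    participant_id = rep(stream$participant_id, nrow(stream$epochs)),
    device_id = rep(stream$device_id, nrow(stream$epochs)),
    epoch_start_iso8601 = format(stream$epochs$epoch_start,
                                 "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    epoch_minutes = stream$epochs$epoch_minutes,
    steps = stream$epochs$steps)
  readr::write_csv(df, path)
}

#' Serialize / read a study configuration
#'
#' @param config A [study_config()].
#' @param path JSON file path.
#' @return `read_study_config()` returns a [study_config()].
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  as_list <- function(m) {
    m <- unclass(m)
    m[!vapply(m, is.null, logical(1))]
  }
  obj <- list(
    n_participants = config$n_participants,
    window_hours = config$window_hours,
    reference_device = config$reference_device,
    median_daily_steps = config$median_daily_steps,
    profile_log_sd = config$profile_log_sd,
    seed = config$seed,
    origin = format(config$origin, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    device_models = lapply(config$device_models, as_list)
  )
  if (!is.null(config$profiles)) {
    obj$profiles <- lapply(config$profiles, function(p) {
      p <- unclass(p); p[!vapply(p, is.null, logical(1))]
    })
  }
  if (!is.null(config$nonwear)) {
    nw <- normalise_nonwear(config$nonwear)
    nw$start <- format(nw$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    nw$end <- format(nw$end, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    obj$nonwear <- nw
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  models <- lapply(obj$device_models, function(m) {
    do.call(device_error_model, m)
  })
  profiles <- NULL
  if (!is.null(obj$profiles)) {
    profiles <- lapply(obj$profiles, function(p) {
      p$deterministic <- isTRUE(p$deterministic)
      do.call(activity_profile, p)
    })
  }
  study_config(
    n_participants = obj$n_participants,
    window_hours = obj$window_hours,
    device_models = models,
    reference_device = obj$reference_device,
    profiles = profiles,
    median_daily_steps = obj$median_daily_steps,
    profile_log_sd = obj$profile_log_sd,
    nonwear = obj$nonwear,
    seed = obj$seed,
    origin = as.POSIXct(obj$origin, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
}
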