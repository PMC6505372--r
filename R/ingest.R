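#' Read device streams listed in a manifest
#'
#' Loads the neutral CSV interchange format: a manifest with columns
#' `participant_id,device_id,path,is_reference` (paths relative to the
#' manifest's directory) and one stream CSV per device with columns
#' `participant_id,device_id,epoch_start_iso8601,epoch_minutes,steps`.
#'
#' Rows with empty or non-numeric ("not-a-number") step values are dropped
#' and counted; structurally invalid data — negative steps, sub-minute
#' epochs, out-of-order or overlapping epochs — abort with a diagnostic
#' naming the row, participant and device.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A list with `streams` (named list of [step_stream()], keyed
#'   `participant_device`), `manifest` (tibble) and `n_dropped_rows` (count
#'   of empty/invalid rows removed).
#' @export
read_streams <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  required <- c("participant_id", "device_id", "path", "is_reference")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  base <- dirname(manifest_path)
  streams <- list()
  dropped <- 0L
  for (k in seq_len(nrow(manifest))) {
    path <- file.path(base, manifest$path[k])
    who <- paste0("participant '", manifest$participant_id[k],
                  "', device '", manifest$device_id[k], "'")
    if (!file.exists(path)) {
      stop("stream file not found for ", who, ": ", path, call. = FALSE)
    }
    df <- readr::read_csv(
      path, show_col_types = FALSE,
      col_types = readr::cols(
        participant_id = readr::col_character(),
        device_id = readr::col_character(),
        epoch_start_iso8601 = readr::col_character(),
        epoch_minutes = readr::col_double(),
        steps = readr::col_double()))
    bad_steps <- is.na(df$steps) & !is.na(df$epoch_start_iso8601)
    neg <- which(!is.na(df$steps) & df$steps < 0)
    if (length(neg) > 0L) {
      stop("negative step count at row ", neg[1], " of ", basename(path),
           " (", who, ")", call. = FALSE)
    }
    drop <- is.na(df$steps) | is.na(df$epoch_start_iso8601) |
      is.na(df$epoch_minutes)
    dropped <- dropped + sum(drop)
    df <- df[!drop, , drop = FALSE]
    epochs <- tibble(
      epoch_start = as.POSIXct(df$epoch_start_iso8601,
                               format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      epoch_minutes = df$epoch_minutes,
      steps = as.integer(round(df$steps)))
    if (anyNA(epochs$epoch_start)) {
      stop("unparseable epoch_start_iso8601 at row ",
           which(is.na(epochs$epoch_start))[1], " of ", basename(path),
           " (", who, ")", call. = FALSE)
    }
    key <- paste(manifest$participant_id[k], manifest$device_id[k], sep = "_")
    streams[[key]] <- step_stream(manifest$participant_id[k],
                                  manifest$device_id[k], epochs)
  }
  list(streams = streams, manifest = manifest, n_dropped_rows = dropped)
}
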