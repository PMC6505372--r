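#' Construct a step stream
#'
#' A step stream holds one device's step counts for one participant as an
#' ordered sequence of reporting epochs. Each epoch is a half-open interval
#' `[epoch_start, epoch_start + epoch_minutes)` carrying a non-negative
#' integer step count. Epochs must be time-ordered and non-overlapping;
#' gaps are allowed (they represent time with no data, e.g. a lost day).
#'
#' @param participant_id Participant label.
#' @param device_id Device label.
#' @param epochs A data frame with columns `epoch_start` (POSIXct),
#'   `epoch_minutes` (numeric, >= 1) and `steps` (non-negative).
#' @return An object of class `step_stream`.
#' @export
step_stream <- function(participant_id, device_id, epochs) {
  epochs <- as_tibble(epochs)
  required <- c("epoch_start", "epoch_minutes", "steps")
  missing_cols <- setdiff(required, names(epochs))
  if (length(missing_cols) > 0L) {
    stop("epochs is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  epochs <- epochs[required]
  # epoch order is normalised here; overlaps remain errors
  if (nrow(epochs) > 1L) {
    epochs <- epochs[order(epochs$epoch_start), , drop = FALSE]
  }
  x <- structure(
    list(participant_id = as.character(participant_id),
         device_id = as.character(device_id),
         epochs = epochs),
    class = "step_stream"
  )
  validate_step_stream(x)
}

validate_step_stream <- function(x) {
  ep <- x$epochs
  who <- paste0("participant '", x$participant_id, "', device '",
                x$device_id, "'")
  if (nrow(ep) == 0L) return(x)
  if (!inherits(ep$epoch_start, "POSIXct")) {
    stop("epoch_start must be POSIXct for ", who, call. = FALSE)
  }
  bad <- which(is.na(ep$steps) | ep$steps < 0)
  if (length(bad) > 0L) {
    stop("negative or missing step count at epoch row ", bad[1], " for ", who,
         call. = FALSE)
  }
  bad <- which(is.na(ep$epoch_minutes) | ep$epoch_minutes < 1)
  if (length(bad) > 0L) {
    stop("epoch duration below 1 minute at epoch row ", bad[1], " for ", who,
         call. = FALSE)
  }
  if (is.unsorted(as.numeric(ep$epoch_start), strictly = TRUE)) {
    stop("epochs are not strictly time-ordered for ", who, call. = FALSE)
  }
  ends <- as.numeric(ep$epoch_start) + ep$epoch_minutes * 60
  if (nrow(ep) > 1L) {
    overlap <- which(ends[-nrow(ep)] > as.numeric(ep$epoch_start[-1]))
    if (length(overlap) > 0L) {
      stop("overlapping epochs at row ", overlap[1] + 1L, " for ", who,
           call. = FALSE)
    }
  }
  x
}

#' Total steps in a stream
#'
#' @param x A `step_stream`.
#' @return The sum of steps over all epochs.
#' @export
total_steps <- function(x) {
  stopifnot(inherits(x, "step_stream"))
  sum(x$epochs$steps)
}

# interval set covered by a stream's epochs (its data coverage)
stream_coverage <- function(x) {
  ep <- x$epochs
  iv_normalise(iv_new(ep$epoch_start,
                      ep$epoch_start + ep$epoch_minutes * 60))
}

stream_is_minute_resolution <- function(x) {
  nrow(x$epochs) == 0L || all(x$epochs$epoch_minutes == 1)
}

#' @export
print.step_stream <- function(x, ...) {
  ep <- x$epochs
  cat("<step_stream> participant", x$participant_id,
      "device", x$device_id, "\n")
  if (nrow(ep) == 0L) {
    cat("  (no epochs)\n")
    return(invisible(x))
  }
  cat(sprintf("  %d epochs, %s to %s\n", nrow(ep),
              format(min(ep$epoch_start), "%Y-%m-%d %H:%M"),
              format(max(ep$epoch_start + ep$epoch_minutes * 60),
                     "%Y-%m-%d %H:%M")))
  cat(sprintf("  total steps: %d\n", as.integer(round(sum(ep$steps)))))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.step_stream <- function(x, ...) {
  tibble(participant_id = x$participant_id,
         device_id = x$device_id,
         epoch_start = x$epochs$epoch_start,
         epoch_minutes = x$epochs$epoch_minutes,
         steps = x$epochs$steps)
}
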