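#' Detect nonwear time from the reference stream
#'
#' Flags maximal runs of consecutive zero-step minutes on the reference
#' monitor whose length is at least `min_zero_run_minutes` as nonworn;
#' everything else in the stream's span is worn. The rule is strict (no
#' interruption tolerance) and the threshold is a tunable parameter with a
#' 60-minute default. Minutes inside the span with no reference data are
#' treated as zero-count (no movement evidence), so long reference outages
#' fold into nonwear.
#'
#' @param reference A minute-resolution [step_stream()].
#' @param min_zero_run_minutes Minimum zero-run length flagged as nonwear
#'   (>= 1; default 60).
#' @return A `wear_mask`: tibble of intervals `(start, end, status)` with
#'   statuses alternating `worn`/`nonworn`, covering the stream's span
#'   exactly, with attributes `participant_id` and `window`.
#' @export
detect_nonwear <- function(reference, min_zero_run_minutes = 60) {
  stopifnot(inherits(reference, "step_stream"), min_zero_run_minutes >= 1)
  if (!stream_is_minute_resolution(reference)) {
    stop("nonwear detection requires a 1-minute-epoch reference stream",
         call. = FALSE)
  }
  ep <- reference$epochs
  if (nrow(ep) == 0L) {
    stop("reference stream has no epochs", call. = FALSE)
  }
  w_start <- min(ep$epoch_start)
  w_end <- max(ep$epoch_start) + 60
  n_min <- as.integer(round(as.numeric(w_end - w_start, units = "mins")))
  steps <- rep(0, n_min) # uncovered minutes count as zero
  idx <- as.integer(round(as.numeric(ep$epoch_start - w_start,
                                     units = "mins"))) + 1L
  steps[idx] <- ep$steps

  runs <- rle(steps == 0)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  nonworn <- runs$values & runs$lengths >= min_zero_run_minutes

  status <- rep("worn", length(runs$lengths))
  status[nonworn] <- "nonworn"
  # merge adjacent runs sharing a status so statuses strictly alternate
  grp <- cumsum(c(TRUE, status[-1] != status[-length(status)]))
  first_of <- !duplicated(grp)
  last_of <- !duplicated(grp, fromLast = TRUE)
  mask <- tibble(
    start = (w_start + (run_start - 1L) * 60)[first_of],
    end = (w_start + run_end * 60)[last_of],
    status = status[first_of])
  structure(mask, class = c("wear_mask", class(mask)),
            participant_id = reference$participant_id,
            window = c(w_start, w_end))
}

#' Construct a wear mask directly
#'
#' Builds the worn/nonworn interval set that [detect_nonwear()] derives from
#' a reference stream, from explicit intervals — useful for tests and for
#' supplying an externally determined mask.
#'
#' @param participant_id Participant label.
#' @param intervals Data frame with POSIXct `start`, `end` and `status`
#'   (`"worn"` or `"nonworn"`) covering the analysis window; adjacent
#'   intervals must not share a status.
#' @return A `wear_mask`.
#' @export
wear_mask <- function(participant_id, intervals) {
  intervals <- as_tibble(intervals)[, c("start", "end", "status")]
  stopifnot(all(intervals$status %in% c("worn", "nonworn")),
            nrow(intervals) >= 1L)
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  if (any(as.numeric(intervals$end) < as.numeric(intervals$start)) ||
      (nrow(intervals) > 1L &&
       any(as.numeric(intervals$end[-nrow(intervals)]) !=
           as.numeric(intervals$start[-1])))) {
    stop("mask intervals must tile the window without gaps or overlaps",
         call. = FALSE)
  }
  if (nrow(intervals) > 1L &&
      any(intervals$status[-1] == intervals$status[-nrow(intervals)])) {
    stop("adjacent mask intervals must not share a status", call. = FALSE)
  }
  structure(intervals, class = c("wear_mask", class(intervals)),
            participant_id = as.character(participant_id),
            window = c(min(intervals$start), max(intervals$end)))
}

nonworn_intervals <- function(mask) {
  iv_new(mask$start[mask$status == "nonworn"],
         mask$end[mask$status == "nonworn"])
}

worn_intervals <- function(mask) {
  iv_new(mask$start[mask$status == "worn"],
         mask$end[mask$status == "worn"])
}

#' Remove reference-defined nonwear time from paired streams
#'
#' Excises the mask's nonworn intervals from every stream of the same
#' participant, by wall-clock interval (tracker epochs are irregular, so
#' masking by epoch index would misalign): epochs fully inside a nonworn
#' interval are dropped; epochs partially overlapping are trimmed to their
#' worn sub-intervals, with steps apportioned to each retained piece in
#' proportion to its length and rounded to the nearest integer. After
#' masking, a stream's coverage is exactly its worn data time, which is what
#' [aggregate_pairs()] intersects across devices.
#'
#' Once-per-day diary epochs (duration of a calendar day or more) cannot be
#' sub-day masked — the daily count cannot be localised within the day — so
#' they are dropped only when the whole day is nonworn and otherwise kept
#' intact; this is a caveat of diary devices, not an error.
#'
#' @param streams A list of [step_stream()] for one participant (a single
#'   stream is also accepted).
#' @param mask A `wear_mask` from [detect_nonwear()] for the same
#'   participant.
#' @return A list of masked streams (or a single stream if one was given).
#' @export
mask_streams <- function(streams, mask) {
  stopifnot(inherits(mask, "wear_mask"))
  single <- inherits(streams, "step_stream")
  if (single) streams <- list(streams)
  pid <- attr(mask, "participant_id")
  out <- lapply(streams, function(s) {
    if (!identical(s$participant_id, pid)) {
      stop("wear mask is for participant '", pid, "' but stream is for '",
           s$participant_id, "'", call. = FALSE)
    }
    mask_one(s, mask)
  })
  if (single) out[[1]] else out
}

mask_one <- function(stream, mask) {
  nw <- iv_normalise(nonworn_intervals(mask))
  ep <- stream$epochs
  if (nrow(nw) == 0L || nrow(ep) == 0L) return(stream)
  ns <- as.numeric(nw$start)
  ne <- as.numeric(nw$end)
  out_start <- numeric(0)
  out_minutes <- numeric(0)
  out_steps <- numeric(0)
  for (i in seq_len(nrow(ep))) {
    s <- as.numeric(ep$epoch_start[i])
    dur <- ep$epoch_minutes[i] * 60
    e <- s + dur
    ov_s <- pmax(s, ns)
    ov_e <- pmin(e, ne)
    hit <- ov_e > ov_s
    if (!any(hit)) { # fully worn
      out_start <- c(out_start, s)
      out_minutes <- c(out_minutes, dur / 60)
      out_steps <- c(out_steps, ep$steps[i])
      next
    }
    overlap <- sum(ov_e[hit] - ov_s[hit])
    if (ep$epoch_minutes[i] >= 1440) {
      # diary-style day epoch: all-or-nothing, cannot be sub-day masked
      if (overlap < dur) {
        out_start <- c(out_start, s)
        out_minutes <- c(out_minutes, dur / 60)
        out_steps <- c(out_steps, ep$steps[i])
      }
      next
    }
    if (overlap >= dur) next # fully nonworn
    # worn sub-intervals = [s, e) minus the nonworn pieces
    cut_s <- sort(ov_s[hit])
    cut_e <- sort(ov_e[hit])
    keep_s <- c(s, cut_e)
    keep_e <- c(cut_s, e)
    ok <- keep_e > keep_s & (keep_e - keep_s) >= 60
    for (k in which(ok)) {
      piece <- keep_e[k] - keep_s[k]
      out_start <- c(out_start, keep_s[k])
      out_minutes <- c(out_minutes, piece / 60)
      out_steps <- c(out_steps, round(ep$steps[i] * piece / dur))
    }
  }
  ord <- order(out_start)
  step_stream(stream$participant_id, stream$device_id,
              tibble(epoch_start = as.POSIXct(out_start[ord],
                                              origin = "1970-01-01",
                                              tz = "UTC"),
                     epoch_minutes = out_minutes[ord],
                     steps = as.integer(out_steps[ord])))
}

#' @export
print.wear_mask <- function(x, ...) {
  nonworn <- sum(x$status == "nonworn")
  cat("<wear_mask> participant", attr(x, "participant_id"), "-",
      nrow(x), "intervals,", nonworn, "nonworn",
      sprintf("(%.0f min)\n", iv_total_minutes(nonworn_intervals(x))))
  NextMethod()
}
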