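#' Aggregate masked streams to per-participant paired totals
#'
#' For every participant and tracker, sums steps over the wall-clock set on
#' which both members of the pair have data: the analysis window intersected
#' with the reference's coverage and the tracker's coverage (worn time only,
#' when the streams were masked beforehand). Epochs partially overlapping the
#' analysis set contribute proportionally, rounded to the nearest step, so a
#' lost tracker day removes that day from both members of the pair while the
#' rest of the window is retained.
#'
#' Pairs are dropped, with a reason recorded in the exclusions table, when
#' either member has zero usable time in the window or when the reference
#' total is not positive (the MAD statistic divides by it).
#'
#' @param streams Named list of [step_stream()] objects (all participants and
#'   devices, typically masked with [mask_streams()]).
#' @param reference_device Device id of the reference monitor.
#' @param window Optional POSIXct length-2 `(start, end)`; defaults to the
#'   union span of the reference streams.
#' @return A list with `pairs` — a `paired_totals` tibble
#'   (`device_id, participant_id, reference_steps, tracker_steps`) — and
#'   `exclusions` (`participant_id, device_id, reason`).
#' @export
aggregate_pairs <- function(streams, reference_device, window = NULL) {
  stopifnot(length(streams) > 0L)
  info <- tibble(
    key = names(streams),
    participant_id = unname(vapply(streams, function(s) s$participant_id,
                                   character(1))),
    device_id = unname(vapply(streams, function(s) s$device_id,
                              character(1))))
  if (!reference_device %in% info$device_id) {
    stop("reference device '", reference_device,
         "' not present in the streams", call. = FALSE)
  }
  if (is.null(window)) {
    refs <- streams[info$key[info$device_id == reference_device]]
    spans <- lapply(refs, stream_coverage)
    spans <- bind_rows(spans)
    if (nrow(spans) == 0L) stop("reference streams are empty", call. = FALSE)
    window <- c(min(spans$start), max(spans$end))
  }
  window_iv <- iv_new(window[1], window[2])

  pairs <- list()
  excl <- list()
  note <- function(p, d, reason) tibble(participant_id = p, device_id = d,
                                        reason = reason)
  for (pid in unique(info$participant_id)) {
    sub <- info[info$participant_id == pid, ]
    ref_key <- sub$key[sub$device_id == reference_device]
    trackers <- sub[sub$device_id != reference_device, ]
    if (length(ref_key) == 0L) {
      for (d in trackers$device_id) {
        excl[[length(excl) + 1L]] <- note(pid, d, "no reference stream")
      }
      next
    }
    ref <- streams[[ref_key[1]]]
    ref_cov <- iv_intersect(stream_coverage(ref), window_iv)
    if (iv_total_minutes(ref_cov) == 0) {
      for (d in trackers$device_id) {
        excl[[length(excl) + 1L]] <-
          note(pid, d, "no usable reference time in window")
      }
      next
    }
    for (k in seq_len(nrow(trackers))) {
      trk <- streams[[trackers$key[k]]]
      dev <- trackers$device_id[k]
      trk_cov <- iv_intersect(stream_coverage(trk), window_iv)
      shared <- iv_intersect(ref_cov, trk_cov)
      if (iv_total_minutes(shared) == 0) {
        excl[[length(excl) + 1L]] <-
          note(pid, dev, "no usable tracker time in window")
        next
      }
      ref_total <- steps_in_intervals(ref, shared)
      trk_total <- steps_in_intervals(trk, shared)
      if (ref_total <= 0) {
        excl[[length(excl) + 1L]] <-
          note(pid, dev, "non-positive reference total")
        next
      }
      pairs[[length(pairs) + 1L]] <- tibble(
        device_id = dev, participant_id = pid,
        reference_steps = ref_total, tracker_steps = trk_total)
    }
  }
  pairs <- if (length(pairs) > 0L) bind_rows(pairs) else
    tibble(device_id = character(), participant_id = character(),
           reference_steps = numeric(), tracker_steps = numeric())
  pairs <- pairs[order(pairs$device_id, pairs$participant_id), ]
  exclusions <- if (length(excl) > 0L) bind_rows(excl) else
    tibble(participant_id = character(), device_id = character(),
           reason = character())
  list(pairs = structure(pairs, class = c("paired_totals", class(pairs))),
       exclusions = exclusions)
}

# steps of a stream falling in an interval set, proportional on partial
# epoch overlap, rounded per epoch; diary-style day epochs (>= 1440 min)
# cannot be apportioned within the day and count whole whenever they
# overlap the set at all
steps_in_intervals <- function(stream, iv) {
  ep <- stream$epochs
  if (nrow(ep) == 0L) return(0)
  frac <- epoch_overlap_minutes(ep$epoch_start, ep$epoch_minutes, iv) /
    ep$epoch_minutes
  daily <- ep$epoch_minutes >= 1440
  frac[daily] <- as.numeric(frac[daily] > 0)
  sum(round(ep$steps * frac))
}

# restrict a stream to [start, end): epochs outside are dropped, epochs
# straddling a boundary are trimmed with proportional (rounded) steps;
# diary-style day epochs are kept whole iff they start inside the window
clip_stream <- function(stream, start, end) {
  ep <- stream$epochs
  if (nrow(ep) == 0L) return(stream)
  s <- as.numeric(ep$epoch_start)
  e <- s + ep$epoch_minutes * 60
  w0 <- as.numeric(start)
  w1 <- as.numeric(end)
  daily <- ep$epoch_minutes >= 1440
  new_s <- pmax(s, w0)
  new_e <- pmin(e, w1)
  keep <- (new_e - new_s) >= 60
  keep[daily] <- s[daily] >= w0 & s[daily] < w1
  new_s[daily] <- s[daily]
  new_e[daily] <- e[daily]
  frac <- ifelse(daily, 1, (new_e - new_s) / (e - s))
  out <- tibble(
    epoch_start = as.POSIXct(new_s[keep], origin = "1970-01-01", tz = "UTC"),
    epoch_minutes = (new_e[keep] - new_s[keep]) / 60,
    steps = as.integer(round(ep$steps[keep] * frac[keep])))
  step_stream(stream$participant_id, stream$device_id, out)
}

#' Extract one device's pairs from a paired-totals table
#'
#' @param pairs A `paired_totals` tibble (see [aggregate_pairs()]).
#' @param device_id Device to keep.
#' @return A `paired_totals` tibble for that device.
#' @export
device_pairs <- function(pairs, device_id) {
  out <- pairs[pairs$device_id == device_id, , drop = FALSE]
  structure(out, class = unique(c("paired_totals", class(out))))
}
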