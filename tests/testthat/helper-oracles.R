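# Independent brute-force oracles, written with explicit sums and loops so
# they share no code path with the package implementations they check.

naive_bland_altman <- function(ref, trk, mult = 1.96) {
  n <- length(ref)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- ref[i] - trk[i]
  m <- sum(d) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - m)^2
  s <- sqrt(ss / (n - 1))
  list(bias = m, sd = s, loa_low = m - mult * s, loa_high = m + mult * s)
}

naive_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

naive_mad_percent <- function(ref, trk) {
  rel <- numeric(length(ref))
  for (i in seq_along(ref)) rel[i] <- abs(trk[i] - ref[i]) / ref[i]
  naive_median(rel) * 100
}

naive_loocv_mad <- function(ref, trk) {
  n <- length(ref)
  corrected <- numeric(n)
  folds <- numeric(n)
  for (i in seq_len(n)) {
    tot <- 0
    for (j in seq_len(n)) if (j != i) tot <- tot + (ref[j] - trk[j])
    folds[i] <- tot / (n - 1)
    corrected[i] <- trk[i] + folds[i]
  }
  list(mad = naive_mad_percent(ref, corrected), per_fold = folds)
}

# brute-force zero-run nonwear scan at minute resolution
naive_nonwear_minutes <- function(steps, threshold) {
  n <- length(steps)
  nonworn <- logical(n)
  i <- 1
  while (i <= n) {
    if (steps[i] == 0) {
      j <- i
      while (j < n && steps[j + 1] == 0) j <- j + 1
      if (j - i + 1 >= threshold) nonworn[i:j] <- TRUE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  nonworn
}

derive_seed_for_test <- function(s, i) s * 1000L + i

make_pairs <- function(ref, trk, device = "dev") {
  tibble::tibble(device_id = device,
                 participant_id = sprintf("p%02d", seq_along(ref)),
                 reference_steps = ref, tracker_steps = trk)
}

origin0 <- as.POSIXct("2024-06-03 00:00:00", tz = "UTC")

# minute stream over n_hours with a given per-minute step vector
minute_stream <- function(steps, participant = "p01", device = "ref",
                          origin = origin0) {
  step_stream(participant, device,
              tibble::tibble(
                epoch_start = origin + 60 * (seq_along(steps) - 1),
                epoch_minutes = 1,
                steps = as.integer(steps)))
}

# 10 steps/min during [08:00, 20:00), zero otherwise, for n_days
toy_pattern_minutes <- function(n_days = 3) {
  day <- c(rep(0L, 8 * 60), rep(10L, 12 * 60), rep(0L, 4 * 60))
  rep(day, n_days)
}

# 5-minute epochs of 50 steps covering [08:00, 20:00) each day, with
# optional per-day omission (lost day) and an optional extra window where
# the tracker keeps counting 50/epoch
toy_tracker_epochs <- function(n_days = 3, skip_days = integer(0),
                               origin = origin0) {
  starts <- c()
  for (d in seq_len(n_days)) {
    if (d %in% skip_days) next
    day0 <- origin + (d - 1) * 86400
    starts <- c(starts, day0 + 3600 * 8 + 300 * (0:143))
  }
  tibble::tibble(
    epoch_start = as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
    epoch_minutes = 5, steps = 50L)
}

# Deterministic 3-participant toy study written to dir:
#  - reference: 10 steps/min 08:00-20:00, 72 h; p1 has a 90-minute zero run
#    10:00-11:30 on day 2 (device off, steps lost)
#  - trk: 5-min identity tracker; for p1 it keeps counting through the
#    reference's off period; for p2 day 2 is lost entirely
#  - trk2: identity tracker; for p3 the stream is empty (fully lost)
write_toy_study <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  zero_run <- origin0 + 86400 + 3600 * 10 # day 2, 10:00
  streams <- list()

  ref_steps <- toy_pattern_minutes()
  p1_ref <- ref_steps
  run_idx <- which(seq_along(ref_steps) - 1 >= (24 + 10) * 60 &
                     seq_along(ref_steps) - 1 < (24 + 11.5) * 60)
  p1_ref[run_idx] <- 0L
  streams[["p1_actigraph"]] <- minute_stream(p1_ref, "p1", "actigraph")
  streams[["p2_actigraph"]] <- minute_stream(ref_steps, "p2", "actigraph")
  streams[["p3_actigraph"]] <- minute_stream(ref_steps, "p3", "actigraph")

  streams[["p1_trk"]] <- step_stream("p1", "trk", toy_tracker_epochs())
  streams[["p2_trk"]] <- step_stream("p2", "trk",
                                     toy_tracker_epochs(skip_days = 2))
  streams[["p3_trk"]] <- step_stream("p3", "trk", toy_tracker_epochs())
  streams[["p1_trk2"]] <- step_stream("p1", "trk2", toy_tracker_epochs())
  streams[["p2_trk2"]] <- step_stream("p2", "trk2", toy_tracker_epochs())
  streams[["p3_trk2"]] <- step_stream("p3", "trk2",
                                      toy_tracker_epochs(skip_days = 1:3))

  rows <- list()
  for (key in names(streams)) {
    s <- streams[[key]]
    fn <- paste0(key, ".csv")
    df <- tibble::tibble(
      participant_id = rep(s$participant_id, nrow(s$epochs)),
      device_id = rep(s$device_id, nrow(s$epochs)),
      epoch_start_iso8601 = format(s$epochs$epoch_start,
                                   "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      epoch_minutes = s$epochs$epoch_minutes,
      steps = s$epochs$steps)
    readr::write_csv(df, file.path(dir, fn))
    rows[[key]] <- tibble::tibble(
      participant_id = s$participant_id, device_id = s$device_id,
      path = fn, is_reference = s$device_id == "actigraph")
  }
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(dplyr::bind_rows(rows), manifest_path)
  manifest_path
}
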