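test_that("written studies read back field-for-field", {
  models <- list(actigraph = device_error_model(),
                 hip = device_error_model(update_interval = 5,
                                          undercount_fraction = 0.1),
                 var = device_error_model(update_interval = "variable",
                                          mean_interval = 12))
  cfg <- study_config(n_participants = 2, device_models = models, seed = 42)
  st <- generate_study(cfg)
  d <- withr::local_tempdir()
  manifest_path <- write_study(st, d)
  loaded <- read_streams(manifest_path)
  expect_length(loaded$streams, 6L)
  for (key in names(st$streams)) {
    a <- st$streams[[key]]
    b <- loaded$streams[[key]]
    expect_identical(a$participant_id, b$participant_id)
    expect_identical(a$device_id, b$device_id)
    expect_equal(as.numeric(a$epochs$epoch_start),
                 as.numeric(b$epochs$epoch_start))
    expect_equal(a$epochs$epoch_minutes, b$epochs$epoch_minutes)
    expect_equal(as.integer(a$epochs$steps), as.integer(b$epochs$steps))
  }
})

test_that("a negative step count aborts with a row-numbered diagnostic", {
  d <- withr::local_tempdir()
  df <- tibble::tibble(
    participant_id = "p1", device_id = "dev",
    epoch_start_iso8601 = c("2024-06-03T00:00:00", "2024-06-03T00:01:00"),
    epoch_minutes = 1, steps = c(5, -3))
  readr::write_csv(df, file.path(d, "p1_dev.csv"))
  readr::write_csv(tibble::tibble(participant_id = "p1", device_id = "dev",
                                  path = "p1_dev.csv", is_reference = TRUE),
                   file.path(d, "manifest.csv"))
  expect_error(read_streams(file.path(d, "manifest.csv")),
               "negative step count at row 2.*p1")
})

test_that("empty step values are dropped and counted, not fatal", {
  d <- withr::local_tempdir()
  df <- tibble::tibble(
    participant_id = "p1", device_id = "dev",
    epoch_start_iso8601 = c("2024-06-03T00:00:00", "2024-06-03T00:01:00",
                            "2024-06-03T00:02:00"),
    epoch_minutes = 1, steps = c(5, NA, 7))
  readr::write_csv(df, file.path(d, "p1_dev.csv"))
  readr::write_csv(tibble::tibble(participant_id = "p1", device_id = "dev",
                                  path = "p1_dev.csv", is_reference = TRUE),
                   file.path(d, "manifest.csv"))
  loaded <- read_streams(file.path(d, "manifest.csv"))
  expect_identical(loaded$n_dropped_rows, 1L)
  expect_identical(total_steps(loaded$streams[[1]]), 12L)
})

test_that("an all-zero reference is one nonworn interval spanning the window", {
  s <- minute_stream(rep(0L, 72 * 60))
  mask <- detect_nonwear(s, 60)
  expect_identical(nrow(mask), 1L)
  expect_identical(mask$status, "nonworn")
  expect_equal(as.numeric(mask$end - mask$start, units = "mins"), 72 * 60)
})

test_that("zero runs are flagged if and only if they reach the threshold", {
  steps <- rep(5L, 24 * 60)
  steps[301:390] <- 0L # one 90-minute zero run
  s <- minute_stream(steps)
  m60 <- detect_nonwear(s, 60)
  nonworn <- m60[m60$status == "nonworn", ]
  expect_identical(nrow(nonworn), 1L)
  expect_equal(nonworn$start, origin0 + 300 * 60)
  expect_equal(nonworn$end, origin0 + 390 * 60)

  m120 <- detect_nonwear(s, 120)
  expect_identical(unique(m120$status), "worn")

  steps59 <- rep(5L, 24 * 60)
  steps59[301:359] <- 0L # 59 minutes: below threshold
  expect_identical(unique(detect_nonwear(minute_stream(steps59), 60)$status),
                   "worn")
})

test_that("nonwear detection matches a brute-force run-length scan", {
  for (seed in 1:8) {
    set.seed(seed)
    steps <- ifelse(runif(12 * 60) < 0.4, 0L,
                    as.integer(rpois(12 * 60, 20)))
    # implant a couple of long runs
    steps[100:180] <- 0L
    steps[400:470] <- 0L
    s <- minute_stream(steps)
    for (thr in c(30, 60, 75)) {
      mask <- detect_nonwear(s, thr)
      got <- rep(FALSE, length(steps))
      nw <- mask[mask$status == "nonworn", ]
      for (k in seq_len(nrow(nw))) {
        i0 <- as.numeric(nw$start[k] - origin0, units = "mins") + 1
        i1 <- as.numeric(nw$end[k] - origin0, units = "mins")
        got[i0:i1] <- TRUE
      }
      expect_identical(got, naive_nonwear_minutes(steps, thr),
                       label = sprintf("seed %d thr %d", seed, thr))
    }
  }
})

test_that("mask statuses alternate and tile the stream span", {
  set.seed(3)
  steps <- ifelse(runif(24 * 60) < 0.5, 0L, 3L)
  steps[50:160] <- 0L
  mask <- detect_nonwear(minute_stream(steps), 60)
  expect_true(all(mask$status[-1] != mask$status[-nrow(mask)]))
  expect_equal(as.numeric(mask$start[-1]), as.numeric(mask$end[-nrow(mask)]))
  expect_equal(as.numeric(mask$start[1]), as.numeric(origin0))
})

test_that("partial epoch overlap removes steps in proportion, by hand", {
  # one 5-minute epoch of 50 steps; nonworn covers its last 2 minutes:
  # round(50 * 3/5) = 30 retained over the worn 3 minutes
  s <- step_stream("p1", "trk",
                   tibble::tibble(epoch_start = origin0,
                                  epoch_minutes = 5, steps = 50L))
  mask <- wear_mask("p1", tibble::tibble(
    start = c(origin0, origin0 + 3 * 60),
    end = c(origin0 + 3 * 60, origin0 + 10 * 60),
    status = c("worn", "nonworn")))
  out <- mask_streams(s, mask)
  expect_identical(total_steps(out), 30L)
  expect_equal(out$epochs$epoch_minutes, 3)
  # mid-epoch nonwear splits the epoch into two worn pieces
  mask2 <- wear_mask("p1", tibble::tibble(
    start = c(origin0, origin0 + 60, origin0 + 3 * 60),
    end = c(origin0 + 60, origin0 + 3 * 60, origin0 + 10 * 60),
    status = c("worn", "nonworn", "worn")))
  out2 <- mask_streams(s, mask2)
  expect_identical(nrow(out2$epochs), 2L)
  expect_identical(sum(out2$epochs$steps), 10L + 20L)
})

test_that("masking with a fully-worn mask is the identity and never adds steps", {
  p <- activity_profile(daily_total_target = 7000)
  tr <- generate_ground_truth(p, 24, seed = 8)
  worn <- wear_mask("p01", tibble::tibble(
    start = origin0, end = origin0 + 86400, status = "worn"))
  expect_identical(mask_streams(tr, worn)$epochs, tr$epochs)
  for (seed in 1:5) {
    set.seed(seed)
    cut0 <- sample(0:800, 1)
    cut1 <- cut0 + sample(60:600, 1)
    mask <- wear_mask("p01", tibble::tibble(
      start = c(origin0, origin0 + cut0 * 60, origin0 + cut1 * 60),
      end = c(origin0 + cut0 * 60, origin0 + cut1 * 60, origin0 + 86400),
      status = c("worn", "nonworn", "worn")))
    masked <- mask_streams(tr, mask)
    expect_lte(total_steps(masked), total_steps(tr))
  }
})

test_that("mask for the wrong participant is an error", {
  s <- minute_stream(rep(1L, 60), participant = "p2")
  mask <- wear_mask("p1", tibble::tibble(
    start = origin0, end = origin0 + 3600, status = "worn"))
  expect_error(mask_streams(s, mask), "participant")
})

test_that("diary day-epochs are masked all-or-nothing", {
  diary <- step_stream("p1", "diary", tibble::tibble(
    epoch_start = origin0 + c(0, 1, 2) * 86400,
    epoch_minutes = 1440, steps = c(6000L, 7000L, 8000L)))
  # nonwear inside day 2 must not scale the diary count
  mask <- wear_mask("p1", tibble::tibble(
    start = c(origin0, origin0 + 86400 + 3600 * 10,
              origin0 + 86400 + 3600 * 12),
    end = c(origin0 + 86400 + 3600 * 10, origin0 + 86400 + 3600 * 12,
            origin0 + 3 * 86400),
    status = c("worn", "nonworn", "worn")))
  out <- mask_streams(diary, mask)
  expect_identical(as.integer(out$epochs$steps), c(6000L, 7000L, 8000L))
  # a fully nonworn day drops the diary epoch
  mask2 <- wear_mask("p1", tibble::tibble(
    start = c(origin0, origin0 + 86400, origin0 + 2 * 86400),
    end = c(origin0 + 86400, origin0 + 2 * 86400, origin0 + 3 * 86400),
    status = c("worn", "nonworn", "worn")))
  out2 <- mask_streams(diary, mask2)
  expect_identical(as.integer(out2$epochs$steps), c(6000L, 8000L))
})

test_that("aggregation matches hand sums and handles lost data", {
  # three hand-written streams over 6 hours at minute resolution
  ref_steps <- c(rep(10L, 120), rep(0L, 120), rep(20L, 120))
  ref <- minute_stream(ref_steps, "p1", "ref")
  trk <- step_stream("p1", "trk", tibble::tibble(
    epoch_start = origin0 + 300 * (0:71), epoch_minutes = 5,
    steps = rep(c(40L, 0L, 90L), each = 24)))
  streams <- list(p1_ref = ref, p1_trk = trk)
  agg <- aggregate_pairs(streams, "ref")
  expect_identical(nrow(agg$pairs), 1L)
  # hand sums: ref 120*10 + 120*20 = 3600; trk 24*40 + 24*90 = 3120
  expect_equal(agg$pairs$reference_steps, 3600)
  expect_equal(agg$pairs$tracker_steps, 3120)

  # epoch order is normalised, so shuffled input aggregates identically
  shuffled <- trk$epochs[sample(nrow(trk$epochs)), ]
  streams$p1_trk <- step_stream("p1", "trk", shuffled)
  agg2 <- aggregate_pairs(streams, "ref")
  expect_equal(agg2$pairs, agg$pairs)
})

test_that("a lost tracker day shrinks the pair; a fully lost tracker drops it", {
  ref <- minute_stream(toy_pattern_minutes(), "p1", "ref")
  lost_day <- step_stream("p1", "trk",
                          toy_tracker_epochs(skip_days = 2))
  gone <- step_stream("p1", "trk2", toy_tracker_epochs(skip_days = 1:3))
  agg <- aggregate_pairs(list(p1_ref = ref, p1_trk = lost_day,
                              p1_trk2 = gone), "ref")
  expect_identical(nrow(agg$pairs), 1L)
  # both totals over days 1 and 3 only: 2 * 7200 = 14400
  expect_equal(agg$pairs$reference_steps, 14400)
  expect_equal(agg$pairs$tracker_steps, 14400)
  expect_identical(agg$exclusions$device_id, "trk2")
  expect_match(agg$exclusions$reason, "no usable tracker time")
})

test_that("reference and tracker totals cover the same worn wall-clock set", {
  models <- list(ref = device_error_model(),
                 ident = device_error_model(), # 1-minute identity tracker
                 trk = device_error_model(update_interval = 5))
  cfg <- study_config(n_participants = 3, device_models = models,
                      reference_device = "ref", seed = 9)
  st <- generate_study(cfg)
  masked <- st$streams
  for (pid in c("p01", "p02", "p03")) {
    mask <- detect_nonwear(st$streams[[paste0(pid, "_ref")]], 60)
    keys <- paste0(pid, c("_ref", "_ident", "_trk"))
    masked[keys] <- mask_streams(st$streams[keys], mask)
  }
  agg <- aggregate_pairs(masked, "ref")
  expect_identical(nrow(agg$pairs), 6L)
  # at matching (1-minute) resolution the shared worn set makes the
  # identity pair exact
  ident <- agg$pairs[agg$pairs$device_id == "ident", ]
  expect_equal(ident$reference_steps, ident$tracker_steps)
  # coarser epochs straddling worn/nonworn boundaries are apportioned
  # proportionally with rounding, so identity holds to a few steps
  trk <- agg$pairs[agg$pairs$device_id == "trk", ]
  expect_true(all(abs(trk$reference_steps - trk$tracker_steps) <= 10))
})
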