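# trajectory behavior: resampling, freezing, ambulation, rotations, epochs

test_that("resampling yields 150 positions per minute from a 5 Hz track", {
  st <- generate_track(track_synth_params(duration = 60, seed = 1))
  expect_identical(nrow(resample_track(st$track)$data), 150L)
  st2 <- generate_track(track_synth_params(duration = 120, seed = 1))
  expect_identical(nrow(resample_track(st2$track)$data), 300L)
  expect_error(resample_track(keypoint_track(
    data.frame(t = numeric(0), center_x = numeric(0), center_y = numeric(0)),
    5)), "empty")
})

test_that("resampling preserves the timestamps of the selected frames", {
  st <- generate_track(track_synth_params(duration = 10, seed = 2))
  rs <- resample_track(st$track)
  expect_equal(rs$data$t, st$track$data$t[seq(1, 50, by = 2)])
  expect_equal(rs$frame_rate, 2.5)
})

test_that("a perfectly static track is one full-length bout", {
  t <- seq(0, 59.6, by = 0.4)
  d <- data.frame(t = t, nose_x = 5, nose_y = 5, center_x = 4, center_y = 5,
                  forepaws_x = 4.5, forepaws_y = 5, hindpaws_x = 3.5,
                  hindpaws_y = 5)
  det <- detect_freezing(keypoint_track(d, 2.5))
  expect_identical(nrow(det$bouts), 1L)
  expect_equal(det$freezing_time, 59.6)
})

test_that("constant-velocity motion above tolerance yields zero bouts", {
  t <- seq(0, 59.6, by = 0.4)
  d <- data.frame(t = t, nose_x = 5 * t, nose_y = 5, center_x = 5 * t - 1,
                  center_y = 5, forepaws_x = 5 * t - 0.5, forepaws_y = 5,
                  hindpaws_x = 5 * t - 1.5, hindpaws_y = 5)
  det <- detect_freezing(keypoint_track(d, 2.5))
  expect_identical(nrow(det$bouts), 0L)
  expect_equal(det$freezing_time, 0)
})

test_that("detector recovers generator bouts up to the analysis resolution", {
  for (s in 1:10) {
    st <- generate_track(track_synth_params(duration = 120,
                                            freeze_fraction = 0.4, seed = s))
    rs <- resample_track(st$track)
    det <- detect_freezing(rs)
    # displacement steps only span up to the last sample, so the detectable
    # window ends one analysis step before the nominal duration
    t_cover <- max(rs$data$t)
    truth <- st$freeze_intervals
    truth$t_end <- pmin(truth$t_end, t_cover)
    truth <- truth[truth$t_end - truth$t_start >= 1.2 - 1e-9, , drop = FALSE]
    expect_identical(nrow(det$bouts), nrow(truth))
    if (nrow(truth)) {
      expect_true(all(abs(det$bouts$t_start - truth$t_start) <= 0.4 + 1e-9))
      expect_true(all(abs(det$bouts$t_end - truth$t_end) <= 0.4 + 1e-9))
    }
  }
})

test_that("detector equals the brute-force window scan on random tracks", {
  for (s in 1:20) {
    st <- generate_track(track_synth_params(duration = 60,
                                            freeze_fraction = 0.5,
                                            mean_freeze_bout = 2, seed = s))
    rs <- resample_track(st$track)
    det <- detect_freezing(rs)
    bf <- brute_force_freezing(rs)
    expect_equal(det$bouts$t_start, bf$bouts$t_start)
    expect_equal(det$bouts$t_end, bf$bouts$t_end)
    expect_equal(det$freezing_time, bf$freezing_time)
    expect_identical(det$static, bf$static)
  }
})

test_that("steps with missing required keypoints never count as static", {
  t <- seq(0, 9.6, by = 0.4)
  d <- data.frame(t = t, nose_x = 5, nose_y = 5, center_x = 4, center_y = 5,
                  forepaws_x = 4.5, forepaws_y = 5, hindpaws_x = 3.5,
                  hindpaws_y = 5)
  d$center_x[13] <- NA  # breaks steps 12 and 13
  det <- detect_freezing(keypoint_track(d, 2.5))
  expect_identical(nrow(det$bouts), 2L)
  d_all_na <- d
  d_all_na[, -1] <- NA
  expect_error(detect_freezing(keypoint_track(d_all_na, 2.5)), "usable")
})

test_that("ambulation metrics match closed forms", {
  t <- seq(0, 59.6, by = 0.4)
  d <- data.frame(t = t, center_x = 10 * t, center_y = 5)
  am <- ambulation_metrics(keypoint_track(d, 2.5, arena_size = c(1000, 10)))
  expect_equal(am$distance, 10 * 59.6)
  expect_equal(am$activity_pct, 100)
  dstat <- data.frame(t = t, center_x = 5, center_y = 5)
  am0 <- ambulation_metrics(keypoint_track(dstat, 2.5))
  expect_equal(am0$distance, 0)
  expect_equal(am0$ambulation_time, 0)
  expect_equal(am0$activity_pct, 0)
})

test_that("ambulation time tracks the generator's ambulate dwell total", {
  # large arena so wall reflections (which can fold a step onto itself and
  # drop its apparent speed) play no role
  for (s in 1:5) {
    st <- generate_track(track_synth_params(duration = 120,
                                            freeze_fraction = 0.4,
                                            arena_size = c(400, 400),
                                            seed = s))
    rs <- resample_track(st$track)
    am <- ambulation_metrics(rs)
    n_steps <- nrow(rs$data) - 1L
    truth <- sum(st$state[seq_len(2L * n_steps)] == "ambulate") * 0.2
    expect_lt(abs(am$ambulation_time - truth), 0.4 + 1e-9)
  }
})

test_that("rotation counts match closed forms for steady spinning", {
  tr <- spin_track(90)                      # ccw, 90 deg/s for 60 s
  expect_identical(count_rotations(tr, "full")$ccw, 15L)
  expect_identical(count_rotations(tr, "full")$cw, 0L)
  expect_identical(count_rotations(tr, "quarter")$ccw, 60L)
  trcw <- spin_track(-90)
  expect_identical(count_rotations(trcw, "full")$cw, 15L)
  expect_identical(count_rotations(trcw, "quarter")$cw, 60L)
})

test_that("rotation counting equals the brute-force crossing count", {
  for (s in 1:10) {
    st <- generate_track(track_synth_params(duration = 60, freeze_fraction = 0.2,
                                            turn_sd = 0.6, seed = s))
    rs <- resample_track(st$track)
    for (mode in c("quarter", "full")) {
      got <- count_rotations(rs, mode)
      bf <- brute_force_rotations(rs, mode)
      expect_identical(got$cw, bf$cw)
      expect_identical(got$ccw, bf$ccw)
    }
  }
})

test_that("net contralateral rotations respect the lesion side", {
  expect_equal(net_contralateral(10, 3, "left"), 7)
  expect_equal(net_contralateral(10, 3, "right"), -7)
})

test_that("percent change from baseline is plain arithmetic with a guarded zero", {
  expect_equal(percent_change_rotations(100, 53), -47)
  expect_equal(percent_change_rotations(100, 100), 0)
  expect_error(percent_change_rotations(0, 10), "positive")
  pre <- c(120, 80, 100); during <- c(60, 60, 90)
  expect_equal(mean(percent_change_rotations(pre, during)),
               mean(100 * (during - pre) / pre))
})

test_that("epoch segmentation partitions samples and respects bounds", {
  st <- generate_track(track_synth_params(duration = 90, seed = 4))
  ep <- epoch_set(c("pre", "dmf", "post"), c(0, 30, 60), c(30, 60, 90))
  parts <- segment_epochs(st$track, ep)
  expect_identical(sum(vapply(parts, function(p) nrow(p$data), integer(1))),
                   nrow(st$track$data))
  # brute-force membership per sample
  t <- st$track$data$t
  for (i in 1:3) {
    expect_identical(nrow(parts[[i]]$data),
                     sum(t >= ep$start[i] & t < ep$end[i]))
  }
  expect_identical(length(segment_epochs(st$track, ep[0, ])), 0L)
  expect_error(segment_epochs(st$track, epoch_set("x", 80, 120)), "span")
  expect_error(epoch_set(c("a", "b"), c(0, 10), c(15, 20)), "overlap")
})

test_that("freezing plus ambulation never exceeds the epoch duration", {
  st <- generate_track(track_synth_params(duration = 300,
                                          freeze_fraction = 0.4, seed = 6))
  ep <- epoch_set(c("a", "b"), c(0, 150), c(150, 300))
  bs <- behavior_summary(st$track, ep)
  expect_true(all(bs$freezing_time + bs$ambulation_time <= 150 + 1e-9))
  expect_true(all(bs$activity_pct >= 0 & bs$activity_pct <= 100))
})

test_that("behavior metrics are isometry invariant; reflection swaps rotations", {
  st <- generate_track(track_synth_params(duration = 60, freeze_fraction = 0.3,
                                          seed = 8))
  rs <- resample_track(st$track)
  moved <- transform_track(rs, angle = 1.1, shift = c(40, -15))
  expect_equal(detect_freezing(moved)$freezing_time,
               detect_freezing(rs)$freezing_time)
  expect_equal(ambulation_metrics(moved)$distance,
               ambulation_metrics(rs)$distance)
  expect_equal(ambulation_metrics(moved)$activity_pct,
               ambulation_metrics(rs)$activity_pct)
  mirrored <- transform_track(rs, reflect = TRUE)
  rot <- count_rotations(rs, "quarter")
  rot_m <- count_rotations(mirrored, "quarter")
  expect_identical(rot$cw, rot_m$ccw)
  expect_identical(rot$ccw, rot_m$cw)
})

test_that("track CSV and EthoVision-dialect readers round-trip coordinates", {
  st <- generate_track(track_synth_params(duration = 10, dropout_rate = 0.01,
                                          seed = 5))
  path <- tempfile(fileext = ".csv")
  write_track_csv(st$track, path)
  back <- read_track_csv(path)
  expect_equal(back$data, st$track$data, tolerance = 1e-12)
  # EthoVision-like export: metadata preamble + semicolon separation
  epath <- tempfile(fileext = ".txt")
  hdr <- names(st$track$data)
  rows <- apply(st$track$data, 1, function(r) {
    paste(ifelse(is.na(r), "-", format(r, digits = 10)), collapse = ";")
  })
  writeLines(c("Number of header lines: 3", "Tracking source;video.avi",
               paste(hdr, collapse = ";"), rows), epath)
  etr <- read_ethovision_track(epath)
  expect_equal(etr$data$center_x, st$track$data$center_x, tolerance = 1e-6)
  unlink(c(path, epath))
})
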