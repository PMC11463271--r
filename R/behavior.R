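#' Freezing-detector parameters
#'
#' Freezing of gait is a continuous period of at least `min_duration` seconds
#' with no change of spatial position of the head, center, or extremities.
#' "No change" is operationalised with a per-step displacement tolerance
#' `epsilon` (cm), since real tracking carries jitter.
#'
#' @param min_duration minimum bout span, seconds
#' @param epsilon maximum per-step displacement (cm) for a keypoint to count
#'   as static
#' @param keypoints_required keypoints that must all be static for a step to
#'   be static
#' @return list of class `freeze_params`
#' @export
freeze_params <- function(min_duration = 1.0, epsilon = 0.5,
                          keypoints_required = c("nose", "center",
                                                 "forepaws", "hindpaws")) {
  assert_scalar_num(min_duration, "min_duration", lower = 0, strict_lower = TRUE)
  assert_scalar_num(epsilon, "epsilon", lower = 0)
  structure(list(min_duration = min_duration, epsilon = epsilon,
                 keypoints_required = keypoints_required),
            class = "freeze_params")
}

#' Resample a track to the analysis rate
#'
#' The tracker convention divides each second into five frames and scores
#' every second frame, i.e. 150 positions per minute per keypoint (2.5 Hz
#' effective). This takes every second sample of the input grid, preserving
#' the timestamps of the selected frames.
#'
#' @param track a `keypoint_track` sampled at >= 5 Hz (or already resampled)
#' @param every keep every `every`-th frame (default 2)
#' @return a `keypoint_track` at `frame_rate / every`
#' @examples
#' st <- generate_track(track_synth_params(duration = 60, seed = 1))
#' nrow(resample_track(st$track)$data)  # 150 samples for one minute
#' @export
resample_track <- function(track, every = 2L) {
  stopifnot(inherits(track, "keypoint_track"))
  n <- nrow(track$data)
  if (n == 0L) stop("empty track", call. = FALSE)
  dt <- diff(track$data$t)
  if (length(dt) && (max(dt) - min(dt)) > 0.25 / track$frame_rate) {
    stop("track time grid is not uniform", call. = FALSE)
  }
  sel <- seq(1L, n, by = as.integer(every))
  keypoint_track(track$data[sel, , drop = FALSE],
                 track$frame_rate / every, track$arena_size)
}

# per-step displacement matrix (steps x keypoints); NA where either end missing
step_displacements <- function(track, keypoints) {
  n <- nrow(track$data)
  disp <- matrix(NA_real_, n - 1L, length(keypoints),
                 dimnames = list(NULL, keypoints))
  for (j in seq_along(keypoints)) {
    xy <- kp_xy(track, keypoints[j])
    disp[, j] <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  }
  disp
}

#' Detect freezing-of-gait bouts
#'
#' A sample step is static iff every required keypoint moved at most
#' `epsilon` cm between consecutive samples; steps with any missing required
#' keypoint are treated as non-static (conservative gap policy). Maximal runs
#' of static steps spanning at least `min_duration` seconds are bouts; a
#' run of `k` static steps starting at sample time `t1` is the half-open
#' interval `[t1, t1 + k * dt)`.
#'
#' @param track a resampled `keypoint_track`
#' @param params a [freeze_params()]
#' @return list with `bouts` (data.frame `t_start`, `t_end`, `duration`),
#'   `freezing_time` (total seconds), and `static` (per-step logical)
#' @export
detect_freezing <- function(track, params = freeze_params()) {
  stopifnot(inherits(track, "keypoint_track"))
  kps <- intersect(params$keypoints_required, track_keypoints(track))
  if (length(kps) == 0L) stop("none of the required keypoints present",
                              call. = FALSE)
  n <- nrow(track$data)
  if (n < 2L) {
    return(list(bouts = data.frame(t_start = numeric(0), t_end = numeric(0),
                                   duration = numeric(0)),
                freezing_time = 0, static = logical(0)))
  }
  disp <- step_displacements(track, kps)
  if (all(is.na(disp))) stop("track has no usable (non-missing) steps",
                             call. = FALSE)
  ok <- !is.na(disp) & disp <= params$epsilon
  static <- rowSums(ok) == length(kps)   # NA counts as non-static
  dt <- 1 / track$frame_rate
  r <- rle(static)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * dt >= params$min_duration - 1e-9)
  t <- track$data$t
  bouts <- data.frame(
    t_start = t[starts[keep]],
    t_end = t[starts[keep]] + r$lengths[keep] * dt
  )
  bouts$duration <- bouts$t_end - bouts$t_start
  list(bouts = bouts, freezing_time = sum(bouts$duration), static = static)
}

#' Ambulation metrics from the center keypoint
#'
#' Distance is the summed center displacement; a step is active iff the
#' center speed exceeds `speed_threshold`. Steps with a missing center are
#' excluded from both numerator and denominator of the activity percentage.
#'
#' @param track a resampled `keypoint_track` containing a `center` keypoint
#' @param speed_threshold cm/s above which a step counts as ambulation
#' @return list with `distance` (cm), `ambulation_time` (s), `activity_pct`
#'   (percent of valid time active), `n_missing_steps`, and per-bout
#'   `ambulation_bouts` (data.frame of maximal active runs)
#' @export
ambulation_metrics <- function(track, speed_threshold = 2) {
  stopifnot(inherits(track, "keypoint_track"))
  if (!"center" %in% track_keypoints(track)) {
    stop("track has no center keypoint", call. = FALSE)
  }
  n <- nrow(track$data)
  dt <- 1 / track$frame_rate
  if (n < 2L) {
    return(list(distance = 0, ambulation_time = 0, activity_pct = 0,
                n_missing_steps = 0L,
                ambulation_bouts = data.frame(t_start = numeric(0),
                                              t_end = numeric(0),
                                              duration = numeric(0))))
  }
  xy <- kp_xy(track, "center")
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  missing <- is.na(d)
  if (mean(missing) > 0.2) {
    warning(sprintf("%.0f%% of center steps missing", 100 * mean(missing)))
  }
  active <- !missing & (d / dt > speed_threshold)
  r <- rle(as.vector(active))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values
  t <- track$data$t
  bouts <- data.frame(t_start = t[starts[keep]],
                      t_end = t[starts[keep]] + r$lengths[keep] * dt)
  bouts$duration <- bouts$t_end - bouts$t_start
  n_valid <- sum(!missing)
  list(
    distance = sum(d[!missing]),
    ambulation_time = sum(active) * dt,
    activity_pct = if (n_valid) 100 * sum(active) / n_valid else 0,
    n_missing_steps = sum(missing),
    ambulation_bouts = bouts
  )
}

#' Count rotations from the center-to-nose heading
#'
#' The heading is the angle of the center-to-nose vector. Signed heading
#' increments are accumulated; each time the cumulative rotation since the
#' last count crosses the mode threshold (90 degrees in `"quarter"` mode,
#' 360 in `"full"` mode) a rotation is counted in that direction and the
#' threshold is subtracted, so continuous spinning yields the closed-form
#' count. Counterclockwise is the direction of increasing angle in a
#' right-handed x/y frame.
#'
#' @param track a `keypoint_track` with nose and center keypoints
#' @param mode `"quarter"` (>90 degree turns, open-field convention) or
#'   `"full"` (360 degree rotations, rotometer convention)
#' @return list with `cw`, `ccw` counts and `net` (`ccw - cw`)
#' @examples
#' # a track spinning counterclockwise at 90 deg/s for 60 s
#' t <- seq(0, 60, by = 0.4); th <- pi / 2 * t
#' d <- data.frame(t = t, center_x = 10, center_y = 10,
#'                 nose_x = 10 + 3 * cos(th), nose_y = 10 + 3 * sin(th))
#' count_rotations(keypoint_track(d, 2.5), mode = "full")$ccw  # 15
#' @export
count_rotations <- function(track, mode = c("quarter", "full")) {
  stopifnot(inherits(track, "keypoint_track"))
  mode <- match.arg(mode)
  kps <- track_keypoints(track)
  if (!all(c("nose", "center") %in% kps)) {
    stop("nose and center keypoints required", call. = FALSE)
  }
  nose <- kp_xy(track, "nose"); ctr <- kp_xy(track, "center")
  v <- nose - ctr
  len <- sqrt(rowSums(v^2))
  degen <- !is.na(len) & len < 1e-9
  if (any(degen)) warning(sprintf("%d degenerate center-to-nose vectors skipped",
                                  sum(degen)))
  ok <- !is.na(len) & !degen
  th <- atan2(v[ok, 2], v[ok, 1])
  if (length(th) < 2L) return(list(cw = 0L, ccw = 0L, net = 0L))
  inc <- wrap_angle(diff(th))
  threshold <- if (mode == "quarter") pi / 2 else 2 * pi
  cw <- 0L; ccw <- 0L; acc <- 0
  tol <- 1e-9   # absorb float accumulation at exact-multiple crossings
  for (a in inc) {
    acc <- acc + a
    while (acc >= threshold - tol) { ccw <- ccw + 1L; acc <- acc - threshold }
    while (acc <= -threshold + tol) { cw <- cw + 1L; acc <- acc + threshold }
  }
  list(cw = cw, ccw = ccw, net = ccw - cw)
}

#' Net contralateral rotations given a lesion side
#'
#' In unilateral lesion models the drug-induced bias is toward the side
#' opposite the lesion: a left-hemisphere lesion yields rightward (clockwise,
#' viewed from above in a right-handed frame) contralateral rotations.
#'
#' @param cw,ccw rotation counts from [count_rotations()]
#' @param lesion_side `"left"` or `"right"`
#' @return `contralateral - ipsilateral` count
#' @export
net_contralateral <- function(cw, ccw, lesion_side = c("left", "right")) {
  lesion_side <- match.arg(lesion_side)
  if (lesion_side == "left") cw - ccw else ccw - cw
}

#' Percent change in rotations from a pre-treatment baseline
#'
#' @param pre baseline count(s); must be positive
#' @param during count(s) during treatment
#' @return `100 * (during - pre) / pre`, vectorized
#' @examples
#' percent_change_rotations(100, 53)  # -47
#' @export
percent_change_rotations <- function(pre, during) {
  if (any(!is.finite(pre)) || any(pre <= 0)) {
    stop("baseline (`pre`) counts must be positive: percent change undefined",
         call. = FALSE)
  }
  100 * (during - pre) / pre
}

#' Change-of-location series
#'
#' Spatial motion along the arena's y axis (toward the magnet) as a function
#' of time, from the center keypoint.
#'
#' @param track a `keypoint_track`
#' @return data.frame with columns `t` and `y`
#' @export
change_of_location <- function(track) {
  stopifnot(inherits(track, "keypoint_track"))
  data.frame(t = track$data$t, y = track$data$center_y)
}

#' Per-epoch behavior summary
#'
#' Resamples the track to the analysis rate, slices it by epoch, and reports
#' the full behavior panel per epoch: freezing time, ambulation time,
#' distance, activity percentage, and rotation counts.
#'
#' @param track a `keypoint_track` at the native (e.g. 5 Hz) rate
#' @param epochs an [epoch_set()]
#' @param fparams a [freeze_params()]
#' @param speed_threshold ambulation speed threshold, cm/s
#' @param rotation_mode passed to [count_rotations()]
#' @return data.frame, one row per epoch, with columns `label`,
#'   `freezing_time`, `ambulation_time`, `distance`, `activity_pct`,
#'   `rotations_cw`, `rotations_ccw`, `n_freeze_bouts`, `mean_bout`
#' @export
behavior_summary <- function(track, epochs, fparams = freeze_params(),
                             speed_threshold = 2,
                             rotation_mode = "quarter") {
  rs <- resample_track(track)
  slices <- segment_epochs(rs, epochs)
  rows <- lapply(names(slices), function(lab) {
    s <- slices[[lab]]
    fz <- detect_freezing(s, fparams)
    am <- ambulation_metrics(s, speed_threshold)
    rot <- count_rotations(s, rotation_mode)
    data.frame(
      label = lab,
      freezing_time = fz$freezing_time,
      ambulation_time = am$ambulation_time,
      distance = am$distance,
      activity_pct = am$activity_pct,
      rotations_cw = rot$cw,
      rotations_ccw = rot$ccw,
      n_freeze_bouts = nrow(fz$bouts),
      mean_bout = if (nrow(fz$bouts)) mean(fz$bouts$duration) else 0,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
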