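# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive per-sample loops, not the package's code paths.

# Freezing by exhaustive scan: evaluate the static predicate per step with an
# explicit keypoint loop, then find maximal qualifying windows by scanning
# every start index.
brute_force_freezing <- function(track, params = freeze_params()) {
  d <- track$data
  t <- d$t
  n <- nrow(d)
  dt <- 1 / track$frame_rate
  kps <- intersect(params$keypoints_required,
                   magnetoquant::track_keypoints(track))
  static <- rep(TRUE, n - 1L)
  for (i in seq_len(n - 1L)) {
    for (kp in kps) {
      dx <- d[[paste0(kp, "_x")]][i + 1L] - d[[paste0(kp, "_x")]][i]
      dy <- d[[paste0(kp, "_y")]][i + 1L] - d[[paste0(kp, "_y")]][i]
      disp <- sqrt(dx^2 + dy^2)
      if (is.na(disp) || disp > params$epsilon) static[i] <- FALSE
    }
  }
  bouts <- data.frame(t_start = numeric(0), t_end = numeric(0))
  i <- 1L
  while (i <= length(static)) {
    if (static[i]) {
      j <- i
      while (j < length(static) && static[j + 1L]) j <- j + 1L
      if ((j - i + 1L) * dt >= params$min_duration - 1e-9) {
        bouts <- rbind(bouts,
                       data.frame(t_start = t[i],
                                  t_end = t[i] + (j - i + 1L) * dt))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  bouts$duration <- if (nrow(bouts)) bouts$t_end - bouts$t_start else numeric(0)
  list(bouts = bouts, freezing_time = sum(bouts$duration), static = static)
}

# Rotation counting by per-increment subdivision of the unwrapped heading.
brute_force_rotations <- function(track, mode) {
  d <- track$data
  v <- cbind(d$nose_x - d$center_x, d$nose_y - d$center_y)
  len <- sqrt(rowSums(v^2))
  ok <- !is.na(len) & len >= 1e-9
  th <- atan2(v[ok, 2], v[ok, 1])
  thr <- if (mode == "quarter") pi / 2 else 2 * pi
  cw <- 0L; ccw <- 0L; acc <- 0
  for (i in seq_along(th)[-1]) {
    a <- th[i] - th[i - 1]
    a <- ((a + pi) %% (2 * pi)) - pi
    acc <- acc + a
    while (acc >= thr) { ccw <- ccw + 1L; acc <- acc - thr }
    while (acc <= -thr) { cw <- cw + 1L; acc <- acc + thr }
  }
  list(cw = cw, ccw = ccw)
}

# Closed-form Welch statistic from the textbook formulas.
closed_form_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Closed-form Pearson r and its t-transform p value.
closed_form_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}

# A spinning-in-place track: constant center, heading advancing at
# `rate_deg` degrees per second, sampled at `fs` Hz for `duration` seconds.
spin_track <- function(rate_deg, duration = 60, fs = 2.5) {
  t <- seq(0, duration, by = 1 / fs)
  th <- rate_deg * pi / 180 * t
  magnetoquant::keypoint_track(
    data.frame(t = t, center_x = 10, center_y = 10,
               nose_x = 10 + 3 * cos(th), nose_y = 10 + 3 * sin(th)),
    frame_rate = fs
  )
}

# Apply an isometry (rotation by `angle` then translation) to every keypoint.
transform_track <- function(track, angle = 0, shift = c(0, 0), reflect = FALSE) {
  d <- track$data
  for (kp in magnetoquant::track_keypoints(track)) {
    x <- d[[paste0(kp, "_x")]]; y <- d[[paste0(kp, "_y")]]
    if (reflect) x <- -x
    xr <- x * cos(angle) - y * sin(angle) + shift[1]
    yr <- x * sin(angle) + y * cos(angle) + shift[2]
    d[[paste0(kp, "_x")]] <- xr; d[[paste0(kp, "_y")]] <- yr
  }
  magnetoquant::keypoint_track(d, track$frame_rate, track$arena_size * 10)
}
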