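#' Parameters for the synthetic locomotion generator
#'
#' The generator realises a two-state (ambulate / freeze) semi-Markov process
#' with exponential dwell times. During ambulation the body center follows a
#' correlated random walk at `mean_ambulation_speed` with wall reflection;
#' during freezing all keypoints are static up to tracking jitter. Keypoints
#' are rigid body-frame offsets from the center rotated by the heading, which
#' makes rotation metrics recoverable from the same process. State switches
#' are aligned to the 2.5 Hz analysis grid (two native frames) so that
#' ground-truth bouts are exactly representable at the analysis resolution.
#'
#' @param duration recording length, seconds
#' @param frame_rate native sampling rate, Hz (tracker convention: 5)
#' @param arena_size arena width x depth, cm
#' @param freeze_fraction long-run fraction of time frozen, in `[0, 1]`
#' @param mean_freeze_bout mean freezing bout length, seconds
#' @param mean_ambulation_speed mean center speed while ambulating, cm/s
#' @param keypoint_offsets named list of body-frame `(x, y)` displacements
#'   from the center, cm; x is along the heading
#' @param jitter_sd per-frame, per-coordinate tracking noise SD, cm
#' @param turn_sd per-frame SD of the heading increment, radians
#' @param dropout_rate per-keypoint, per-frame probability of starting a
#'   missing-data run (tracker dropout)
#' @param dropout_mean_frames mean length of a dropout run, frames
#' @param seed integer seed
#' @return a list of class `track_synth_params`
#' @export
track_synth_params <- function(duration = 300,
                               frame_rate = 5,
                               arena_size = c(26.5, 26.5),
                               freeze_fraction = 0.3,
                               mean_freeze_bout = 4,
                               mean_ambulation_speed = 8,
                               keypoint_offsets = list(
                                 nose = c(3, 0), center = c(0, 0),
                                 forepaws = c(1.5, 0), hindpaws = c(-1.5, 0),
                                 tail = c(-4, 0)
                               ),
                               jitter_sd = 0.05,
                               turn_sd = 0.25,
                               dropout_rate = 0,
                               dropout_mean_frames = 3,
                               seed = 1L) {
  assert_scalar_num(duration, "duration", lower = 0, strict_lower = TRUE)
  assert_scalar_num(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  assert_proportion(freeze_fraction, "freeze_fraction")
  assert_scalar_num(mean_freeze_bout, "mean_freeze_bout", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(mean_ambulation_speed, "mean_ambulation_speed", lower = 0)
  assert_scalar_num(jitter_sd, "jitter_sd", lower = 0)
  assert_proportion(dropout_rate, "dropout_rate")
  structure(
    list(duration = duration, frame_rate = frame_rate,
         arena_size = as.numeric(arena_size),
         freeze_fraction = freeze_fraction,
         mean_freeze_bout = mean_freeze_bout,
         mean_ambulation_speed = mean_ambulation_speed,
         keypoint_offsets = keypoint_offsets,
         jitter_sd = jitter_sd, turn_sd = turn_sd,
         dropout_rate = dropout_rate,
         dropout_mean_frames = dropout_mean_frames,
         seed = as.integer(seed)),
    class = "track_synth_params"
  )
}

# Sample the quantum-aligned state sequence for an alternating-renewal
# process. Returns integer vector over quanta: 1 = ambulate, 2 = freeze.
sample_state_quanta <- function(n_quanta, q_dt, freeze_fraction,
                                mean_freeze_bout) {
  if (freeze_fraction <= 0) return(rep(1L, n_quanta))
  if (freeze_fraction >= 1) return(rep(2L, n_quanta))
  mean_amb <- mean_freeze_bout * (1 - freeze_fraction) / freeze_fraction
  state <- integer(0)
  cur <- if (stats::runif(1) < freeze_fraction) 2L else 1L
  while (length(state) < n_quanta) {
    m <- if (cur == 2L) mean_freeze_bout else mean_amb
    k <- max(1L, as.integer(round(stats::rexp(1, 1 / m) / q_dt)))
    state <- c(state, rep(cur, k))
    cur <- 3L - cur
  }
  state[seq_len(n_quanta)]
}

# Shared trajectory core: given a per-quantum state sequence, walk the
# center/heading and assemble the keypoint table.
build_track_from_states <- function(p, state_q) {
  fr <- p$frame_rate
  n_frames <- length(state_q) * 2L
  state_f <- rep(state_q, each = 2L)
  t <- (seq_len(n_frames) - 1L) / fr
  w <- p$arena_size[1]; h <- p$arena_size[2]
  margin <- 1
  x <- numeric(n_frames); y <- numeric(n_frames); th <- numeric(n_frames)
  x[1] <- stats::runif(1, w * 0.25, w * 0.75)
  y[1] <- stats::runif(1, h * 0.25, h * 0.75)
  th[1] <- stats::runif(1, -pi, pi)
  step <- p$mean_ambulation_speed / fr
  turns <- stats::rnorm(n_frames, 0, p$turn_sd)
  for (i in seq_len(n_frames - 1L)) {
    if (state_f[i] == 1L) {
      th[i + 1] <- th[i] + turns[i]
      nx <- x[i] + step * cos(th[i + 1])
      ny <- y[i] + step * sin(th[i + 1])
      # reflect off walls, flipping the relevant heading component
      if (nx < margin) { nx <- 2 * margin - nx; th[i + 1] <- pi - th[i + 1] }
      if (nx > w - margin) { nx <- 2 * (w - margin) - nx; th[i + 1] <- pi - th[i + 1] }
      if (ny < margin) { ny <- 2 * margin - ny; th[i + 1] <- -th[i + 1] }
      if (ny > h - margin) { ny <- 2 * (h - margin) - ny; th[i + 1] <- -th[i + 1] }
      x[i + 1] <- nx; y[i + 1] <- ny
    } else {
      x[i + 1] <- x[i]; y[i + 1] <- y[i]; th[i + 1] <- th[i]
    }
  }
  kps <- names(p$keypoint_offsets)
  d <- data.frame(t = t)
  for (kp in kps) {
    off <- p$keypoint_offsets[[kp]]
    kx <- x + off[1] * cos(th) - off[2] * sin(th)
    ky <- y + off[1] * sin(th) + off[2] * cos(th)
    if (p$jitter_sd > 0) {
      kx <- kx + stats::rnorm(n_frames, 0, p$jitter_sd)
      ky <- ky + stats::rnorm(n_frames, 0, p$jitter_sd)
    }
    if (p$dropout_rate > 0) {
      drop <- rep(FALSE, n_frames)
      starts <- which(stats::runif(n_frames) < p$dropout_rate)
      for (s in starts) {
        len <- 1L + stats::rgeom(1, 1 / p$dropout_mean_frames)
        drop[s:min(n_frames, s + len - 1L)] <- TRUE
      }
      kx[drop] <- NA_real_; ky[drop] <- NA_real_
    }
    d[[paste0(kp, "_x")]] <- kx
    d[[paste0(kp, "_y")]] <- ky
  }
  list(data = d, t = t, state_f = state_f)
}

# runs of state 2 (freeze) over quanta -> interval data.frame in seconds
states_to_intervals <- function(state_q, q_dt) {
  r <- rle(state_q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  sel <- r$values == 2L
  data.frame(t_start = starts[sel] * q_dt, t_end = ends[sel] * q_dt)
}

#' Generate a synthetic keypoint track with known freezing ground truth
#'
#' @param params a [track_synth_params()]
#' @return list of class `synthetic_track` with elements `track`
#'   (a [keypoint_track()]), `freeze_intervals` (data.frame `t_start`,
#'   `t_end`, seconds, tiling the freeze state), `state` (per-frame
#'   `"ambulate"`/`"freeze"`), and `params`.
#' @examples
#' st <- generate_track(track_synth_params(duration = 60, seed = 7))
#' sum(st$freeze_intervals$t_end - st$freeze_intervals$t_start) / 60
#' @export
generate_track <- function(params) {
  stopifnot(inherits(params, "track_synth_params"))
  p <- params
  with_seed(p$seed, {
    q_dt <- 2 / p$frame_rate
    n_quanta <- max(1L, as.integer(round(p$duration / q_dt)))
    state_q <- sample_state_quanta(n_quanta, q_dt, p$freeze_fraction,
                                   p$mean_freeze_bout)
    core <- build_track_from_states(p, state_q)
    structure(
      list(
        track = keypoint_track(core$data, p$frame_rate, p$arena_size),
        freeze_intervals = states_to_intervals(state_q, q_dt),
        state = c("ambulate", "freeze")[core$state_f],
        params = p
      ),
      class = "synthetic_track"
    )
  })
}

#' Generate a track whose freezing hazard is gated by local field strength
#'
#' Identical locomotion model to [generate_track()], except that freezing can
#' only start while the animal's center sits where the magnetic field meets
#' or exceeds `threshold_mT`; below the threshold the animal always
#' ambulates. Used to test recovery of a behavioral field threshold from
#' occupancy-binned freezing rates.
#'
#' @param params a [track_synth_params()]; `freeze_fraction` is ignored (the
#'   field gate replaces it)
#' @param grid a [field_grid()] covering the arena
#' @param threshold_mT field strength at or above which freezing can start
#' @param freeze_hazard rate (1/s) of entering a freeze while above threshold
#' @param gate_margin_mT interior margin added to the gate: freezes start
#'   only where the field exceeds `threshold_mT + gate_margin_mT`, so that
#'   tracking jitter (which perturbs the field read back from tracked
#'   positions by well under this margin at realistic gradients) cannot move
#'   a frozen sample below the nominal threshold
#' @return a `synthetic_track` (see [generate_track()])
#' @export
generate_track_field_coupled <- function(params, grid, threshold_mT = 180,
                                         freeze_hazard = 0.3,
                                         gate_margin_mT = 2) {
  stopifnot(inherits(params, "track_synth_params"))
  p <- params
  with_seed(p$seed, {
    q_dt <- 2 / p$frame_rate
    n_quanta <- max(1L, as.integer(round(p$duration / q_dt)))
    p_enter <- 1 - exp(-freeze_hazard * q_dt)
    # simulate state and position jointly, quantum by quantum
    fr <- p$frame_rate
    w <- p$arena_size[1]; h <- p$arena_size[2]
    margin <- 1
    step <- p$mean_ambulation_speed / fr
    x <- stats::runif(1, w * 0.25, w * 0.75)
    y <- stats::runif(1, h * 0.25, h * 0.75)
    th <- stats::runif(1, -pi, pi)
    state_q <- integer(n_quanta)
    xs <- numeric(2 * n_quanta); ys <- numeric(2 * n_quanta)
    ths <- numeric(2 * n_quanta)
    freeze_left <- 0L
    for (q in seq_len(n_quanta)) {
      if (freeze_left > 0L) {
        state_q[q] <- 2L
        freeze_left <- freeze_left - 1L
      } else {
        b <- field_at(grid, min(max(x, min(grid$x_nodes)), max(grid$x_nodes)),
                      min(max(y, min(grid$y_nodes)), max(grid$y_nodes)))
        if (b >= threshold_mT + gate_margin_mT && stats::runif(1) < p_enter) {
          state_q[q] <- 2L
          freeze_left <- max(1L, as.integer(round(
            stats::rexp(1, 1 / p$mean_freeze_bout) / q_dt))) - 1L
        } else {
          state_q[q] <- 1L
        }
      }
      for (j in 1:2) {
        i <- 2L * (q - 1L) + j
        if (state_q[q] == 1L) {
          th <- th + stats::rnorm(1, 0, p$turn_sd)
          nx <- x + step * cos(th); ny <- y + step * sin(th)
          if (nx < margin) { nx <- 2 * margin - nx; th <- pi - th }
          if (nx > w - margin) { nx <- 2 * (w - margin) - nx; th <- pi - th }
          if (ny < margin) { ny <- 2 * margin - ny; th <- -th }
          if (ny > h - margin) { ny <- 2 * (h - margin) - ny; th <- -th }
          x <- nx; y <- ny
        }
        xs[i] <- x; ys[i] <- y; ths[i] <- th
      }
    }
    n_frames <- 2L * n_quanta
    t <- (seq_len(n_frames) - 1L) / fr
    d <- data.frame(t = t)
    for (kp in names(p$keypoint_offsets)) {
      off <- p$keypoint_offsets[[kp]]
      kx <- xs + off[1] * cos(ths) - off[2] * sin(ths)
      ky <- ys + off[1] * sin(ths) + off[2] * cos(ths)
      if (p$jitter_sd > 0) {
        kx <- kx + stats::rnorm(n_frames, 0, p$jitter_sd)
        ky <- ky + stats::rnorm(n_frames, 0, p$jitter_sd)
      }
      d[[paste0(kp, "_x")]] <- kx
      d[[paste0(kp, "_y")]] <- ky
    }
    structure(
      list(
        track = keypoint_track(d, p$frame_rate, p$arena_size),
        freeze_intervals = states_to_intervals(state_q, q_dt),
        state = c("ambulate", "freeze")[rep(state_q, each = 2L)],
        params = p
      ),
      class = "synthetic_track"
    )
  })
}
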