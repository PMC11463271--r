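#' Dual-channel photometry session
#'
#' Paired calcium-dependent (465 nm) and isosbestic (405 nm) traces on one
#' time grid, with optional TTL event times marking behavioral triggers.
#'
#' @param t time, seconds
#' @param f465 raw calcium-dependent channel, arbitrary units
#' @param f405 raw isosbestic channel, arbitrary units
#' @param fs sampling rate, Hz
#' @param events TTL event times, seconds (within the recording)
#' @return object of class `photometry_session`
#' @export
photometry_session <- function(t, f465, f405, fs, events = numeric(0)) {
  if (length(t) != length(f465) || length(f465) != length(f405)) {
    stop("t, f465 and f405 must have equal length", call. = FALSE)
  }
  assert_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  if (length(events) && (any(events < t[1]) || any(events > t[length(t)]))) {
    stop("events must lie within the recording", call. = FALSE)
  }
  structure(list(t = as.numeric(t), f465 = as.numeric(f465),
                 f405 = as.numeric(f405), fs = fs,
                 events = as.numeric(events)),
            class = "photometry_session")
}

#' Read a photometry session CSV (columns t, f465, f405)
#' @param path CSV path
#' @param events_path optional one-column CSV of TTL event times
#' @param fs sampling rate; inferred from the time grid when `NULL`
#' @return a `photometry_session`
#' @export
read_photometry_csv <- function(path, events_path = NULL, fs = NULL) {
  d <- utils::read.csv(path)
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$t))
  ev <- if (!is.null(events_path)) utils::read.csv(events_path)[[1]] else numeric(0)
  photometry_session(d$t, d$f465, d$f405, fs, ev)
}

#' Ordinary least-squares fit of the isosbestic channel to the signal channel
#'
#' Regresses `f465` on `f405`; the fitted values are the motion/bleaching
#' prediction to subtract from the raw signal.
#'
#' @param f465,f405 equal-length numeric traces
#' @return list with `slope`, `intercept`, and `f405_fitted`
#' @export
fit_isosbestic <- function(f465, f405) {
  if (length(f465) != length(f405) || length(f465) < 2L) {
    stop("need two equal-length traces with >= 2 samples", call. = FALSE)
  }
  if (stats::sd(f405) == 0) {
    stop("constant isosbestic channel: fit undefined", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, f405), f465)
  co <- fit$coefficients
  list(slope = unname(co[2]), intercept = unname(co[1]),
       f405_fitted = unname(co[1] + co[2] * f405))
}

#' Isosbestic-corrected dF/F (%)
#'
#' Both raw channels are optionally low-pass filtered (2nd-order Butterworth,
#' `lowpass_hz` corner, zero-phase), then the isosbestic channel is linearly
#' fitted to the signal channel over the whole session and subtracted:
#' `net = f465 - f405_fitted`. The session median of `net` is subtracted and
#' the result divided by the reference to give percent dF/F. Because the
#' least-squares residual is centred, `median(net)` is usually near zero, so
#' when it falls below `floor_frac * median(f465)` the session median of the
#' raw 465 channel is used as the denominator instead and the trace is
#' flagged (`denominator_substituted`).
#'
#' @param session a [photometry_session()]
#' @param lowpass_hz corner frequency in Hz, or `NULL` to skip filtering;
#'   skipped automatically when `fs <= 2 * lowpass_hz`
#' @param floor_frac denominator guard as a fraction of `median(f465)`
#' @return list of class `dff_trace`: `t`, `dff` (percent), `net`,
#'   `net_median`, `denominator`, `denominator_substituted`, `fit`, `fs`,
#'   `events`
#' @export
compute_dff <- function(session, lowpass_hz = 15, floor_frac = 0.01) {
  stopifnot(inherits(session, "photometry_session"))
  f465 <- session$f465
  f405 <- session$f405
  if (!is.null(lowpass_hz) && session$fs > 2 * lowpass_hz) {
    bf <- signal::butter(2, 2 * lowpass_hz / session$fs, type = "low")
    f465 <- as.numeric(signal::filtfilt(bf, f465))
    f405 <- as.numeric(signal::filtfilt(bf, f405))
  }
  fit <- fit_isosbestic(f465, f405)
  net <- f465 - fit$f405_fitted
  net_med <- stats::median(net)
  floor_val <- floor_frac * stats::median(f465)
  substituted <- net_med < floor_val
  denom <- if (substituted) stats::median(f465) else net_med
  if (!is.finite(denom) || denom <= 0) {
    stop("dF/F denominator is non-positive after the guard", call. = FALSE)
  }
  structure(
    list(t = session$t, dff = 100 * (net - net_med) / denom, net = net,
         net_median = net_med, denominator = denom,
         denominator_substituted = substituted, fit = fit, fs = session$fs,
         events = session$events),
    class = "dff_trace"
  )
}

#' Per-epoch mean dF/F (%)
#'
#' @param dff a `dff_trace` from [compute_dff()]
#' @param epochs an [epoch_set()]
#' @return data.frame with columns `label` and `mean_dff`
#' @export
epoch_means <- function(dff, epochs) {
  stopifnot(inherits(dff, "dff_trace"))
  rows <- lapply(seq_len(nrow(epochs)), function(i) {
    sel <- dff$t >= epochs$start[i] & dff$t < epochs$end[i]
    if (!any(sel)) stop(sprintf("epoch '%s' contains no samples",
                                epochs$label[i]), call. = FALSE)
    data.frame(label = epochs$label[i], mean_dff = mean(dff$dff[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Event-aligned dF/F segments and mean trace
#'
#' Cuts a `[-pre_s, post_s]` window around each TTL event, re-baselines each
#' trial to its pre-event window mean, and averages across trials. Events
#' whose window would run outside the session are dropped with a warning.
#'
#' @param dff a `dff_trace`
#' @param events event times, seconds (defaults to the session TTLs)
#' @param pre_s,post_s window extent before/after the event, seconds
#' @return list of class `event_aligned`: `lag` (seconds relative to event),
#'   `trials` (trial x time matrix), `mean_trace`, `n_trials`,
#'   `events_used`
#' @export
align_to_events <- function(dff, events = dff$events, pre_s = 2, post_s = 5) {
  stopifnot(inherits(dff, "dff_trace"))
  fs <- dff$fs
  npre <- as.integer(round(pre_s * fs))
  npost <- as.integer(round(post_s * fs))
  t0 <- dff$t[1]
  n <- length(dff$t)
  idx <- as.integer(round((events - t0) * fs)) + 1L
  ok <- idx - npre >= 1L & idx + npost <= n
  if (any(!ok)) warning(sprintf("%d event(s) dropped: window outside session",
                                sum(!ok)))
  idx <- idx[ok]
  if (length(idx) == 0L) stop("no retained events", call. = FALSE)
  lag <- (-npre:npost) / fs
  trials <- t(vapply(idx, function(i) {
    seg <- dff$dff[(i - npre):(i + npost)]
    if (npre > 0L) seg - mean(seg[seq_len(npre)]) else seg
  }, numeric(npre + npost + 1L)))
  list(lag = lag, trials = trials, mean_trace = colMeans(trials),
       n_trials = length(idx), events_used = events[ok])
}
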