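#' Parameters for the synthetic dual-channel photometry generator
#'
#' Emulates a demodulated two-color fiber-photometry recording: the
#' calcium-dependent 465 nm channel carries a bleaching baseline, a slow
#' shared motion artifact, a train of indicator transients and white noise;
#' the isosbestic 405 nm channel carries the same shared components scaled by
#' `iso_gain` plus its own noise, but no transients. The shared structure is
#' what an isosbestic linear fit is meant to remove.
#'
#' @param duration recording length, seconds
#' @param fs sampling rate, Hz
#' @param baseline mean raw fluorescence of the 465 channel, arbitrary units
#' @param bleach_tau photobleaching time constant, seconds
#' @param n_transients number of calcium transients
#' @param transient_amplitude transient peak amplitude, same units as
#'   `baseline`
#' @param transient_rise,transient_decay kernel time constants, seconds
#'   (`transient_decay > transient_rise > 0`)
#' @param transient_times optional explicit onset times; when `NULL`, onsets
#'   are drawn uniformly over the session interior
#' @param artifact_amplitude SD of the slow shared artifact, same units
#' @param artifact_tau correlation time of the artifact, seconds
#' @param iso_gain scale of the shared components in the 405 channel
#' @param noise_sd per-sample white-noise SD in each channel
#' @param seed integer seed
#' @return list of class `photometry_synth_params`
#' @export
photometry_synth_params <- function(duration = 300, fs = 100, baseline = 100,
                                    bleach_tau = 1200, n_transients = 10,
                                    transient_amplitude = 5,
                                    transient_rise = 0.5,
                                    transient_decay = 1.5,
                                    transient_times = NULL,
                                    artifact_amplitude = 5, artifact_tau = 2,
                                    iso_gain = 0.5, noise_sd = 0.3,
                                    seed = 1L) {
  assert_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  assert_scalar_num(duration, "duration", lower = 0, strict_lower = TRUE)
  if (!(transient_decay > transient_rise && transient_rise > 0)) {
    stop("need transient_decay > transient_rise > 0", call. = FALSE)
  }
  if (n_transients < 0) stop("n_transients must be >= 0", call. = FALSE)
  structure(
    list(duration = duration, fs = fs, baseline = baseline,
         bleach_tau = bleach_tau, n_transients = as.integer(n_transients),
         transient_amplitude = transient_amplitude,
         transient_rise = transient_rise, transient_decay = transient_decay,
         transient_times = transient_times,
         artifact_amplitude = artifact_amplitude, artifact_tau = artifact_tau,
         iso_gain = iso_gain, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "photometry_synth_params"
  )
}

# unit-peak double-exponential transient kernel evaluated at lags `tl` (s)
transient_kernel <- function(tl, rise, decay) {
  k <- exp(-tl / decay) - exp(-tl / rise)
  k[tl < 0] <- 0
  tpk <- log(decay / rise) * rise * decay / (decay - rise)
  k / (exp(-tpk / decay) - exp(-tpk / rise))
}

#' Unit-peak transient kernel shape
#'
#' Double-exponential indicator kernel, normalised to peak 1, evaluated at
#' lags relative to onset. Useful as the reference shape when checking
#' event-aligned averages against injected ground truth.
#'
#' @param lag lags relative to transient onset, seconds (negative lags are 0)
#' @param rise,decay kernel time constants, seconds
#' @return numeric vector of kernel values
#' @export
transient_shape <- function(lag, rise = 0.5, decay = 1.5) {
  transient_kernel(lag, rise, decay)
}

# slow artifact: Ornstein-Uhlenbeck process scaled to target SD
ou_process <- function(n, fs, tau, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  a <- exp(-1 / (fs * tau))
  z <- stats::rnorm(n)
  x <- as.numeric(stats::filter(z * sqrt(1 - a^2), a, method = "recursive"))
  x * sd_target
}

#' Generate a synthetic photometry session with known ground truth
#'
#' @param params a [photometry_synth_params()]
#' @return list of class `synthetic_photometry`: `session` (a
#'   [photometry_session()] whose TTL events are the transient onsets),
#'   `truth` (list with `transient_times`, `transient_amplitude`, `artifact`,
#'   `kernel_peak_lag`), and `params`.
#' @export
generate_photometry <- function(params) {
  stopifnot(inherits(params, "photometry_synth_params"))
  p <- params
  with_seed(p$seed, {
    n <- as.integer(round(p$duration * p$fs))
    t <- (seq_len(n) - 1L) / p$fs
    bleach <- exp(-t / p$bleach_tau)
    artifact <- ou_process(n, p$fs, p$artifact_tau, p$artifact_amplitude)
    times <- if (!is.null(p$transient_times)) {
      sort(p$transient_times)
    } else if (p$n_transients > 0) {
      sort(stats::runif(p$n_transients, 0.05 * p$duration, 0.9 * p$duration))
    } else {
      numeric(0)
    }
    train <- numeric(n)
    for (tt in times) {
      train <- train + p$transient_amplitude *
        transient_kernel(t - tt, p$transient_rise, p$transient_decay)
    }
    shared <- p$baseline * bleach + artifact
    noise465 <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else 0
    noise405 <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else 0
    f465 <- shared + train + noise465
    f405 <- p$iso_gain * shared + noise405
    tpk <- log(p$transient_decay / p$transient_rise) *
      p$transient_rise * p$transient_decay /
      (p$transient_decay - p$transient_rise)
    structure(
      list(
        session = photometry_session(t, f465, f405, p$fs, events = times),
        truth = list(transient_times = times,
                     transient_amplitude = p$transient_amplitude,
                     artifact = artifact, kernel_peak_lag = tpk),
        params = p
      ),
      class = "synthetic_photometry"
    )
  })
}
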