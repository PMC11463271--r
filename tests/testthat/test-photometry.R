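# photometry: isosbestic fit, dF/F, epoch means, event alignment

test_that("isosbestic fit recovers an exact linear relation", {
  set.seed(1)
  f405 <- 50 + cumsum(rnorm(200))
  f465 <- 2 * f405 + 1
  fit <- fit_isosbestic(f465, f405)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  expect_equal(fit$f405_fitted, f465, tolerance = 1e-10)
})

test_that("isosbestic fit matches the closed-form normal equations", {
  set.seed(2)
  for (i in 1:10) {
    f405 <- rnorm(300, 80, 5)
    f465 <- rnorm(300, 100, 8)
    fit <- fit_isosbestic(f465, f405)
    slope <- cov(f465, f405) / var(f405)
    expect_equal(fit$slope, slope, tolerance = 1e-10)
    expect_equal(fit$intercept, mean(f465) - slope * mean(f405),
                 tolerance = 1e-10)
  }
  # independent channels: slope shrinks to zero
  set.seed(3)
  fit0 <- fit_isosbestic(rnorm(20000), rnorm(20000))
  expect_lt(abs(fit0$slope), 0.05)
  expect_error(fit_isosbestic(rnorm(10), rep(1, 10)), "constant")
})

test_that("dF/F of a purely linear session is identically zero", {
  t <- seq(0, 10, by = 0.01)
  f405 <- 60 + 5 * sin(t)
  f465 <- 1.8 * f405 + 12
  s <- photometry_session(t, f465, f405, fs = 100)
  dff <- compute_dff(s, lowpass_hz = NULL)  # the exact-identity case
  expect_true(dff$denominator_substituted)
  expect_equal(max(abs(dff$dff)), 0, tolerance = 1e-8)
})

test_that("dF/F is centred and invariant to common positive rescaling", {
  syn <- generate_photometry(photometry_synth_params(duration = 60,
                                                     n_transients = 0,
                                                     seed = 4))
  d1 <- compute_dff(syn$session)
  expect_equal(median(d1$dff), 0, tolerance = 1e-12)
  s2 <- photometry_session(syn$session$t, 3.7 * syn$session$f465,
                           3.7 * syn$session$f405, syn$session$fs)
  d2 <- compute_dff(s2)
  expect_equal(d2$dff, d1$dff, tolerance = 1e-6)
})

test_that("isosbestic correction removes the shared artifact", {
  syn <- generate_photometry(photometry_synth_params(duration = 120,
                                                     n_transients = 0,
                                                     seed = 5))
  dff <- compute_dff(syn$session)
  expect_lt(abs(cor(dff$dff, syn$truth$artifact)), 0.1)
  expect_gt(abs(cor(syn$session$f465, syn$truth$artifact)), 0.5)
})

test_that("transient peaks appear at the injected times", {
  ev <- c(20, 45, 70, 95)
  syn <- generate_photometry(photometry_synth_params(
    duration = 120, transient_times = ev, n_transients = 4,
    transient_amplitude = 20, noise_sd = 0.1, artifact_amplitude = 1,
    seed = 6))
  dff <- compute_dff(syn$session)
  lag_pk <- syn$truth$kernel_peak_lag
  for (e in ev) {
    win <- dff$t > e - 0.5 & dff$t < e + lag_pk + 2
    tpk <- dff$t[win][which.max(dff$dff[win])]
    expect_lt(abs(tpk - (e + lag_pk)), 0.25)
  }
})

test_that("epoch means equal brute-force per-sample averages", {
  syn <- generate_photometry(photometry_synth_params(duration = 90, seed = 7))
  dff <- compute_dff(syn$session)
  ep <- epoch_set(c("pre", "dmf", "post"), c(0, 30, 60), c(30, 60, 90))
  em <- epoch_means(dff, ep)
  for (i in 1:3) {
    sel <- dff$t >= ep$start[i] & dff$t < ep$end[i]
    expect_equal(em$mean_dff[i], sum(dff$dff[sel]) / sum(sel))
  }
  # a step change at an epoch boundary is recovered exactly
  t <- seq(0, 59.99, by = 0.01)
  fake <- structure(list(t = t, dff = ifelse(t >= 30, 7, 0), fs = 100,
                         events = numeric(0)), class = "dff_trace")
  em2 <- epoch_means(fake, epoch_set(c("pre", "dmf"), c(0, 30), c(30, 60)))
  expect_equal(em2$mean_dff, c(0, 7))
  expect_error(epoch_means(dff, epoch_set("late", 89.991, 89.995)), "samples")
})

test_that("event alignment is exact in degenerate cases", {
  t <- seq(0, 99.99, by = 0.01)
  zero <- structure(list(t = t, dff = rep(0, length(t)), fs = 100,
                         events = 50), class = "dff_trace")
  al <- align_to_events(zero, 50, pre_s = 1, post_s = 2)
  expect_true(all(al$trials == 0))
  per <- structure(list(t = t, dff = sin(2 * pi * t / 10), fs = 100,
                        events = numeric(0)), class = "dff_trace")
  al2 <- align_to_events(per, seq(20, 80, by = 10), pre_s = 1, post_s = 2)
  expect_equal(al2$mean_trace, al2$trials[1, ], tolerance = 1e-9)
  expect_warning(align_to_events(per, c(0.1, 50), pre_s = 1, post_s = 2),
                 "dropped")
  expect_error(suppressWarnings(align_to_events(per, 0.1, pre_s = 1,
                                                post_s = 2)), "retained")
})

test_that("event-aligned mean recovers the injected kernel", {
  # 8 s spacing so the previous transient's tail has fully decayed before
  # the next pre-event baseline window
  ev <- seq(10, 290, by = 8)
  syn <- generate_photometry(photometry_synth_params(
    duration = 300, transient_times = ev, n_transients = length(ev),
    seed = 8))
  dff <- compute_dff(syn$session)
  al <- align_to_events(dff, ev, pre_s = 0.5, post_s = 3)
  kern <- transient_shape(al$lag, 0.5, 1.5)
  keep <- al$lag >= 0
  expect_gt(cor(al$mean_trace[keep], kern[keep]), 0.95)
  expected_peak <- 100 * syn$params$transient_amplitude / dff$denominator
  expect_lt(abs(max(al$mean_trace) - expected_peak) / expected_peak, 0.1)
})

test_that("sessions round-trip through CSV with TTL events", {
  syn <- generate_photometry(photometry_synth_params(duration = 10,
                                                     n_transients = 3,
                                                     seed = 9))
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t = syn$session$t, f465 = syn$session$f465,
                              f405 = syn$session$f405), p1, row.names = FALSE)
  utils::write.csv(data.frame(t = syn$session$events), p2, row.names = FALSE)
  back <- read_photometry_csv(p1, p2)
  expect_equal(back$f465, syn$session$f465, tolerance = 1e-9)
  expect_equal(back$events, syn$session$events, tolerance = 1e-9)
  expect_equal(back$fs, 100, tolerance = 1e-6)
  unlink(c(p1, p2))
})
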