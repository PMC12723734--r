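test_that("pixel ACF matches hand-computed values and flags zero-mean pixels", {
  alt <- tab_movie(array(rep(c(2, 0), 3), c(6, 1, 1)), 46, 2.5)
  expect_equal(pixel_acf(alt, 1, engine = "direct")$G[1, 1, 1], -1)
  expect_equal(pixel_acf(alt, 1, engine = "fft")$G[1, 1, 1], -1)

  const <- tab_movie(array(5, c(8, 2, 2)), 46, 2.5)
  expect_true(all(pixel_acf(const, 1:3)$G == 0))

  # one pixel identically zero -> undefined G, flagged NA
  arr <- array(rexp(40), c(10, 2, 2))
  arr[, 2, 2] <- 0
  pa <- pixel_acf(tab_movie(arr, 46, 2.5), 1:2)
  expect_true(all(is.na(pa$G[2, 2, ])))
  expect_true(all(is.finite(pa$G[1, 1, ])))
})

test_that("FFT and direct ACF engines agree to 1e-10 relative", {
  set.seed(17)
  nf <- 200
  m <- tab_movie(array(rexp(nf * 4 * 4, 1 / 7), c(nf, 4, 4)), 46, 2.5)
  lags <- c(1L, 2L, 3L, 7L, 19L, 60L, 150L)
  g_fft <- pixel_acf(m, lags, engine = "fft")$G
  g_dir <- pixel_acf(m, lags, engine = "direct")$G
  expect_lt(max(abs(g_fft - g_dir)) / max(abs(g_dir)), 1e-10)
})

test_that("the ACF numerator is exactly the second-order cumulant", {
  set.seed(18)
  nf <- 120
  m <- tab_movie(array(rpois(nf * 3 * 3, 20) + 0.0, c(nf, 3, 3)), 46, 2.5)
  mu <- apply(m$data, c(2, 3), mean)
  for (tau in c(1L, 4L, 30L)) {
    g <- pixel_acf(m, tau, engine = "direct")$G[, , 1]
    expect_equal(g * mu^2, second_order_cumulant(m, tau), tolerance = 1e-13)
    g2 <- pixel_acf(m, tau, engine = "fft")$G[, , 1]
    expect_equal(g2 * mu^2, second_order_cumulant(m, tau), tolerance = 1e-10)
  }
})

test_that("segment averaging computes mean and SEM per lag", {
  mk <- function(vals) {
    # fabricate a pixel_acf with fixed G values on a 1x1 grid
    structure(list(G = array(vals, c(1, 1, length(vals))),
                   lags = seq_along(vals),
                   lags_ms = 2.5 * seq_along(vals),
                   mean_intensity = matrix(1, 1, 1),
                   n_frames = 100L), class = "pixel_acf")
  }
  # identical segments -> SEM 0
  rec0 <- average_segments(list(mk(c(1, 0.5)), mk(c(1, 0.5))))
  expect_true(all(rec0$sem == 0))

  # two segments 0.9 / 1.1 -> mean 1.0, SEM 0.1
  rec <- average_segments(list(mk(0.9), mk(1.1)))
  expect_equal(rec$G[1, 1, 1], 1.0)
  expect_equal(rec$sem[1, 1, 1], 0.1)

  # six segments recorded as such
  rec6 <- average_segments(lapply(1:6, function(i) mk(c(1, 0.5, 0.2))))
  expect_identical(rec6$n_segments, 6L)

  # single segment: SEM undefined, flagged
  rec1 <- average_segments(list(mk(c(1, 0.5))))
  expect_true(all(is.na(rec1$sem)))
})

test_that("ACF signal-to-noise follows the amplitude / tail-sd rule", {
  tail5 <- c(0.05, -0.03, 0.01, 0.02, -0.05)
  g <- c(1, 1, 1, 0.5, 0.3, tail5)
  expect_equal(estimate_snr(g), 1 / sd(tail5))

  expect_equal(estimate_snr(rep(0, 10)), 0)          # flat zero ACF
  expect_equal(estimate_snr(c(2, 2, 2, rep(1, 7))), Inf)  # zero tail sd
  expect_equal(estimate_snr(c(2, 2, 2, 0.5, 0.2, tail5 / 20)),
               2 / sd(tail5 / 20))
  expect_error(estimate_snr(c(1, 0.5)), "6 lags")
})

test_that("the two-component model refits its own noiseless curve to < 1%", {
  lags <- acf_lag_grid(6000) * 2.5
  truth <- c(G0 = 0.5, f_fast = 0.6, tau_fast = 20, f_slow = 0.4,
             tau_slow = 400, g_inf = 0)
  g <- 0.5 * (1 - 0.6 + 0.6 * exp(-lags / 20)) *
    (1 - 0.4 + 0.4 * exp(-lags / 400))
  # with the offset pinned at its known value the product model is
  # uniquely identified (a free offset opens a near-degenerate direction)
  fit <- fit_acf(lags, g, model = "two_component", g_inf_fixed = 0)
  expect_true(fit$converged)
  cf <- coef(fit)
  expect_lt(abs(cf["G0"] - 0.5) / 0.5, 0.01)
  expect_lt(abs(cf["tau_fast_ms"] - 20) / 20, 0.01)
  expect_lt(abs(cf["tau_slow_ms"] - 400) / 400, 0.01)
  expect_lt(abs(cf["f_fast"] - 0.6), 0.01)
  expect_lt(abs(cf["f_slow"] - 0.4), 0.01)
  expect_lt(fit$reduced_chi2, 1e-10)
  # model methods are consistent
  expect_equal(predict(fit, lags), g, tolerance = 1e-4)
  expect_equal(fitted(fit) + residuals(fit), g, tolerance = 1e-12)
})

test_that("relaxation times are relabeled so fast <= slow", {
  lags <- acf_lag_grid(4000) * 2.5
  g <- 0.4 * (0.5 + 0.5 * exp(-lags / 30)) * (0.5 + 0.5 * exp(-lags / 600))
  fit <- fit_acf(lags, g)
  cf <- coef(fit)
  expect_lte(cf["tau_fast_ms"], cf["tau_slow_ms"])
})

test_that("a telegraph trace decays with the telegraph correlation time", {
  # two-state Markov blinking: correlation time -1/log(1 - k_on - k_off)
  p_on <- 0.2; mean_on <- 5
  k_off <- 1 / mean_on; k_on <- k_off * p_on / (1 - p_on)
  tau_frames <- -1 / log(1 - k_on - k_off)
  sim <- simulate_blinking_emitter(60000, c(1L, 1L), position_px = c(0, 0),
                                   p_on = p_on, mean_on_frames = mean_on,
                                   psf_sigma_px = 0.5, photons_per_frame = 200,
                                   background_photons = 0, noise = FALSE,
                                   pixel_size_nm = 46, frame_time_ms = 1,
                                   seed = 23)
  lags <- 1:20
  pa <- pixel_acf(sim$movie, lags)
  g <- pa$G[1, 1, ]
  fit <- fit_acf(lags * 1.0, g, model = "one_component")
  expect_lt(abs(coef(fit)["tau_fast_ms"] - tau_frames) / tau_frames, 0.1)
})

test_that("binding ACF amplitude scales as 1/occupancy at fixed kinetics", {
  amp <- vapply(c(2, 4, 8), function(rate) {
    f <- single_site_field(207, 207, c(414, 414))
    kin <- kinetics_model(rate, 50, 51, 1)
    ev <- simulate_binding_events(f, kin, 50000 * 2.5, seed = 11)
    acq <- acquisition_config(2.5, 46, 50000L, fov_px = c(9L, 9L))
    opt <- optics_model(130, 57.5, 0, 0, 0)
    sim <- render_movie(ev, opt, acq, seed = 11)
    pa <- pixel_acf(sim$movie, 1:3)
    mean(pa$G[5, 5, ])
  }, 0)
  expect_lt(abs(amp[1] / amp[2] - 2), 0.5)
  expect_lt(abs(amp[2] / amp[3] - 2), 0.5)
  # absolute scale: G0 ~ 1 / (rate * mean dwell)
  expect_lt(abs(amp[1] * (2 * 0.05) - 1), 0.35)
})

test_that("the mean gated pixel ACF matches the theoretical binding curve", {
  seed <- 3
  px <- 46; dt <- 2.5; nf <- 12000L; fovpx <- 16L
  field <- fibril_field(c(fovpx * px, fovpx * px), 2, 0.2, seed = seed)
  kin <- kinetics_model(2, 23, 482, 0.95)
  ev <- simulate_binding_events(field, kin, nf * dt, seed = seed)
  optics <- optics_model(130, 57.5, 0.55, 0.5, 0)
  acq <- acquisition_config(dt, px, nf, fov_px = c(fovpx, fovpx))
  rec <- segmented_pixel_acf(ev, optics, acq, n_segments = 6, seed = seed)
  snr <- estimate_snr(rec)
  gate <- is.finite(snr) & snr > 10
  expect_gt(sum(gate), 10)
  mg <- apply(rec$G, 3, function(m) mean(m[gate]))
  th <- expected_acf(kin, 0.1, rec$lags_ms)$G
  expect_gt(cor(mg, th), 0.98)
})

test_that("pixel-level fitting gates on SNR and maps stay in range", {
  # small uniform-kinetics movie
  seed <- 19
  px <- 46; dt <- 2.5; nf <- 6000L; fovpx <- 10L
  field <- fibril_field(c(fovpx * px, fovpx * px), 1, 0.3, seed = seed)
  kin <- kinetics_model(3, 20, 200, 0.9)
  ev <- simulate_binding_events(field, kin, nf * dt, seed = seed)
  optics <- optics_model(130, 57.5, 0.55, 0.5, 0)
  acq <- acquisition_config(dt, px, nf, fov_px = c(fovpx, fovpx))
  rec <- segmented_pixel_acf(ev, optics, acq, n_segments = 4, seed = seed)

  # an impossible gate masks everything
  fits_none <- fit_acf_pixels(rec, snr_gate = Inf)
  expect_identical(nrow(fits_none), 0L)
  maps_none <- build_maps(fits_none)
  expect_false(any(maps_none$valid))
  expect_true(all(is.na(maps_none$tau_slow_ms)))

  fits <- fit_acf_pixels(rec, snr_gate = 5,
                         tau_bounds_ms = c(dt, nf / 4 * dt))
  expect_gt(nrow(fits), 5)
  maps <- build_maps(fits, snr_gate = 5)
  ff <- maps$fast_fraction[maps$valid]
  expect_true(all(ff >= 0 & ff <= 1))
  expect_true(all(maps$tau_fast_ms[maps$valid] <=
                    maps$tau_slow_ms[maps$valid]))
  # invalid pixels are NA, not zero
  expect_false(any(maps$tau_slow_ms[!maps$valid] == 0, na.rm = TRUE))
})

test_that("lag grids are increasing, unique, and bounded", {
  g <- acf_lag_grid(6000)
  expect_true(all(diff(g) > 0))
  expect_identical(g[1], 1L)
  expect_lte(max(g), 2000L)
  expect_error(acf_lag_grid(10, max_lag = 20), "max_lag")
})
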