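test_that("fibril_field is reproducible and validates input", {
  f1 <- fibril_field(c(4000, 4000), 3, 0.1, seed = 5)
  f2 <- fibril_field(c(4000, 4000), 3, 0.1, seed = 5)
  expect_identical(f1, f2)
  f3 <- fibril_field(c(4000, 4000), 3, 0.1, seed = 6)
  expect_false(identical(f1$sites, f3$sites))
  expect_error(fibril_field(c(-1, 100), 1, 0.1), "FOV")
  # sites inside FOV
  expect_true(all(f1$sites[, "x_nm"] >= 0 & f1$sites[, "x_nm"] <= 4000))
  expect_true(all(f1$sites[, "y_nm"] >= 0 & f1$sites[, "y_nm"] <= 4000))
})

test_that("no fibrils means no binding sites", {
  f <- fibril_field(c(2000, 2000), 0, 0.1, seed = 1)
  expect_identical(nrow(f$sites), 0L)
})

test_that("site counts follow a Poisson law along the backbone", {
  # 1000 nm near-straight fibril in a large FOV (cannot hit the border),
  # density 0.1/nm -> counts ~ Poisson(100)
  counts <- vapply(1:200, function(s)
    nrow(fibril_field(c(10000, 10000), 1, 0.1, persistence_nm = 1e9,
                      length_nm = 1000, seed = s)$sites), 1L)
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 200))
  expect_gt(var(counts), 50)  # genuinely dispersed, not deterministic
})

test_that("binding-event dwells follow the specified mixture", {
  fov <- c(2000, 2000)
  field <- fibril_field(fov, 1, 0.05, seed = 1)

  # pure fast component: exponential with mean tau_fast (events arriving
  # during the pre-observation burn-in are length-biased, so condition on
  # arrivals after time zero)
  kin1 <- kinetics_model(10, 20, 400, f_fast = 1)
  ev1 <- simulate_binding_events(field, kin1, 4e5, seed = 2)
  ev1 <- ev1[ev1$t_on_ms > 0, ]
  expect_gt(nrow(ev1), 5000)
  se <- 20 / sqrt(nrow(ev1))
  expect_lt(abs(mean(ev1$dwell_ms) - 20), 3 * se)

  # 50/50 mixture of 20 and 400 ms -> mean 210 ms
  kin2 <- kinetics_model(10, 20, 400, f_fast = 0.5)
  ev2 <- simulate_binding_events(field, kin2, 1e6, seed = 3)
  ev2 <- ev2[ev2$t_on_ms > 0, ]
  sd_mix <- sqrt(0.5 * (2 * 20^2) + 0.5 * (2 * 400^2) - 210^2)
  expect_lt(abs(mean(ev2$dwell_ms) - 210), 3 * sd_mix / sqrt(nrow(ev2)))

  # empirical CDF converges to the mixture CDF (KS at n = 10,000)
  set.seed(4)
  d <- sample(ev2$dwell_ms, 10000)
  pmix <- function(q) 0.5 * pexp(q, 1 / 20) + 0.5 * pexp(q, 1 / 400)
  expect_gt(suppressWarnings(ks.test(d, pmix)$p.value), 0.01)

  # events are time-sorted and strictly positive dwell
  expect_false(is.unsorted(ev2$t_on_ms))
  expect_true(all(ev2$dwell_ms > 0))
})

test_that("zero arrival rate and empty fields give empty event lists", {
  field <- fibril_field(c(2000, 2000), 1, 0.05, seed = 1)
  kin <- kinetics_model(0, 20, 400, 0.5)
  expect_identical(nrow(simulate_binding_events(field, kin, 1e5)), 0L)
  empty <- fibril_field(c(2000, 2000), 0, 0.05, seed = 1)
  kin2 <- kinetics_model(5, 20, 400, 0.5)
  expect_identical(nrow(simulate_binding_events(empty, kin2, 1e5)), 0L)
})

test_that("rendering with no events and no noise gives a zero movie", {
  ev <- simulate_binding_events(fibril_field(c(500, 500), 0, 0.1, seed = 1),
                                kinetics_model(1, 10, 100, 0.5), 1e3)
  acq <- acquisition_config(30, 92, 10, fov_px = c(8L, 8L))
  optics <- optics_model(130, 690, 0, 0, 0)
  sim <- render_movie(ev, optics, acq, seed = 1, noise = FALSE)
  expect_true(all(sim$movie$data == 0))
})

test_that("noise-free rendering conserves photons frame by frame", {
  r <- render_single_emitter(frames_on = 10:19, n_frames = 25,
                             photons = 1000, fov_px = 31L)
  per_frame <- apply(r$sim$movie$data, 1, sum)
  expect_true(all(abs(per_frame[10:19] - 1000) / 1000 < 0.005))
  expect_true(all(per_frame[-(10:19)] == 0))
  # total photon conservation across the event
  expect_lt(abs(sum(per_frame) - 10 * 1000) / 1e4, 0.005)
})

test_that("rendering is deterministic in the seed", {
  field <- fibril_field(c(1000, 1000), 1, 0.1, seed = 4)
  kin <- kinetics_model(5, 20, 200, 0.8)
  ev <- simulate_binding_events(field, kin, 3e3, seed = 4)
  acq <- acquisition_config(30, 92, 100, fov_px = c(11L, 11L))
  optics <- optics_model(130, 690, 0.55, 2, 0)
  a <- render_movie(ev, optics, acq, seed = 9)
  b <- render_movie(ev, optics, acq, seed = 9)
  c <- render_movie(ev, optics, acq, seed = 10)
  expect_identical(a$movie$data, b$movie$data)
  expect_false(identical(a$movie$data, c$movie$data))
})

test_that("undersampled PSF triggers a warning", {
  ev <- simulate_binding_events(fibril_field(c(500, 500), 0, 0.1, seed = 1),
                                kinetics_model(1, 10, 100, 0.5), 1e3)
  acq <- acquisition_config(30, 92, 10, fov_px = c(8L, 8L))
  optics <- optics_model(10, 690, 0, 0, 0)  # 10 nm PSF on 92 nm pixels
  expect_warning(render_movie(ev, optics, acq, noise = FALSE),
                 "undersampled")
})

test_that("expected_acf has the right limits and reductions", {
  kin <- kinetics_model(1, 20, 400, f_fast = 1)  # no slow component
  lags <- c(0, 5, 20, 60, 1e6)
  g <- expected_acf(kin, mean_occupancy = 0.2, lags_ms = lags, g_inf = 0.01)
  # pure single exponential with time constant tau_fast
  expect_equal(g$G, 5 * exp(-lags / 20) + 0.01, tolerance = 1e-12)
  # lag 0 -> G0 + G_inf; lag -> inf -> G_inf
  expect_equal(g$G[1], 5 + 0.01)
  expect_equal(g$G[5], 0.01, tolerance = 1e-8)

  # two components: dwell-weighted fast fraction
  kin2 <- kinetics_model(1, 20, 400, f_fast = 0.5)
  wf <- 0.5 * 20 / (0.5 * 20 + 0.5 * 400)
  g2 <- expected_acf(kin2, 0.5, c(0, 30))
  expect_equal(g2$G[2], 2 * (wf * exp(-30 / 20) + (1 - wf) * exp(-30 / 400)))
})

test_that("frame-boundary-aligned on-frame counts are geometric", {
  k <- sample_on_frame_counts(20000, 30, 17, seed = 8)
  # P(K = k) proportional to exp(-k dt / tau): check the log-ratio
  tab <- tabulate(k)
  ratios <- tab[2:4] / tab[1:3]
  expect_true(all(abs(log(ratios) + 30 / 17) < 0.15))
  # a uniform arrival phase spreads events over one extra frame, pulling
  # the k = 1 bin far below the geometric continuation of the tail
  ku <- sample_on_frame_counts(20000, 30, 17, phase = "uniform", seed = 8)
  tu <- tabulate(ku)
  expect_lt(tu[1] / tu[2], tab[1] / tab[2])
})
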