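test_that("LoG filter response is zero on constants and linear", {
  expect_true(all(abs(log_filter(matrix(7, 20, 20))) < 1e-12))

  set.seed(1)
  a <- matrix(rexp(400), 20, 20)
  b <- matrix(rexp(400), 20, 20)
  expect_equal(log_filter(a + b), log_filter(a) + log_filter(b),
               tolerance = 1e-12)
})

test_that("LoG filter peaks at the center of a matched Gaussian spot", {
  xy <- expand.grid(r = 1:25, c = 1:25)
  spot <- matrix(exp(-((xy$r - 13)^2 + (xy$c - 16)^2) / (2 * 1.5^2)), 25, 25)
  f <- log_filter(spot, sigma_px = 1.5)
  peak <- which(f == max(f), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(13, 16))
  expect_gt(max(f), 0)
})

test_that("candidate detection finds isolated bright spots exactly once", {
  set.seed(2)
  noise <- matrix(rnorm(64 * 64), 64, 64)
  xy <- expand.grid(r = 1:64, c = 1:64)
  spot <- 20 * exp(-((xy$r - 30)^2 + (xy$c - 41)^2) / (2 * 1.3^2))
  cand <- detect_candidates(log_filter(noise + matrix(spot, 64, 64)))
  expect_identical(nrow(cand), 1L)
  expect_equal(c(cand$row, cand$col), c(30, 41))

  expect_identical(nrow(detect_candidates(matrix(0, 32, 32))), 0L)
})

test_that("noise-only candidate rates are stable across seed batches", {
  rate <- function(seeds) {
    n <- vapply(seeds, function(s) {
      set.seed(s)
      nrow(detect_candidates(log_filter(matrix(rnorm(64 * 64), 64, 64))))
    }, 1L)
    c(mean = mean(n), var = var(n), m = length(n))
  }
  a <- rate(1:150)
  b <- rate(151:300)
  se <- sqrt(a["var"] / a["m"] + b["var"] / b["m"])
  expect_lt(abs(a["mean"] - b["mean"]), 3 * se)
  expect_gt(a["mean"], 0)  # the 3-sigma rule does admit rare noise maxima
})

test_that("Gaussian fitting recovers subpixel positions to < 1 nm", {
  # emitter 17 nm (0.185 px) off a pixel center, noise free
  r <- render_single_emitter(offset_nm = c(17, 0), frames_on = 3:10)
  sub <- r$sim$movie$data[5, , ]
  fit <- fit_gaussian2d(sub, init = list(sigma = 1.3))
  expect_true(fit$fit_ok)
  x_nm <- (fit$x0_px + 0.5) * 92
  y_nm <- (fit$y0_px + 0.5) * 92
  expect_lt(abs(x_nm - r$truth_x), 1)
  expect_lt(abs(y_nm - r$truth_y), 1)
  expect_equal(fit$photons, 690, tolerance = 0.01)
})

test_that("flat subimages are rejected", {
  expect_false(fit_gaussian2d(matrix(3, 9, 9))$fit_ok)
})

test_that("localization precision is consistent with the photon-limited bound", {
  # 690 photons/frame, background 2 photons/px, Poisson noise, 200 repeats
  set.seed(4)
  px <- 92; sigma_psf <- 1.3
  n_rep <- 200
  err <- matrix(NA_real_, n_rep, 2)
  patch_r <- 0:(13 - 1)
  for (i in seq_len(n_rep)) {
    x0 <- 6 + runif(1, -0.5, 0.5); y0 <- 6 + runif(1, -0.5, 0.5)
    lam <- 690 * outer(tabsr:::pixel_gauss_1d(patch_r, y0, sigma_psf),
                       tabsr:::pixel_gauss_1d(patch_r, x0, sigma_psf)) + 2
    sub <- matrix(rpois(length(lam), lam), nrow(lam))
    fit <- fit_gaussian2d(sub, init = list(sigma = sigma_psf))
    if (fit$fit_ok) err[i, ] <- c(fit$x0_px - x0, fit$y0_px - y0)
  }
  err <- err[stats::complete.cases(err), ]
  rmse_nm <- sqrt(mean(err^2)) * px
  # pixelation-corrected sigma with a background inflation term
  sa2 <- sigma_psf^2 + 1 / 12
  bound_nm <- px * sqrt(sa2 / 690) * sqrt(1 + 8 * pi * sa2 * 2 / 690)
  expect_gt(rmse_nm / bound_nm, 0.5)
  expect_lt(rmse_nm / bound_nm, 1.5)
})

test_that("noise-free movies localize to nanometer accuracy end to end", {
  r <- render_single_emitter(offset_nm = c(17, -23), frames_on = 3:10,
                             n_frames = 12)
  locs <- localize_movie(r$sim$movie)
  expect_identical(nrow(locs), 8L)
  err <- sqrt((locs$x_nm - r$truth_x)^2 + (locs$y_nm - r$truth_y)^2)
  expect_lt(max(err), 2)
})

test_that("quality filtering removes constructed outliers and keeps the rest", {
  tab <- as_loc_table(data.frame(
    frame = 1:4, x_nm = 500, y_nm = 500, photons = c(600, 700, 650, 620),
    sigma_nm = c(120, 118, 360, 125),  # third: 3x the nominal PSF width
    residual = 0.1, fit_ok = TRUE))
  out <- filter_localizations(tab)
  expect_identical(nrow(out), 3L)
  expect_false(360 %in% out$sigma_nm)

  # all-pass thresholds are the identity
  all_pass <- filter_localizations(tab, sigma_bounds_nm = c(0, Inf))
  expect_identical(nrow(all_pass), nrow(tab))

  empty <- tab[0, ]
  expect_identical(nrow(filter_localizations(as_loc_table(empty))), 0L)
})

test_that("detected brightness matches the simulated brightness scale", {
  # frame-aligned multi-frame events so every occupied frame is full
  set.seed(9)
  n <- 120
  ev <- as_event_list(data.frame(
    site = seq_len(n), x_nm = runif(n, 400, 5500),
    y_nm = runif(n, 400, 5500), t_on_ms = 30 * sample(0:500, n, TRUE),
    dwell_ms = 300, component = 1L, photons_per_frame_mean = NA_real_))
  acq <- acquisition_config(30, 92, 520, fov_px = c(64L, 64L))
  optics <- optics_model(130, 690, 0.55, 2, 0)
  sim <- render_movie(ev, optics, acq, seed = 4)
  locs <- filter_localizations(suppressWarnings(localize_movie(sim$movie)))
  expect_gt(nrow(locs), 500)
  truth_mean <- mean(sim$truth$events$photons_per_frame_mean)
  expect_lt(abs(mean(locs$photons) - truth_mean) / truth_mean, 0.1)
})

test_that("steady-state movies give a stationary localization rate", {
  sim <- simulate_scenario(list(n_frames = 400L), seed = 12)
  locs <- suppressWarnings(localize_movie(sim$movie))
  counts <- tabulate(locs$frame, nbins = 400)
  # per-frame counts are autocorrelated over ~ tau_slow / frame_time
  # frames; bin over 50-frame windows so the slope test sees (nearly)
  # independent observations
  bins <- colSums(matrix(counts, 50))
  fit <- summary(lm(bins ~ seq_along(bins)))
  expect_gt(coef(fit)["seq_along(bins)", "Pr(>|t|)"], 0.05)
  expect_gt(mean(counts), 0.5)  # a usable event rate throughout
})

test_that("localization tables round-trip through CSV", {
  tab <- fibril_loc_table(50, seed = 3)
  p <- tempfile(fileext = ".csv")
  write_localizations(tab, p)
  tab2 <- read_localizations(p)
  expect_equal(tab2$x_nm, tab$x_nm, tolerance = 1e-9)
  expect_equal(attr(tab2, "pixel_size_nm"), 92)
  expect_equal(attr(tab2, "fov_px"), c(64L, 64L))
})
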