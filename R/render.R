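#' Render a fluorescence movie from a binding-event list
#'
#' Image formation: every bound molecule contributes, in each frame it
#' overlaps, an integrated (error-function) 2-D Gaussian PSF centered at its
#' site, scaled by its per-event brightness and its fractional temporal
#' overlap with the frame. Per-event mean brightness is drawn log-normal
#' with mean `optics$mean_photons_per_frame` and CV `optics$brightness_cv`,
#' reproducing the broad brightness spread of single-molecule data. With
#' `noise = TRUE`, Poisson shot noise is applied to signal + background and
#' Gaussian read noise is added, then clamped at 0.
#'
#' A `frames` range allows long movies to be rendered (and analyzed) one
#' segment at a time without holding the full stack in memory; per-event
#' brightness is drawn from a sub-stream independent of the range, so the
#' same event has the same brightness in every segment.
#'
#' @param events an `event_list` from [simulate_binding_events()].
#' @param optics an [optics_model()].
#' @param acq an [acquisition_config()] (frame time, pixel size, FOV,
#'   frame count).
#' @param seed RNG seed; fixed seed gives a bit-identical movie.
#' @param frames optional integer `c(first, last)` 1-based frame range.
#' @param noise logical; disable to obtain the noiseless expected image
#'   (useful for photon-conservation checks).
#' @return A list of class `tab_sim`: `movie` (a [tab_movie()]) and
#'   `truth` (ground truth: the event list with drawn brightnesses, the
#'   optics, acquisition and seed).
#' @export
render_movie <- function(events, optics, acq, seed = NULL, frames = NULL,
                         noise = TRUE) {
  stopifnot(inherits(optics, "optics_model"), inherits(acq, "tab_acq"))
  psf_px <- optics$psf_sigma_nm / acq$pixel_size_nm
  if (psf_px < 0.25)
    warning("PSF sigma below 0.25 pixel: undersampled PSF")
  frames <- frames %||% c(1L, acq$n_frames)
  f0 <- as.integer(frames[1]); f1 <- as.integer(frames[2])
  stopifnot(f0 >= 1L, f1 <= acq$n_frames, f0 < f1)
  nf <- f1 - f0 + 1L
  nr <- acq$fov_px[1]; nc <- acq$fov_px[2]
  dt <- acq$exposure_ms
  data <- array(0, c(nf, nr, nc))

  ev <- events
  if (nrow(ev) > 0) {
    # per-event brightness: log-normal, mean m, cv -> meanlog/sdlog
    m <- optics$mean_photons_per_frame
    cv <- optics$brightness_cv
    sdl <- sqrt(log(1 + cv^2))
    b <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "brightness"),
                   stats::rlnorm(nrow(ev), log(m) - sdl^2 / 2, sdl))
    ev$photons_per_frame_mean <- ifelse(is.na(ev$photons_per_frame_mean), b,
                                        ev$photons_per_frame_mean)
    rad <- ceiling(4 * psf_px) + 1L
    t0 <- ev$t_on_ms
    t1 <- ev$t_on_ms + ev$dwell_ms
    fa <- pmax(floor(t0 / dt) + 1L, f0)
    fb <- pmin(floor((t1 - 1e-12) / dt) + 1L, f1)
    keep <- which(fb >= fa)
    for (i in keep) {
      fr <- fa[i]:fb[i]
      # fractional temporal overlap of the event with each frame
      w <- (pmin(t1[i], fr * dt) - pmax(t0[i], (fr - 1) * dt)) / dt
      # site position in pixel-index coordinates (pixel center = integer)
      cx <- ev$x_nm[i] / acq$pixel_size_nm - 0.5
      cy <- ev$y_nm[i] / acq$pixel_size_nm - 0.5
      r0 <- max(0L, floor(cy) - rad); r1 <- min(nr - 1L, ceiling(cy) + rad)
      c0 <- max(0L, floor(cx) - rad); c1 <- min(nc - 1L, ceiling(cx) + rad)
      if (r0 > r1 || c0 > c1) next
      patch <- outer(pixel_gauss_1d(r0:r1, cy, psf_px),
                     pixel_gauss_1d(c0:c1, cx, psf_px))
      fi <- fr - f0 + 1L
      data[fi, (r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)] <-
        data[fi, (r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L), drop = FALSE] +
        outer(w * ev$photons_per_frame_mean[i], patch)
    }
  }

  bg <- optics$background_photons_per_pixel_per_frame
  if (noise) {
    noise_seed <- if (is.null(seed)) NULL else
      derive_seed(seed, paste0("noise", f0, "_", f1))
    data <- with_seed(noise_seed, {
      x <- array(as.numeric(stats::rpois(length(data), data + bg)), dim(data))
      if (optics$read_noise_e > 0)
        x <- x + array(stats::rnorm(length(x), 0, optics$read_noise_e), dim(x))
      pmax(x, 0)
    })
  } else {
    data <- data + bg
  }
  movie <- tab_movie(data, acq$pixel_size_nm, dt, is_photons = TRUE)
  structure(list(movie = movie,
                 truth = list(events = ev, optics = optics, acq = acq,
                              seed = seed, frames = c(f0, f1))),
            class = "tab_sim")
}

#' @export
print.tab_sim <- function(x, ...) {
  cat("<tab_sim> simulated movie with ground truth\n")
  print(x$movie)
  cat(sprintf("  %d binding events\n", nrow(x$truth$events)))
  invisible(x)
}

#' Simulate a single stationary blinking emitter (telegraph process)
#'
#' The emitter switches between on and off states as a two-state Markov
#' chain with stationary on-probability `p_on` and mean on-duration
#' `mean_on_frames`; when on it emits `photons_per_frame` through an
#' integrated Gaussian PSF. This is the standard scenario for measuring the
#' sqrt(2) resolution enhancement of second-order fluctuation imaging.
#'
#' @param n_frames number of frames.
#' @param fov_px `c(rows, cols)`.
#' @param position_px emitter position `c(row, col)` in 0-based pixel-index
#'   coordinates (integer value = pixel center); subpixel values allowed.
#' @param p_on stationary on-state probability.
#' @param mean_on_frames mean on-run length in frames.
#' @param psf_sigma_px PSF sigma in pixels.
#' @param photons_per_frame emitted photons per frame while on.
#' @param background_photons background level per pixel per frame.
#' @param pixel_size_nm,frame_time_ms metadata for the returned movie.
#' @param noise apply Poisson noise (default `TRUE`).
#' @param seed RNG seed.
#' @return A list: `movie` (a [tab_movie()]), `states` (0/1 per frame).
#' @export
simulate_blinking_emitter <- function(n_frames, fov_px = c(64L, 64L),
                                      position_px = (fov_px - 1) / 2 + 0.3,
                                      p_on = 0.3, mean_on_frames = 3,
                                      psf_sigma_px = 1.3,
                                      photons_per_frame = 1000,
                                      background_photons = 1,
                                      pixel_size_nm = 92,
                                      frame_time_ms = 30,
                                      noise = TRUE, seed = NULL) {
  k_off <- 1 / mean_on_frames
  k_on <- k_off * p_on / (1 - p_on)
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "telegraph"), {
    s <- integer(n_frames)
    s[1] <- stats::rbinom(1, 1, p_on)
    u <- stats::runif(n_frames)
    for (t in 2:n_frames)
      s[t] <- if (s[t - 1] == 1L) as.integer(u[t] >= k_off)
              else as.integer(u[t] < k_on)
    nr <- fov_px[1]; nc <- fov_px[2]
    patch <- outer(pixel_gauss_1d(0:(nr - 1L), position_px[1], psf_sigma_px),
                   pixel_gauss_1d(0:(nc - 1L), position_px[2], psf_sigma_px))
    lam <- outer(s * photons_per_frame, patch) + background_photons
    data <- if (noise)
      array(as.numeric(stats::rpois(length(lam), lam)), dim(lam)) else lam
    list(movie = tab_movie(data, pixel_size_nm, frame_time_ms, TRUE),
         states = s)
  })
}
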