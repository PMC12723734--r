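# Shared fixture builders; everything is generated in code at test time.

# Bind 3-D arrays along the first (frame) dimension.
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], 1L)), d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

# Wrap a data frame as a loc_table with metadata.
as_loc_table <- function(df, pixel_size_nm = 92, frame_time_ms = 30,
                         fov_px = c(64L, 64L)) {
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("loc_table", "data.frame"),
            pixel_size_nm = pixel_size_nm, frame_time_ms = frame_time_ms,
            fov_px = fov_px)
}

# Localizations scattered along a gently curved fibril with Gaussian
# localization error; emulates a PAINT table without running detection.
fibril_loc_table <- function(n, seed, loc_sd_nm = 15, fov_px = c(64L, 64L),
                             pixel_size_nm = 92) {
  set.seed(seed)
  t <- runif(n)
  x <- 1000 + t * 4000
  y <- 2500 + 300 * sin(t * 6)
  as_loc_table(data.frame(
    frame = sample.int(5000, n, replace = TRUE),
    x_nm = x + rnorm(n, 0, loc_sd_nm),
    y_nm = y + rnorm(n, 0, loc_sd_nm),
    photons = 690, sigma_nm = 120, residual = 0.1, fit_ok = TRUE),
    pixel_size_nm = pixel_size_nm, fov_px = fov_px)
}

# A single-site fibril field at a given position (for controlled kinetics).
single_site_field <- function(x_nm, y_nm, fov_nm) {
  structure(list(segments = list(),
                 sites = matrix(c(x_nm, y_nm), 1, 2,
                                dimnames = list(NULL, c("x_nm", "y_nm"))),
                 site_density_per_nm = 1, fov_nm = fov_nm),
            class = "fibril_field")
}

# An event list with explicit rows (class tagged).
as_event_list <- function(df) {
  df <- df[order(df$t_on_ms), , drop = FALSE]
  class(df) <- c("event_list", "data.frame")
  df
}

# One emitter placed at a pixel center plus an offset, on for an exact
# frame range; noise-free by default.
render_single_emitter <- function(offset_nm = c(17, -23), fov_px = 21L,
                                  n_frames = 12L, frames_on = 3:10,
                                  photons = 690, pixel_size_nm = 92,
                                  frame_time_ms = 30, noise = FALSE,
                                  background = 0, seed = 1) {
  ctr <- (fov_px - 1) / 2
  x <- (ctr + 0.5) * pixel_size_nm + offset_nm[1]
  y <- (ctr + 0.5) * pixel_size_nm + offset_nm[2]
  ev <- as_event_list(data.frame(
    site = 1L, x_nm = x, y_nm = y,
    t_on_ms = (min(frames_on) - 1) * frame_time_ms,
    dwell_ms = length(frames_on) * frame_time_ms,
    component = 1L, photons_per_frame_mean = photons))
  acq <- acquisition_config(frame_time_ms, pixel_size_nm, n_frames,
                            fov_px = c(fov_px, fov_px))
  optics <- optics_model(130, photons, 0, background, 0)
  list(sim = render_movie(ev, optics, acq, seed = seed, noise = noise),
       truth_x = x, truth_y = y)
}
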