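#' Pipeline configuration
#'
#' Collects scenario and stage parameters for an end-to-end run
#' (simulate -> PAINT / SOFI / iFCS / FRC). Stage parameter defaults follow
#' standard practice for transient-binding data: LoG sigma 1.5 px,
#' detection threshold 3 frame SDs, 5 nm histogram bins, 25 nm rendering
#' kernel, 6 movie segments, SNR gate 10, FRC threshold 1/7. A run's
#' config + seed fully determine its outputs.
#'
#' @param scenario either a list of simulation parameters (see
#'   [simulate_scenario()]) or a list `list(movie = "path.tif")` naming an
#'   input movie.
#' @param run_paint,run_sofi,run_ifcs,run_frc stage toggles.
#' @param log_sigma_px,threshold_k,psf_sigma_px PAINT detection parameters.
#' @param bin_nm,kernel_sigma_nm reconstruction parameters.
#' @param sofi_mode `"first_lag"` or `"sum_to_half_decay"`.
#' @param n_segments,snr_gate,acf_max_lag iFCS parameters.
#' @param frc_threshold FRC threshold.
#' @param seed master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = list(), run_paint = TRUE,
                            run_sofi = TRUE, run_ifcs = TRUE,
                            run_frc = TRUE, log_sigma_px = 1.5,
                            threshold_k = 3, psf_sigma_px = 1.3,
                            bin_nm = 5, kernel_sigma_nm = 25,
                            sofi_mode = "first_lag", n_segments = 6,
                            snr_gate = 10, acf_max_lag = NULL,
                            frc_threshold = 1 / 7, seed = 1) {
  structure(list(scenario = scenario, run_paint = run_paint,
                 run_sofi = run_sofi, run_ifcs = run_ifcs,
                 run_frc = run_frc, log_sigma_px = log_sigma_px,
                 threshold_k = threshold_k, psf_sigma_px = psf_sigma_px,
                 bin_nm = bin_nm, kernel_sigma_nm = kernel_sigma_nm,
                 sofi_mode = sofi_mode, n_segments = n_segments,
                 snr_gate = snr_gate, acf_max_lag = acf_max_lag,
                 frc_threshold = frc_threshold, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Simulate a transient-binding scenario
#'
#' Builds the fibril field, samples binding events and renders the movie
#' for a scenario parameter list. The defaults are the PAINT/SOFI regime:
#' 30 ms frames at 92 nm pixels with a nanomolar-dye arrival rate low
#' enough for single-molecule sparsity. Recognized elements (defaults):
#' `fov_px` (64), `pixel_size_nm` (92), `frame_time_ms` (30), `n_frames`
#' (2000), `n_fibrils` (3), `site_density_per_nm` (0.2),
#' `arrival_rate_per_site_per_s` (0.03), `tau_fast_ms` (23), `tau_slow_ms`
#' (482), `f_fast` (0.95), `psf_sigma_nm` (130), `mean_photons_per_frame`
#' (690), `brightness_cv` (0.55), `background` (2), `read_noise_e` (0).
#'
#' @param scenario named list of overrides.
#' @param seed master seed.
#' @param frames optional frame range passed to [render_movie()].
#' @return A `tab_sim` (movie + ground truth).
#' @export
simulate_scenario <- function(scenario = list(), seed = 1, frames = NULL) {
  p <- utils::modifyList(list(
    fov_px = 64L, pixel_size_nm = 92, frame_time_ms = 30, n_frames = 2000L,
    n_fibrils = 3L, site_density_per_nm = 0.2,
    arrival_rate_per_site_per_s = 0.03, tau_fast_ms = 23, tau_slow_ms = 482,
    f_fast = 0.95, psf_sigma_nm = 130, mean_photons_per_frame = 690,
    brightness_cv = 0.55, background = 2, read_noise_e = 0), scenario)
  fov_px <- rep_len(p$fov_px, 2L)
  fov_nm <- fov_px * p$pixel_size_nm
  field <- fibril_field(fov_nm, p$n_fibrils, p$site_density_per_nm,
                        seed = seed)
  kin <- kinetics_model(p$arrival_rate_per_site_per_s, p$tau_fast_ms,
                        p$tau_slow_ms, p$f_fast)
  ev <- simulate_binding_events(field, kin, p$n_frames * p$frame_time_ms,
                                seed = seed)
  optics <- optics_model(p$psf_sigma_nm, p$mean_photons_per_frame,
                         p$brightness_cv, p$background, p$read_noise_e)
  acq <- acquisition_config(p$frame_time_ms, p$pixel_size_nm, p$n_frames,
                            fov_px = fov_px)
  sim <- render_movie(ev, optics, acq, seed = seed, frames = frames)
  sim$truth$field <- field
  sim$truth$kinetics <- kin
  sim
}

#' Run the end-to-end pipeline
#'
#' Simulates (or reads) a movie, then runs the enabled stages and writes
#' all artifacts into `out_dir`: localization CSV, PAINT and SOFI TIFFs,
#' averaged-ACF CSV, parameter-map CSV, FRC curve CSV, and a
#' machine-readable run manifest (config, seed, package version, per-stage
#' timings and filter counts).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and artifact
#'   paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("tabsr")),
                   stages = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(value = val, elapsed_s = proc.time()[["elapsed"]] - t0)
  }
  res <- list(out_dir = out_dir)

  sim <- NULL
  if (!is.null(config$scenario$movie)) {
    movie <- read_movie(config$scenario$movie)
  } else {
    st <- t_stage(simulate_scenario(config$scenario, seed = config$seed))
    sim <- st$value
    movie <- sim$movie
    manifest$stages$simulate <- list(elapsed_s = st$elapsed_s,
                                     n_events = nrow(sim$truth$events))
    ev_path <- file.path(out_dir, "events.csv")
    utils::write.csv(sim$truth$events, ev_path, row.names = FALSE)
    res$events_csv <- ev_path
  }
  res$movie <- movie

  locs <- NULL
  if (isTRUE(config$run_paint)) {
    st <- t_stage({
      l <- localize_movie(movie, sigma_filter_px = config$log_sigma_px,
                          k = config$threshold_k,
                          psf_sigma_px = config$psf_sigma_px)
      filter_localizations(l)
    })
    locs <- st$value
    manifest$stages$paint <- list(elapsed_s = st$elapsed_s,
                                  counts = as.list(attr(locs, "counts") %||%
                                                     attr(locs, "filtered")),
                                  n_localizations = nrow(locs))
    res$localizations <- locs
    res$localizations_csv <- file.path(out_dir, "localizations.csv")
    write_localizations(locs, res$localizations_csv)
    if (nrow(locs) > 0) {
      rec <- reconstruct(locs, bin_nm = config$bin_nm,
                         kernel_sigma_nm = config$kernel_sigma_nm)
      res$paint_image <- rec
      res$paint_tif <- file.path(out_dir, "paint.tif")
      write_image(unclass(rec), res$paint_tif)
    }
  }

  if (isTRUE(config$run_sofi)) {
    st <- t_stage(sofi_image(movie, mode = config$sofi_mode))
    res$sofi <- st$value
    manifest$stages$sofi <- list(elapsed_s = st$elapsed_s,
                                 taus_used = st$value$taus_used)
    res$sofi_tif <- file.path(out_dir, "sofi.tif")
    write_image(res$sofi, res$sofi_tif)
  }

  if (isTRUE(config$run_ifcs)) {
    st <- t_stage({
      segs <- split_segments(movie, config$n_segments)
      lags <- acf_lag_grid(n_frames(segs[[1]]),
                           max_lag = config$acf_max_lag %||%
                             (n_frames(segs[[1]]) %/% 3L))
      rec <- average_segments(lapply(segs, pixel_acf, lags = lags))
      fits <- fit_acf_pixels(rec, snr_gate = config$snr_gate)
      list(record = rec, fits = fits, maps = build_maps(fits))
    })
    res$ifcs <- st$value
    manifest$stages$ifcs <- list(
      elapsed_s = st$elapsed_s,
      n_gated_pixels = nrow(st$value$fits),
      n_valid = sum(st$value$maps$valid))
    res$maps_csv <- file.path(out_dir, "parameter_maps.csv")
    utils::write.csv(as.data.frame(st$value$fits), res$maps_csv,
                     row.names = FALSE)
    acfd <- st$value$record
    res$acf_csv <- file.path(out_dir, "acf_mean.csv")
    utils::write.csv(data.frame(lag_ms = acfd$lags_ms,
                                G = apply(acfd$G, 3, mean, na.rm = TRUE)),
                     res$acf_csv, row.names = FALSE)
  }

  if (isTRUE(config$run_frc) && !is.null(locs) && nrow(locs) >= 2L) {
    st <- t_stage(frc_resolution(locs, bin_nm = config$bin_nm,
                                 threshold = config$frc_threshold,
                                 seed = config$seed))
    res$frc <- st$value
    manifest$stages$frc <- list(elapsed_s = st$elapsed_s,
                                resolution_nm = st$value$resolution_nm)
    res$frc_csv <- file.path(out_dir, "frc.csv")
    utils::write.csv(data.frame(
      freq_per_nm = st$value$curve$spatial_freq_per_nm,
      frc = st$value$curve$frc), res$frc_csv, row.names = FALSE)
  }

  manifest$config_hash <- sum(utf8ToInt(paste(
    utils::capture.output(utils::str(unclass(config))), collapse = "")))
  res$manifest_json <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, res$manifest_json, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(res)
}

#' Validate the artifacts of a pipeline run
#'
#' Re-checks run invariants from the written artifacts: manifest present
#' and parseable, reconstruction mass ~ localization count, parameter maps
#' within physical ranges, FRC values within `[-1, 1]`. Checks whose
#' artifacts were not produced are reported `"skipped"`, not failed.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return Data frame with columns `check`, `status`
#'   (`"pass"`/`"fail"`/`"skipped"`), `detail`.
#' @export
validate_run <- function(run_dir) {
  out <- list()
  add <- function(check, status, detail = "")
    out[[length(out) + 1L]] <<- data.frame(check = check, status = status,
                                           detail = detail)
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) {
    add("manifest", "fail", "manifest.json missing")
    return(do.call(rbind, out))
  }
  man <- tryCatch(jsonlite::read_json(man_path), error = function(e) NULL)
  add("manifest", if (is.null(man)) "fail" else "pass")

  loc_path <- file.path(run_dir, "localizations.csv")
  paint_path <- file.path(run_dir, "paint.tif")
  if (file.exists(loc_path) && file.exists(paint_path)) {
    locs <- read_localizations(loc_path)
    img <- tiff::readTIFF(paint_path)
    meta <- jsonlite::read_json(paste0(paint_path, ".json"))
    mass <- sum(img) * meta$float_scale
    rel <- abs(mass - nrow(locs)) / max(nrow(locs), 1)
    add("reconstruction_mass", if (rel < 0.01) "pass" else "fail",
        sprintf("mass %.2f vs %d localizations", mass, nrow(locs)))
  } else add("reconstruction_mass", "skipped")

  map_path <- file.path(run_dir, "parameter_maps.csv")
  if (file.exists(map_path)) {
    maps <- utils::read.csv(map_path)
    ok <- nrow(maps) == 0 ||
      (all(maps$tau_fast_ms > 0, na.rm = TRUE) &&
         all(maps$f_fast >= 0 & maps$f_fast <= 1, na.rm = TRUE))
    add("parameter_ranges", if (ok) "pass" else "fail")
    if ("n_segments" %in% names(man$config) &&
        (man$config$n_segments %||% 2) < 2) {
      add("acf_sem", "skipped", "single segment: SEM undefined")
    }
  } else add("parameter_ranges", "skipped")

  frc_path <- file.path(run_dir, "frc.csv")
  if (file.exists(frc_path)) {
    frc <- utils::read.csv(frc_path)
    ok <- all(frc$frc >= -1.000001 & frc$frc <= 1.000001, na.rm = TRUE)
    add("frc_range", if (ok) "pass" else "fail")
  } else add("frc_range", "skipped")

  do.call(rbind, out)
}
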