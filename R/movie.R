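#' Fluorescence movie container
#'
#' A `tab_movie` wraps a 3-D array of non-negative intensities
#' (frames x rows x cols) with the acquisition metadata needed by all
#' downstream stages: pixel size at the object plane and frame time.
#' Intensities are stored as doubles even for photon-resolved data so that
#' cumulant arithmetic cannot overflow.
#'
#' Pixel coordinates are 0-based; the physical center of pixel `(r, c)` is
#' at `((r + 0.5) * pixel_size_nm, (c + 0.5) * pixel_size_nm)`, with `y`
#' along rows and `x` along columns. All localizations are reported in nm
#' in this frame.
#'
#' @param data numeric 3-D array, frames x rows x cols, finite and >= 0,
#'   with at least 2 frames (temporal analysis needs at least one lag).
#' @param pixel_size_nm positive pixel size at the object plane (nm).
#' @param frame_time_ms positive frame (exposure) time in ms.
#' @param is_photons logical; `TRUE` if intensities are photons rather than
#'   raw camera counts.
#' @return An object of class `tab_movie`.
#' @seealso [read_movie()], [to_photons()], [split_segments()]
#' @export
tab_movie <- function(data, pixel_size_nm, frame_time_ms, is_photons = TRUE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (frames x rows x cols)")
  if (dim(data)[1] < 2L)
    stop("at least 2 frames required")
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite")
  if (any(data < 0))
    stop("intensities must be >= 0")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a positive scalar")
  if (!is.numeric(frame_time_ms) || length(frame_time_ms) != 1L ||
      frame_time_ms <= 0)
    stop("`frame_time_ms` must be a positive scalar")
  storage.mode(data) <- "double"
  structure(list(data = data,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 frame_time_ms = as.numeric(frame_time_ms),
                 is_photons = isTRUE(is_photons)),
            class = "tab_movie")
}

#' @export
print.tab_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tab_movie> %d frames of %d x %d px\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel %.1f nm, frame %.2f ms, %s\n", x$pixel_size_nm,
              x$frame_time_ms,
              if (x$is_photons) "photon units" else "camera counts"))
  cat(sprintf("  intensity range [%.3g, %.3g], duration %.2f s\n",
              min(x$data), max(x$data), d[1] * x$frame_time_ms / 1000))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie a [tab_movie()].
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$data)[1]

#' Acquisition configuration
#'
#' Bundles the camera/acquisition parameters of an imaging run. Two regimes
#' are typical for transient-binding movies: 30 ms frames at 92 nm pixels
#' (PAINT/SOFI) and 2.5 ms frames at 46 nm pixels (iFCS/SOFI).
#'
#' @param exposure_ms frame (exposure) time in ms.
#' @param pixel_size_nm pixel size at the object plane (nm).
#' @param n_frames number of frames (>= 2).
#' @param fov_px integer vector `c(rows, cols)` of the field of view.
#' @param photon_conversion_gain camera counts per photoelectron (> 0).
#' @param camera_offset camera count offset.
#' @param read_noise_e Gaussian read noise, rms electrons per pixel.
#' @return A list of class `tab_acq`.
#' @export
acquisition_config <- function(exposure_ms, pixel_size_nm, n_frames,
                               fov_px = c(64L, 64L),
                               photon_conversion_gain = 1,
                               camera_offset = 0, read_noise_e = 0) {
  if (photon_conversion_gain <= 0) stop("gain must be > 0")
  if (n_frames < 2L) stop("at least 2 frames required")
  structure(list(exposure_ms = exposure_ms, pixel_size_nm = pixel_size_nm,
                 n_frames = as.integer(n_frames),
                 fov_px = as.integer(fov_px),
                 photon_conversion_gain = photon_conversion_gain,
                 camera_offset = camera_offset,
                 read_noise_e = read_noise_e),
            class = "tab_acq")
}

meta_sidecar_path <- function(path) paste0(path, ".json")

#' Read a multi-frame TIFF movie
#'
#' Reads a multi-frame grayscale TIFF into a [tab_movie()]. If a JSON
#' metadata sidecar written by [write_movie()] is present
#' (`<path>.json`), pixel size, frame time, photon flag and float scale
#' are taken from it; explicit arguments override the sidecar.
#'
#' @param path path to a readable multi-frame grayscale TIFF.
#' @param pixel_size_nm,frame_time_ms acquisition metadata (required when no
#'   sidecar exists).
#' @param is_photons logical photon-unit flag (default `FALSE` for raw
#'   camera data without a sidecar).
#' @return A [tab_movie()]; intensities are returned unchanged (integer
#'   stacks round-trip bit-identically).
#' @export
read_movie <- function(path, pixel_size_nm = NULL, frame_time_ms = NULL,
                       is_photons = NULL) {
  if (!file.exists(path)) stop("cannot read movie: no such file: ", path)
  meta <- NULL
  sp <- meta_sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pixel_size_nm <- pixel_size_nm %||% meta$pixel_size_nm
  frame_time_ms <- frame_time_ms %||% meta$frame_time_ms
  is_photons <- is_photons %||% (meta$is_photons %||% FALSE)
  if (is.null(pixel_size_nm) || is.null(frame_time_ms))
    stop("pixel_size_nm and frame_time_ms must be supplied ",
         "(no metadata sidecar found)")
  frames <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) < 2L) stop("at least 2 frames required")
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("non-uniform frame shapes in TIFF stack")
  bits <- attr(frames[[1]], "bits.per.sample") %||% 16L
  d <- dim(frames[[1]])
  arr <- array(0, c(length(frames), d[1], d[2]))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  if (!is.null(meta$float_scale)) {
    arr <- pmax(arr, 0) * meta$float_scale
  } else if (bits < 32L) {
    # integer samples come back normalized to [0, 1]; restore exact counts
    arr <- round(arr * (2^bits - 1))
  }
  tab_movie(arr, pixel_size_nm, frame_time_ms, is_photons)
}

#' Write a movie as a multi-frame TIFF with a JSON metadata sidecar
#'
#' Integer-valued stacks within the uint16 range are written as 16-bit
#' integers (bit-identical round-trip). Other stacks are written as 32-bit
#' floats normalized by their maximum, with the scale factor recorded in the
#' sidecar so [read_movie()] restores physical units.
#'
#' @param movie a [tab_movie()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "tab_movie"))
  x <- movie$data
  integral <- max(x) <= 65535 && all(x == round(x))
  scale <- NULL
  if (integral) {
    frames <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ] / 65535)
    tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  } else {
    scale <- max(x, 1e-300)
    frames <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ] / scale)
    tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  }
  meta <- list(pixel_size_nm = movie$pixel_size_nm,
               frame_time_ms = movie$frame_time_ms,
               is_photons = movie$is_photons,
               n_frames = dim(x)[1])
  if (!is.null(scale)) meta$float_scale <- scale
  jsonlite::write_json(meta, meta_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a binary mask (single-frame 8-bit TIFF, 0 = background)
#'
#' @param path TIFF path.
#' @return Logical matrix, `TRUE` inside the mask.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(m)) m <- m[[1]]
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m != 0
}

#' Convert camera counts to photons
#'
#' Applies `max(0, (counts - offset) / gain)` elementwise and flags the
#' movie as photon-resolved.
#'
#' @param movie a [tab_movie()] in camera counts (`is_photons = FALSE`).
#' @param gain camera counts per photon (> 0).
#' @param offset camera count offset.
#' @return A photon-unit [tab_movie()].
#' @export
to_photons <- function(movie, gain, offset = 0) {
  stopifnot(inherits(movie, "tab_movie"))
  if (movie$is_photons) stop("movie is already in photon units")
  if (gain <= 0) stop("gain must be > 0")
  out <- movie
  x <- (movie$data - offset) / gain
  x[x < 0] <- 0
  out$data <- x
  out$is_photons <- TRUE
  out
}

#' Split a movie into contiguous temporal segments
#'
#' Segments are contiguous, non-overlapping and in temporal order. When the
#' frame count is not divisible by `n_segments` the trailing remainder
#' frames are dropped (floor division), keeping the per-segment statistics
#' identical.
#'
#' @param movie a [tab_movie()].
#' @param n_segments number of segments (>= 1, <= frames).
#' @return List of `n_segments` [tab_movie()] objects.
#' @export
split_segments <- function(movie, n_segments) {
  stopifnot(inherits(movie, "tab_movie"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("n_segments must be >= 1")
  nf <- n_frames(movie)
  if (n_segments > nf) stop("n_segments exceeds frame count")
  len <- nf %/% n_segments
  if (len < 2L) stop("segments would have fewer than 2 frames")
  lapply(seq_len(n_segments), function(i) {
    idx <- ((i - 1L) * len + 1L):(i * len)
    tab_movie(movie$data[idx, , , drop = FALSE], movie$pixel_size_nm,
              movie$frame_time_ms, movie$is_photons)
  })
}
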