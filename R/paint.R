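#' Laplacian-of-Gaussian spot filter
#'
#' Applies a negated Laplacian-of-Gaussian filter so that bright,
#' PSF-sized spots yield positive maxima. The filter is separable
#' (`gxx * g + g * gyy`), the second-derivative kernel has an exactly zero
#' discrete sum (a constant frame maps to an identically zero response) and
#' boundary handling is replicate padding.
#'
#' @param frame 2-D numeric array (one movie frame), finite values.
#' @param sigma_px filter scale in pixels (default 1.5, matched to a
#'   diffraction-limited spot).
#' @return Filtered frame, same shape.
#' @export
log_filter <- function(frame, sigma_px = 1.5) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  g <- gauss_kernel_1d(sigma_px)
  d2 <- gauss_d2_kernel_1d(sigma_px)
  -(conv2_sep(frame, d2, g) + conv2_sep(frame, g, d2))
}

#' Detect candidate molecules in a filtered frame
#'
#' Candidates are 8-connected local maxima of the filtered frame whose value
#' exceeds `k` times the standard deviation of the filtered frame's pixel
#' values (the std is computed on the whole frame, signal pixels included).
#' Maxima closer than `min_sep_px` are deduplicated, keeping the brighter
#' (one emitter, one candidate).
#'
#' @param filtered output of [log_filter()].
#' @param k threshold multiplier (default 3).
#' @param min_sep_px deduplication radius in pixels (default 3, i.e. twice
#'   the default filter sigma).
#' @return Data frame with 1-based integer `row`, `col` and filter `value`,
#'   ordered by decreasing value; zero rows when nothing is found.
#' @export
detect_candidates <- function(filtered, k = 3, min_sep_px = 3) {
  thr <- k * stats::sd(as.vector(filtered))
  nr <- nrow(filtered); nc <- ncol(filtered)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- filtered
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    is_max <- is_max & (filtered >= nb)
  }
  idx <- which(is_max & filtered > thr & is.finite(thr), arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  val <- filtered[idx]
  o <- order(val, decreasing = TRUE)
  idx <- idx[o, , drop = FALSE]; val <- val[o]
  keep <- logical(length(val))
  for (i in seq_along(val)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (idx[keep, 1] - idx[i, 1])^2 + (idx[keep, 2] - idx[i, 2])^2
    if (all(d2 > min_sep_px^2)) keep[i] <- TRUE
  }
  data.frame(row = as.integer(idx[keep, 1]), col = as.integer(idx[keep, 2]),
             value = val[keep])
}

# Integrated 2-D Gaussian model over unit pixels; cr/cc are 0-based local
# pixel indices.
gauss2d_model <- function(par, rows, cols) {
  # par: amplitude (total photons), y0 (row), x0 (col), sigma, offset
  par[1] * outer(pixel_gauss_1d(rows, par[2], par[4]),
                 pixel_gauss_1d(cols, par[3], par[4])) + par[5]
}

#' Fit a subimage with an integrated 2-D Gaussian PSF
#'
#' Nonlinear least squares (Levenberg-Marquardt) of total photons, subpixel
#' center, PSF sigma and a constant offset against a candidate subimage.
#' The Gaussian is integrated over pixel areas (error-function model), which
#' is the correct forward model when the pixel size is comparable to the
#' PSF sigma.
#'
#' @param subimage 2-D numeric array containing a single candidate.
#' @param init optional named list with starting values `photons`, `y0`,
#'   `x0` (0-based local pixel coordinates), `sigma`, `offset`.
#' @param sigma_bounds_px allowed sigma range (default `c(0.3, 10)`).
#' @return A list: `photons`, `y0_px`, `x0_px` (0-based local pixel
#'   coordinates, pixel center = integer), `sigma_px`, `offset`,
#'   `residual_norm` (rms residual / rms signal), `fit_ok`.
#' @export
fit_gaussian2d <- function(subimage, init = NULL,
                           sigma_bounds_px = c(0.3, 10)) {
  stopifnot(is.matrix(subimage))
  nr <- nrow(subimage); nc <- ncol(subimage)
  rows <- 0:(nr - 1L); cols <- 0:(nc - 1L)
  bad <- list(photons = NA_real_, y0_px = NA_real_, x0_px = NA_real_,
              sigma_px = NA_real_, offset = NA_real_,
              residual_norm = NA_real_, fit_ok = FALSE)
  if (max(subimage) - min(subimage) <= 0) return(bad)
  off0 <- min(subimage)
  pk <- which(subimage == max(subimage), arr.ind = TRUE)[1, ]
  amp0 <- max(sum(subimage - off0), 1e-6)
  s0 <- if (!is.null(init$sigma)) init$sigma else max(nr, nc) / 6
  par0 <- c(init$photons %||% amp0, init$y0 %||% (pk[1] - 1),
            init$x0 %||% (pk[2] - 1), s0, init$offset %||% off0)
  lower <- c(1e-9, -1, -1, sigma_bounds_px[1], -Inf)
  upper <- c(Inf, nr, nc, sigma_bounds_px[2], Inf)
  # non-convergence is reported through fit_ok, not as a warning
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par0,
      fn = function(p) as.vector(gauss2d_model(p, rows, cols) - subimage),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- fit$par
  ok <- fit$info %in% 1:4 && p[1] > 0 &&
    p[2] > -0.5 && p[2] < nr - 0.5 && p[3] > -0.5 && p[3] < nc - 0.5 &&
    p[4] > sigma_bounds_px[1] * 1.001 && p[4] < sigma_bounds_px[2] * 0.999
  rn <- sqrt(mean(fit$fvec^2)) / max(sqrt(mean((subimage - p[5])^2)), 1e-12)
  p <- unname(p)
  list(photons = p[1], y0_px = p[2], x0_px = p[3], sigma_px = p[4],
       offset = p[5], residual_norm = rn, fit_ok = ok)
}

#' Detect and localize single molecules in every frame
#'
#' For each frame: LoG filtering ([log_filter()]), thresholding at `k`
#' frame standard deviations ([detect_candidates()]), then subpixel fitting
#' of a square window around each candidate with [fit_gaussian2d()].
#' Candidates whose window is clipped by the frame edge are discarded (and
#' counted).
#'
#' @param movie a [tab_movie()].
#' @param sigma_filter_px LoG filter sigma (default 1.5 px).
#' @param k detection threshold in frame standard deviations (default 3).
#' @param psf_sigma_px expected PSF sigma used for the fit window and
#'   initial guess (default 1.3 px, ~120 nm at 92 nm pixels).
#' @param keep_failed keep rows for non-converged fits (default `FALSE`).
#' @return A data frame of class `loc_table`, sorted by frame, with columns
#'   `frame`, `x_nm`, `y_nm`, `photons`, `sigma_nm`, `residual`, `fit_ok`.
#'   Attributes: `pixel_size_nm`, `frame_time_ms`, `fov_px`, `counts`
#'   (candidates, clipped windows, failed fits).
#' @export
localize_movie <- function(movie, sigma_filter_px = 1.5, k = 3,
                           psf_sigma_px = 1.3, keep_failed = FALSE) {
  stopifnot(inherits(movie, "tab_movie"))
  half <- ceiling(3 * psf_sigma_px)
  px <- movie$pixel_size_nm
  nf <- n_frames(movie)
  nr <- dim(movie$data)[2]; nc <- dim(movie$data)[3]
  out <- vector("list", nf)
  n_cand <- 0L; n_clip <- 0L; n_fail <- 0L
  for (f in seq_len(nf)) {
    fr <- movie$data[f, , ]
    cand <- detect_candidates(log_filter(fr, sigma_filter_px), k = k,
                              min_sep_px = 2 * sigma_filter_px)
    if (nrow(cand) == 0L) next
    n_cand <- n_cand + nrow(cand)
    recs <- list()
    for (i in seq_len(nrow(cand))) {
      r <- cand$row[i]; c <- cand$col[i]
      if (r - half < 1L || r + half > nr || c - half < 1L || c + half > nc) {
        n_clip <- n_clip + 1L
        next
      }
      sub <- fr[(r - half):(r + half), (c - half):(c + half)]
      fit <- fit_gaussian2d(sub, init = list(sigma = psf_sigma_px))
      if (!fit$fit_ok) n_fail <- n_fail + 1L
      if (!fit$fit_ok && !keep_failed) next
      recs[[length(recs) + 1L]] <- data.frame(
        frame = f,
        x_nm = (c - half - 1L + fit$x0_px + 0.5) * px,
        y_nm = (r - half - 1L + fit$y0_px + 0.5) * px,
        photons = fit$photons,
        sigma_nm = fit$sigma_px * px,
        residual = fit$residual_norm,
        fit_ok = fit$fit_ok)
    }
    if (length(recs)) out[[f]] <- do.call(rbind, recs)
  }
  tab <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(tab))
    tab <- data.frame(frame = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), photons = numeric(0),
                      sigma_nm = numeric(0), residual = numeric(0),
                      fit_ok = logical(0))
  rownames(tab) <- NULL
  structure(tab, class = c("loc_table", "data.frame"),
            pixel_size_nm = px, frame_time_ms = movie$frame_time_ms,
            fov_px = c(nr, nc),
            counts = c(candidates = n_cand, clipped = n_clip,
                       failed = n_fail))
}

#' Filter a localization table on fit quality
#'
#' Keeps localizations with a converged fit, fitted PSF sigma inside
#' `sigma_bounds_nm`, photons above `min_photons` and normalized residual
#' below `max_residual`; removed counts are recorded in the `filtered`
#' attribute.
#'
#' @param table a `loc_table` from [localize_movie()].
#' @param sigma_bounds_nm allowed fitted sigma range in nm.
#' @param min_photons minimum photons per localization.
#' @param max_residual maximum normalized fit residual.
#' @return The filtered `loc_table` (attributes preserved).
#' @export
filter_localizations <- function(table, sigma_bounds_nm = c(50, 250),
                                 min_photons = 0, max_residual = Inf) {
  at <- attributes(table)
  if (nrow(table) == 0L) return(table)
  keep <- (is.na(table$fit_ok) | table$fit_ok) &
    table$sigma_nm >= sigma_bounds_nm[1] &
    table$sigma_nm <= sigma_bounds_nm[2] &
    table$photons >= min_photons &
    table$residual <= max_residual
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in setdiff(names(at), c("names", "row.names")))
    attr(out, a) <- at[[a]]
  attr(out, "filtered") <- c(removed = sum(!keep), kept = sum(keep))
  out
}

#' Write / read localization tables as CSV
#'
#' The CSV has a header `frame,x_nm,y_nm,photons,sigma_nm,residual,fit_ok`
#' plus a `# key=value` comment line carrying pixel size and frame time.
#'
#' @param table a `loc_table`.
#' @param path CSV path.
#' @return `path` (write) or a `loc_table` (read).
#' @export
write_localizations <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size_nm=%g frame_time_ms=%g fov_px=%dx%d",
                     attr(table, "pixel_size_nm") %||% NA,
                     attr(table, "frame_time_ms") %||% NA,
                     (attr(table, "fov_px") %||% c(NA, NA))[1],
                     (attr(table, "fov_px") %||% c(NA, NA))[2]), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  hdr <- readLines(path, n = 1L)
  tab <- utils::read.csv(path, comment.char = "#")
  num <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[0-9.eE+-]+"), hdr))
    if (length(m)) as.numeric(sub(paste0(key, "="), "", m)) else NA_real_
  }
  fov <- regmatches(hdr, regexpr("fov_px=[0-9]+x[0-9]+", hdr))
  structure(tab, class = c("loc_table", "data.frame"),
            pixel_size_nm = num("pixel_size_nm"),
            frame_time_ms = num("frame_time_ms"),
            fov_px = if (length(fov))
              as.integer(strsplit(sub("fov_px=", "", fov), "x")[[1]])
            else NULL)
}
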