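#' Pixel-wise second-order temporal cumulant
#'
#' For each pixel, `C2(tau) = mean_t[ dI(t) * dI(t + tau) ]` with
#' `dI = I - temporal mean`, where the mean is over the `n - tau` summed
#' products (FCS-style normalization). Uncorrelated noise averages to zero
#' while correlated blinking/binding fluctuations survive, and because the
#' fluctuations of distinct emitters are independent, their contributions
#' add with a squared PSF, giving the sqrt(2) resolution gain of
#' second-order fluctuation imaging.
#'
#' This quantity is exactly the numerator of the normalized pixel
#' autocorrelation used by iFCS ([pixel_acf()]), allowing the computation
#' to be shared.
#'
#' @param movie a [tab_movie()].
#' @param tau positive integer lag in frames, `tau < n_frames`.
#' @return Numeric matrix (rows x cols) of cumulant values (may be
#'   negative; negativity is estimator noise).
#' @export
second_order_cumulant <- function(movie, tau) {
  stopifnot(inherits(movie, "tab_movie"))
  tau <- as.integer(tau)
  nf <- n_frames(movie)
  if (tau < 1L || tau >= nf) stop("tau must satisfy 1 <= tau < n_frames")
  d <- dim(movie$data)
  M <- matrix(movie$data, nrow = nf)
  dI <- sweep(M, 2L, colMeans(M))
  C2 <- colSums(dI[1:(nf - tau), , drop = FALSE] *
                  dI[(1L + tau):nf, , drop = FALSE]) / (nf - tau)
  matrix(C2, d[2], d[3])
}

#' Choose the maximum SOFI lag from an averaged autocorrelation curve
#'
#' Returns the smallest lag at which the curve has decayed to 50% or less
#' of its reference amplitude (the value at the first supplied lag). For an
#' exponential decay with time constant `tau_d` supplied from lag 0 this is
#' `ceiling(tau_d * log(2))`. Falls back (with a warning) to the largest
#' available lag when the curve never decays below 50%, and to 1 when the
#' amplitude is not positive (e.g. white noise).
#'
#' @param g numeric autocorrelation values.
#' @param lags integer lags (same length, strictly increasing); supply from
#'   lag 0 for analytic curves, from lag 1 for empirical curves (whose
#'   lag-0 value carries the shot-noise variance).
#' @return Positive integer lag.
#' @export
select_tau_max <- function(g, lags = seq_along(g) - 1L) {
  stopifnot(length(g) == length(lags), !is.unsorted(lags))
  amp <- g[1]
  if (!is.finite(amp) || amp <= 0) {
    warning("non-positive ACF amplitude; tau_max = 1")
    return(1L)
  }
  pos <- lags > 0L
  below <- pos & (g <= amp / 2)
  if (!any(below)) {
    warning("ACF never decays below 50%; tau_max set to largest lag")
    return(as.integer(max(lags[pos])))
  }
  as.integer(min(lags[below]))
}

#' Second-order SOFI image
#'
#' Computes the pixel-wise second-order cumulant image, either from the
#' first nonzero lag only (`mode = "first_lag"`, appropriate for long-frame
#' acquisitions where the correlation decays within one frame) or summed
#' over lags `0 < tau <= tau_max` (`mode = "sum_to_half_decay"`), with
#' `tau_max` chosen as the ~50% decay point of the SNR-gated mean
#' autocorrelation over the field of view (avoiding noise from larger
#' lags). Negative values are retained in the raw output; clamping at 0 is
#' applied only when rendering ([as_image()]), since clamping before the
#' lag sum would bias it.
#'
#' @param movie a [tab_movie()].
#' @param mode `"first_lag"` or `"sum_to_half_decay"`.
#' @param max_lag largest lag examined when selecting `tau_max` (default
#'   `min(100, n_frames - 2)`).
#' @param snr_gate SNR gate for the pixels defining the mean ACF (default
#'   10; all pixels are used if none pass).
#' @return An object of class `sofi_image`: `values` (raw, unclamped
#'   matrix), `taus_used`, `pixel_size_nm`.
#' @export
sofi_image <- function(movie, mode = c("first_lag", "sum_to_half_decay"),
                       max_lag = NULL, snr_gate = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(movie, "tab_movie"))
  if (mode == "first_lag") {
    vals <- second_order_cumulant(movie, 1L)
    taus <- 1L
  } else {
    max_lag <- as.integer(max_lag %||% min(100L, n_frames(movie) - 2L))
    ac <- pixel_acf(movie, lags = seq_len(max_lag))
    snr <- estimate_snr_matrix(ac$G, ac$lags)
    gate <- is.finite(snr) & snr > snr_gate
    if (!any(gate)) gate <- !is.na(snr)
    mg <- apply(ac$G, 3L, function(m) mean(m[gate], na.rm = TRUE))
    tau_max <- select_tau_max(mg, lags = seq_len(max_lag))
    taus <- seq_len(tau_max)
    vals <- 0
    for (tau in taus) vals <- vals + second_order_cumulant(movie, tau)
  }
  structure(list(values = vals, taus_used = taus,
                 pixel_size_nm = movie$pixel_size_nm),
            class = "sofi_image")
}

#' @export
print.sofi_image <- function(x, ...) {
  cat(sprintf("<sofi_image> %d x %d px, lags %s, value range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values),
              paste(range(x$taus_used), collapse = ".."),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Render a SOFI image for display (negative values clamped at 0)
#' @param x a `sofi_image`.
#' @return Non-negative numeric matrix.
#' @export
as_image <- function(x) UseMethod("as_image")

#' @export
as_image.sofi_image <- function(x) pmax(x$values, 0)

#' @export
plot.sofi_image <- function(x, ...) {
  graphics::image(t(as_image(x))[, nrow(x$values):1],
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  axes = FALSE, ...)
  invisible(x)
}

#' Write a SOFI image (or any numeric image) as 32-bit float TIFF
#' @param img numeric matrix or `sofi_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (inherits(img, "sofi_image")) img <- img$values
  scale <- max(abs(img), 1e-300)
  tiff::writeTIFF(pmax(img, 0) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(float_scale = scale),
                       meta_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
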