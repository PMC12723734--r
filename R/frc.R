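#' Randomly split a localization table into two half-data sets
#'
#' Each localization is assigned independently with probability 1/2; the
#' two subsets are disjoint and exhaustive, and the split is reproducible
#' for a fixed seed.
#'
#' @param table a `loc_table` with at least 2 localizations.
#' @param seed RNG seed.
#' @return List of two `loc_table`s (attributes preserved).
#' @export
split_localizations <- function(table, seed = NULL) {
  if (nrow(table) < 2L) stop("need at least 2 localizations to split")
  pick <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "frc"),
                    stats::runif(nrow(table)) < 0.5)
  at <- attributes(table)
  halves <- list(table[pick, , drop = FALSE], table[!pick, , drop = FALSE])
  lapply(halves, function(h) {
    rownames(h) <- NULL
    for (a in setdiff(names(at), c("names", "row.names")))
      attr(h, a) <- at[[a]]
    h
  })
}

#' Fourier ring correlation between two images
#'
#' Computes, for concentric rings of spatial frequency of width one Fourier
#' pixel, the normalized cross-spectrum
#' `FRC(r_i) = Re sum_{r in ring i} F1(r) conj(F2(r)) /
#' sqrt(sum |F1|^2 sum |F2|^2)`. Input images should be the raw (unsmoothed)
#' localization histograms of the two half data sets; kernel smoothing
#' would bias the spectrum.
#'
#' @param img1,img2 real 2-D arrays of equal shape.
#' @param bin_nm physical bin size of the images (nm), setting the
#'   frequency axis in cycles/nm.
#' @return An object of class `frc_curve`: data frame fields
#'   `spatial_freq_per_nm` (ring centers), `frc`, `n_pixels` per ring, plus
#'   `ring_width_per_nm`. Rings with zero power are `NA` (flagged
#'   undefined).
#' @export
frc_curve <- function(img1, img2, bin_nm = 5) {
  stopifnot(identical(dim(img1), dim(img2)))
  nr <- nrow(img1); nc <- ncol(img1)
  F1 <- stats::fft(img1)
  F2 <- stats::fft(img2)
  # frequency coordinates in cycles/nm for an unshifted FFT
  fr <- ifelse(0:(nr - 1) <= nr %/% 2, 0:(nr - 1), 0:(nr - 1) - nr) / (nr * bin_nm)
  fc <- ifelse(0:(nc - 1) <= nc %/% 2, 0:(nc - 1), 0:(nc - 1) - nc) / (nc * bin_nm)
  rad <- sqrt(outer(fr^2, fc^2, "+"))
  step <- 1 / (min(nr, nc) * bin_nm)  # one Fourier pixel
  ring <- as.integer(round(rad / step))
  max_ring <- as.integer(floor(min(nr, nc) / 2))  # up to Nyquist
  keep <- ring <= max_ring
  num <- Re(F1 * Conj(F2))
  p1 <- Mod(F1)^2
  p2 <- Mod(F2)^2
  rn <- rowsum(num[keep], ring[keep])
  r1 <- rowsum(p1[keep], ring[keep])
  r2 <- rowsum(p2[keep], ring[keep])
  cnt <- rowsum(rep(1, sum(keep)), ring[keep])
  den <- sqrt(r1 * r2)
  frc <- ifelse(den > 0, rn / den, NA_real_)
  rings <- as.integer(rownames(rn))
  structure(list(spatial_freq_per_nm = rings * step,
                 frc = as.numeric(frc),
                 n_pixels = as.integer(cnt),
                 ring_width_per_nm = step, bin_nm = bin_nm),
            class = "frc_curve")
}

#' @export
print.frc_curve <- function(x, ...) {
  cat(sprintf("<frc_curve> %d rings to %.4g /nm (ring width %.4g /nm)\n",
              length(x$frc), max(x$spatial_freq_per_nm), x$ring_width_per_nm))
  invisible(x)
}

#' @export
plot.frc_curve <- function(x, threshold = 1 / 7, ...) {
  graphics::plot(x$spatial_freq_per_nm, x$frc, type = "l",
                 xlab = "spatial frequency (1/nm)", ylab = "FRC", ...)
  graphics::abline(h = threshold, lty = 2, col = "red")
  invisible(x)
}

#' Effective resolution from an FRC curve (1/7 threshold)
#'
#' Finds the lowest-frequency crossing of the FRC below `threshold`,
#' locates the critical frequency by linear interpolation between the
#' neighboring rings, and returns its inverse as the effective resolution.
#'
#' @param curve an `frc_curve` (or list with `spatial_freq_per_nm`, `frc`).
#' @param threshold FRC threshold (default 1/7).
#' @return List: `resolution_nm` (`NA` with a warning when the curve never
#'   crosses), `critical_freq_per_nm`, `threshold`.
#' @export
resolution_from_frc <- function(curve, threshold = 1 / 7) {
  f <- curve$spatial_freq_per_nm
  y <- curve$frc
  ok <- is.finite(y) & is.finite(f)
  f <- f[ok]; y <- y[ok]
  cross <- which(y < threshold & seq_along(y) > 1L)
  cross <- cross[vapply(cross, function(i) y[i - 1] >= threshold, TRUE)]
  if (!length(cross)) {
    warning("FRC never crosses the threshold; resolution undefined")
    return(list(resolution_nm = NA_real_, critical_freq_per_nm = NA_real_,
                threshold = threshold))
  }
  i <- cross[1]
  # linear interpolation of the FRC between rings i-1 and i
  fc <- f[i - 1] + (f[i] - f[i - 1]) * (y[i - 1] - threshold) /
    (y[i - 1] - y[i])
  list(resolution_nm = 1 / fc, critical_freq_per_nm = fc,
       threshold = threshold)
}

#' PAINT resolution estimate by half-data Fourier ring correlation
#'
#' Convenience wrapper: split the localization table, build the two raw
#' 5 nm histograms, compute the FRC curve and the 1/7-threshold resolution.
#'
#' @param table a `loc_table`.
#' @param bin_nm histogram bin size (default 5 nm).
#' @param threshold FRC threshold (default 1/7).
#' @param seed RNG seed for the random split.
#' @return List: `resolution_nm`, `curve` (an `frc_curve`), `halves`
#'   (localization counts).
#' @export
frc_resolution <- function(table, bin_nm = 5, threshold = 1 / 7,
                           seed = NULL) {
  halves <- split_localizations(table, seed = seed)
  h1 <- reconstruct(halves[[1]], bin_nm = bin_nm, smooth = FALSE)
  h2 <- reconstruct(halves[[2]], bin_nm = bin_nm, smooth = FALSE)
  curve <- frc_curve(unclass(h1), unclass(h2), bin_nm = bin_nm)
  res <- resolution_from_frc(curve, threshold = threshold)
  list(resolution_nm = res$resolution_nm, curve = curve,
       critical_freq_per_nm = res$critical_freq_per_nm,
       halves = c(nrow(halves[[1]]), nrow(halves[[2]])))
}
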