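#' Quasi-logarithmic lag grid
#'
#' Full linear lag grids waste effort at long lags where the ACF is smooth;
#' fits use a quasi-logarithmic grid (~`points_per_decade` lags per decade)
#' between 1 and `max_lag` frames.
#'
#' @param n_frames frames per segment.
#' @param points_per_decade grid density (default 16).
#' @param max_lag largest lag in frames (default `n_frames %/% 3`).
#' @return Increasing integer vector of lags.
#' @export
acf_lag_grid <- function(n_frames, points_per_decade = 16, max_lag = NULL) {
  max_lag <- as.integer(max_lag %||% (n_frames %/% 3L))
  stopifnot(max_lag >= 1L, max_lag < n_frames)
  lg <- 10^seq(0, log10(max_lag), by = 1 / points_per_decade)
  unique(pmin(as.integer(round(lg)), max_lag))
}

#' Per-pixel normalized temporal autocorrelation (iFCS)
#'
#' For each pixel, `G(tau) = mean_t[ dI(t) dI(t+tau) ] / mean_t[I]^2`. The
#' numerator is exactly the second-order cumulant of [second_order_cumulant()]
#' (the computation is shared between SOFI and iFCS). The default engine
#' evaluates all lags at once by FFT (zero-padded, so it is the exact
#' linear correlation, matching direct summation to ~1e-12 relative);
#' `engine = "direct"` calls [second_order_cumulant()] per lag.
#'
#' Pixels with zero temporal mean have an undefined G and are returned as
#' `NA` (flagged invalid).
#'
#' @param movie a [tab_movie()] (one segment).
#' @param lags increasing positive integer lags in frames, all `<`
#'   `n_frames`.
#' @param engine `"fft"` or `"direct"`.
#' @return A list of class `pixel_acf`: `G` (array rows x cols x n_lags),
#'   `lags` (frames), `lags_ms`, `mean_intensity` (matrix), `n_frames`.
#' @export
pixel_acf <- function(movie, lags, engine = c("fft", "direct")) {
  engine <- match.arg(engine)
  stopifnot(inherits(movie, "tab_movie"))
  lags <- as.integer(lags)
  nf <- n_frames(movie)
  if (any(lags < 1L) || any(lags >= nf)) stop("lags must be in [1, n_frames)")
  d <- dim(movie$data)
  nr <- d[2]; nc <- d[3]; np <- nr * nc
  M <- matrix(movie$data, nrow = nf)
  mu <- colMeans(M)
  G <- array(NA_real_, c(nr, nc, length(lags)))
  if (engine == "direct") {
    for (i in seq_along(lags)) {
      num <- second_order_cumulant(movie, lags[i])
      G[, , i] <- num / matrix(mu^2, nr, nc)
    }
  } else {
    m <- stats::nextn(nf + max(lags), 2)
    # block over pixels to bound memory
    block <- max(1L, min(np, as.integer(2^22 / m)))
    starts <- seq(1L, np, by = block)
    for (s in starts) {
      cols <- s:min(s + block - 1L, np)
      dI <- sweep(M[, cols, drop = FALSE], 2L, mu[cols])
      P <- matrix(0, m, length(cols))
      P[1:nf, ] <- dI
      Fp <- stats::mvfft(P)
      ac <- Re(stats::mvfft(Fp * Conj(Fp), inverse = TRUE)) / m
      for (i in seq_along(lags)) {
        num <- ac[lags[i] + 1L, ] / (nf - lags[i])
        gi <- num / mu[cols]^2
        arr <- array(NA_real_, c(length(cols)))
        arr[] <- gi
        tmp <- G[, , i]
        tmp[cols] <- arr
        G[, , i] <- tmp
      }
    }
  }
  G[!is.finite(G)] <- NA_real_
  zero_mean <- matrix(mu == 0, nr, nc)
  for (i in seq_along(lags)) {
    tmp <- G[, , i]
    tmp[zero_mean] <- NA_real_
    G[, , i] <- tmp
  }
  structure(list(G = G, lags = lags, lags_ms = lags * movie$frame_time_ms,
                 mean_intensity = matrix(mu, nr, nc), n_frames = nf),
            class = "pixel_acf")
}

#' Average per-segment autocorrelation functions
#'
#' Averages the per-pixel ACFs of two or more movie segments and quantifies
#' the uncertainty at each lag by the standard error of the mean across
#' segments. A single segment is accepted but its SEM is `NA` (flagged).
#'
#' @param acfs list of `pixel_acf` objects with identical lag grids.
#' @return A list of class `acf_record`: `G` (mean, rows x cols x lags),
#'   `sem`, `lags`, `lags_ms`, `n_segments`, `mean_intensity` (average over
#'   segments).
#' @export
average_segments <- function(acfs) {
  stopifnot(length(acfs) >= 1L,
            all(vapply(acfs, inherits, TRUE, "pixel_acf")))
  lags <- acfs[[1]]$lags
  for (a in acfs) stopifnot(identical(a$lags, lags))
  n <- length(acfs)
  stack <- lapply(acfs, `[[`, "G")
  Gm <- Reduce(`+`, stack) / n
  if (n >= 2L) {
    ss <- Reduce(`+`, lapply(stack, function(g) (g - Gm)^2))
    sem <- sqrt(ss / (n - 1L)) / sqrt(n)
  } else {
    sem <- array(NA_real_, dim(Gm))
  }
  mi <- Reduce(`+`, lapply(acfs, `[[`, "mean_intensity")) / n
  structure(list(G = Gm, sem = sem, lags = lags,
                 lags_ms = acfs[[1]]$lags_ms, n_segments = n,
                 mean_intensity = mi),
            class = "acf_record")
}

#' @export
print.acf_record <- function(x, ...) {
  cat(sprintf("<acf_record> %d x %d px, %d lags (%.3g-%.3g ms), %d segments\n",
              dim(x$G)[1], dim(x$G)[2], length(x$lags), min(x$lags_ms),
              max(x$lags_ms), x$n_segments))
  invisible(x)
}

# amplitude = mean of G over the first three supplied (nonzero) lags;
# SNR = amplitude / sd of G over the last five lags.
estimate_snr_matrix <- function(G, lags) {
  nl <- dim(G)[3]
  if (nl < 6L) stop("SNR estimation needs at least 6 lags")
  amp <- apply(G[, , 1:3, drop = FALSE], c(1, 2), mean)
  tail_sd <- apply(G[, , (nl - 4L):nl, drop = FALSE], c(1, 2), stats::sd)
  snr <- ifelse(amp <= 0 | is.na(amp), 0,
                ifelse(tail_sd == 0, Inf, amp / tail_sd))
  snr[is.na(tail_sd)] <- NA_real_
  snr
}

#' Signal-to-noise ratio of autocorrelation functions
#'
#' The ACF amplitude (mean of G over the first three nonzero lags of the
#' averaged curve, a pre-fit surrogate for G0) divided by the standard
#' deviation of the last five time lags. Non-positive amplitudes give
#' SNR 0; a zero tail standard deviation gives `Inf`.
#'
#' @param record an `acf_record` (per-pixel SNR matrix is returned) or a
#'   numeric G vector with `lags`.
#' @param lags lags for the vector method.
#' @return Numeric matrix (or scalar for a vector input).
#' @export
estimate_snr <- function(record, lags = NULL) {
  if (inherits(record, "acf_record") || inherits(record, "pixel_acf"))
    return(estimate_snr_matrix(record$G, record$lags))
  g <- as.numeric(record)
  if (length(g) < 6L) stop("SNR estimation needs at least 6 lags")
  amp <- mean(g[1:3])
  tail_sd <- stats::sd(g[(length(g) - 4L):length(g)])
  if (is.na(amp) || amp <= 0) return(0)
  if (tail_sd == 0) return(Inf)
  amp / tail_sd
}

#' Segment-wise per-pixel ACF of a long simulated acquisition
#'
#' Renders a long binding-event movie one segment at a time (so the full
#' stack never has to be held in memory), computes each segment's per-pixel
#' ACF on a common lag grid, and averages the segments. This is the
#' standard route for the high-temporal-resolution iFCS regime (2.5 ms
#' frames, 36,000 frames in six 15 s segments).
#'
#' @param events an `event_list` from [simulate_binding_events()].
#' @param optics an [optics_model()].
#' @param acq an [acquisition_config()] covering the full acquisition.
#' @param n_segments number of segments (default 6).
#' @param lags lag grid in frames (default [acf_lag_grid()] on a third of
#'   a segment).
#' @param seed RNG seed passed to [render_movie()].
#' @return An `acf_record` (see [average_segments()]).
#' @export
segmented_pixel_acf <- function(events, optics, acq, n_segments = 6,
                                lags = NULL, seed = NULL) {
  seglen <- acq$n_frames %/% n_segments
  lags <- lags %||% acf_lag_grid(seglen, max_lag = seglen %/% 3L)
  acfs <- lapply(seq_len(n_segments), function(i) {
    sim <- render_movie(events, optics, acq, seed = seed,
                        frames = c((i - 1L) * seglen + 1L, i * seglen))
    pixel_acf(sim$movie, lags)
  })
  average_segments(acfs)
}

#' Extract the averaged ACF of one pixel as a data frame
#'
#' @param record an `acf_record`.
#' @param row,col 1-based pixel indices.
#' @return Data frame with `lag_ms`, `G`, `sem`.
#' @export
acf_at_pixel <- function(record, row, col) {
  data.frame(lag_ms = record$lags_ms, G = record$G[row, col, ],
             sem = record$sem[row, col, ])
}
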