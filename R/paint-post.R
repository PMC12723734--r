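#' Reconstruct a super-resolved density map from localizations
#'
#' Builds a 2-D histogram of localization positions with `bin_nm` square
#' bins covering the field of view and convolves it with a 2-D Gaussian
#' kernel of standard deviation `kernel_sigma_nm`. The kernel is normalized
#' to unit mass, so the total image mass equals the number of localizations
#' up to kernel truncation at the image edge.
#'
#' @param table a non-empty `loc_table` (needs `pixel_size_nm` and `fov_px`
#'   attributes, or an explicit `fov_nm`).
#' @param bin_nm histogram bin size (default 5 nm).
#' @param kernel_sigma_nm rendering kernel sigma (default 25 nm, a
#'   conservative choice matching a 30-50 nm empirical resolution).
#' @param fov_nm optional `c(height, width)` in nm overriding the table
#'   metadata.
#' @param smooth set `FALSE` to return the raw histogram (used for Fourier
#'   ring correlation, where kernel smoothing would bias the spectrum).
#' @return Numeric matrix (rows = y bins, cols = x bins) with attributes
#'   `bin_nm` and `origin_nm`.
#' @export
reconstruct <- function(table, bin_nm = 5, kernel_sigma_nm = 25,
                        fov_nm = NULL, smooth = TRUE) {
  if (nrow(table) == 0L) stop("empty localization table")
  if (is.null(fov_nm)) {
    fov_px <- attr(table, "fov_px")
    px <- attr(table, "pixel_size_nm")
    if (is.null(fov_px) || is.null(px))
      stop("fov_nm required when the table lacks FOV metadata")
    fov_nm <- fov_px * px
  }
  nby <- ceiling(fov_nm[1] / bin_nm)
  nbx <- ceiling(fov_nm[2] / bin_nm)
  iy <- pmin(pmax(floor(table$y_nm / bin_nm), 0), nby - 1L) + 1L
  ix <- pmin(pmax(floor(table$x_nm / bin_nm), 0), nbx - 1L) + 1L
  h <- matrix(0, nby, nbx)
  cnt <- table(factor((ix - 1L) * nby + iy, levels = seq_len(nby * nbx)))
  h[] <- as.numeric(cnt)
  if (smooth && kernel_sigma_nm > 0) {
    sb <- kernel_sigma_nm / bin_nm
    kk <- gauss_kernel_1d(sb, radius = ceiling(5 * sb))
    h <- conv2_sep_zero(h, kk, kk)
  }
  structure(h, bin_nm = bin_nm, origin_nm = c(0, 0))
}

# Separable convolution with zero padding (no edge mass folding); used for
# density rendering where replicate padding would fabricate mass.
conv2_sep_zero <- function(img, kr, kc) {
  Kr <- conv_band_matrix_zero(nrow(img), kr)
  Kc <- conv_band_matrix_zero(ncol(img), kc)
  Kr %*% img %*% t(Kc)
}

conv_band_matrix_zero <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- seq_len(n)
    src <- idx + off
    valid <- src >= 1L & src <= n
    K[cbind(idx[valid], src[valid])] <- K[cbind(idx[valid], src[valid])] +
      kernel[j]
  }
  K
}

#' Link localizations across consecutive frames into on-time runs
#'
#' Greedy nearest-neighbor linking between consecutive frames within
#' `radius_nm`; no gap frames are allowed (a missed frame terminates the
#' run, deliberately reproducing linking interruptions caused by emitter
#' overlap). Run lengths in frames are histogrammed.
#'
#' @param table a `loc_table` sorted by frame.
#' @param radius_nm linking radius (default one pixel).
#' @return A list of class `ontime_dist`: `counts` (integer vector indexed
#'   by run length k = 1, 2, ...), `frame_time_ms`, `n_runs`.
#' @export
link_on_times <- function(table, radius_nm = attr(table, "pixel_size_nm")) {
  if (is.null(radius_nm)) stop("radius_nm required")
  ft <- attr(table, "frame_time_ms")
  if (nrow(table) == 0L)
    return(structure(list(counts = integer(0), frame_time_ms = ft,
                          n_runs = 0L), class = "ontime_dist"))
  stopifnot(!is.unsorted(table$frame))
  run_len <- integer(0)
  # active runs: positions + current lengths, from the previous frame
  prev_xy <- NULL; prev_len <- integer(0); prev_frame <- -1L
  frames <- unique(table$frame)
  for (f in frames) {
    cur <- table[table$frame == f, c("x_nm", "y_nm"), drop = FALSE]
    cur_len <- rep(1L, nrow(cur))
    if (!is.null(prev_xy) && f == prev_frame + 1L && nrow(prev_xy) > 0) {
      d <- outer(prev_xy$x_nm, cur$x_nm, "-")^2 +
        outer(prev_xy$y_nm, cur$y_nm, "-")^2
      linked_prev <- logical(nrow(prev_xy))
      repeat {
        m <- which.min(d)
        if (length(m) == 0L || !is.finite(d[m]) || d[m] > radius_nm^2) break
        i <- (m - 1L) %% nrow(d) + 1L
        j <- (m - 1L) %/% nrow(d) + 1L
        cur_len[j] <- prev_len[i] + 1L
        linked_prev[i] <- TRUE
        d[i, ] <- Inf; d[, j] <- Inf
      }
      run_len <- c(run_len, prev_len[!linked_prev])
    } else if (!is.null(prev_xy)) {
      run_len <- c(run_len, prev_len)
    }
    prev_xy <- cur; prev_len <- cur_len; prev_frame <- f
  }
  run_len <- c(run_len, prev_len)
  structure(list(counts = tabulate(run_len), frame_time_ms = ft,
                 n_runs = length(run_len)),
            class = "ontime_dist")
}

#' @export
print.ontime_dist <- function(x, ...) {
  cat(sprintf("<ontime_dist> %d runs, max length %d frames (%.1f ms/frame)\n",
              x$n_runs, length(x$counts), x$frame_time_ms))
  invisible(x)
}

#' Build an on-time distribution from raw run-length samples
#'
#' @param run_lengths integer vector of on-run lengths in frames.
#' @param frame_time_ms frame time.
#' @return An `ontime_dist`.
#' @export
ontime_dist <- function(run_lengths, frame_time_ms) {
  stopifnot(all(run_lengths >= 1))
  structure(list(counts = tabulate(as.integer(run_lengths)),
                 frame_time_ms = frame_time_ms,
                 n_runs = length(run_lengths)),
            class = "ontime_dist")
}

#' Fit exponential decay models to an on-time distribution
#'
#' Weighted least squares of run-length counts against a sum of
#' `n_components` exponential terms `A_i * exp(-k * dt / tau_i)` with
#' Poisson weights `1 / max(count, 1)`. Decay times are relabeled so
#' `tau` is increasing.
#'
#' @param dist an `ontime_dist`.
#' @param n_components 1 or 2.
#' @param drop_first_bin exclude the k = 1 bin (single-frame detections mix
#'   sub-frame events); default `FALSE`.
#' @return An object of class `tab_ontime_fit` with elements `tau_ms`,
#'   `amplitudes`, `reduced_chi2`, `n_components`, `converged`, `data`.
#' @export
fit_on_time_decay <- function(dist, n_components = 2,
                              drop_first_bin = FALSE) {
  stopifnot(inherits(dist, "ontime_dist"), n_components %in% 1:2)
  k <- seq_along(dist$counts)
  counts <- dist$counts
  if (drop_first_bin && length(k) > 1L) { k <- k[-1]; counts <- counts[-1] }
  occ <- counts > 0
  need <- if (n_components == 2) 5L else 3L
  if (sum(occ) < need)
    stop("too few occupied histogram bins (", sum(occ), ") for ",
         n_components, "-component fit")
  dt <- dist$frame_time_ms
  w <- 1 / pmax(counts, 1)
  model <- function(p) {
    # p: log amplitudes then log taus
    A <- exp(p[seq_len(n_components)])
    tau <- exp(p[n_components + seq_len(n_components)])
    rowSums(vapply(seq_len(n_components),
                   function(i) A[i] * exp(-k * dt / tau[i]),
                   numeric(length(k))))
  }
  # initial guess: split the empirical decay range
  tau0 <- -dt / log(max(min(sum(counts * k) / sum(counts), 10), 1.2)^-1)
  tau0 <- max(tau0, dt / 4)
  taus0 <- if (n_components == 2) c(tau0 / 3, tau0 * 3) else tau0
  A0 <- rep(max(counts), n_components)
  p0 <- log(c(A0, taus0))
  fit <- suppressWarnings(
    minpack.lm::nls.lm(p0, fn = function(p) sqrt(w) * (model(p) - counts),
                       control = minpack.lm::nls.lm.control(maxiter = 200)))
  conv <- fit$info %in% 1:4
  A <- exp(fit$par[seq_len(n_components)])
  tau <- exp(fit$par[n_components + seq_len(n_components)])
  o <- order(tau)
  A <- A[o]; tau <- tau[o]
  dof <- length(k) - 2 * n_components
  chi2 <- sum(fit$fvec^2) / max(dof, 1)
  structure(list(tau_ms = tau, amplitudes = A, reduced_chi2 = chi2,
                 n_components = n_components, converged = conv,
                 data = data.frame(k = k, count = counts),
                 frame_time_ms = dt),
            class = "tab_ontime_fit")
}

#' @export
print.tab_ontime_fit <- function(x, ...) {
  cat(sprintf("<tab_ontime_fit> %d-component exponential decay\n",
              x$n_components))
  for (i in seq_len(x$n_components))
    cat(sprintf("  tau_%d = %.1f ms (amplitude %.1f)\n", i, x$tau_ms[i],
                x$amplitudes[i]))
  cat(sprintf("  reduced chi-squared = %.3g%s\n", x$reduced_chi2,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.tab_ontime_fit <- function(object, ...) {
  stats::setNames(c(object$tau_ms, object$amplitudes),
                  c(paste0("tau", seq_len(object$n_components), "_ms"),
                    paste0("A", seq_len(object$n_components))))
}

#' Measure the Gaussian width of a ridge profile
#'
#' Samples intensity profiles perpendicular to a line (bilinear
#' interpolation), averages them along the line and fits a 1-D Gaussian
#' plus offset; used to quantify apparent fibril widths in reconstruction
#' and temporal-average images.
#'
#' @param image 2-D numeric array.
#' @param p1,p2 line endpoints `c(row, col)` in 0-based pixel coordinates.
#' @param half_width_px profile half-width perpendicular to the line.
#' @param pixel_size_nm physical pixel size of `image` (nm).
#' @param n_samples number of profile samples along the line.
#' @return List with `sigma_nm`, `sigma_px`, `center_px`, `profile`
#'   (data frame offset_px/intensity).
#' @export
measure_profile_width <- function(image, p1, p2, half_width_px,
                                  pixel_size_nm, n_samples = 50) {
  stopifnot(is.matrix(image))
  v <- c(p2[1] - p1[1], p2[2] - p1[2])
  L <- sqrt(sum(v^2))
  if (L <= 0) stop("degenerate line")
  u <- v / L
  perp <- c(-u[2], u[1])
  offs <- seq(-half_width_px, half_width_px, by = 0.5)
  ts <- seq(0, 1, length.out = n_samples)
  prof <- vapply(offs, function(o) {
    pts_r <- p1[1] + ts * v[1] + o * perp[1]
    pts_c <- p1[2] + ts * v[2] + o * perp[2]
    mean(bilinear_sample(image, pts_r, pts_c))
  }, 0)
  if (stats::sd(prof) == 0) stop("flat profile: no ridge to fit")
  fit <- minpack.lm::nls.lm(
    c(max(prof) - min(prof), 0, half_width_px / 3, min(prof)),
    fn = function(p) p[1] * exp(-(offs - p[2])^2 / (2 * p[3]^2)) + p[4] - prof,
    lower = c(0, -half_width_px, 0.05, -Inf),
    upper = c(Inf, half_width_px, 4 * half_width_px, Inf))
  if (!(fit$info %in% 1:4)) stop("profile fit did not converge")
  s <- abs(fit$par[3])
  list(sigma_nm = s * pixel_size_nm, sigma_px = s, center_px = fit$par[2],
       profile = data.frame(offset_px = offs, intensity = prof))
}

bilinear_sample <- function(image, r, c) {
  # 0-based continuous pixel-index coordinates, clamped to the image
  nr <- nrow(image); nc <- ncol(image)
  r <- pmin(pmax(r, 0), nr - 1); c <- pmin(pmax(c, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c0 + 2)
  image[i00] * (1 - fr) * (1 - fc) + image[i01] * (1 - fr) * fc +
    image[i10] * fr * (1 - fc) + image[i11] * fr * fc
}
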