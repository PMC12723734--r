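# Two-component binding model:
#   G(tau) = G0 * (1 - ff + ff*exp(-tau/tf)) * (1 - fs + fs*exp(-tau/ts)) + Ginf
# One-component model: ff = 1, fs = 0.
acf_model_two <- function(lag_ms, G0, f_fast, tau_fast, f_slow, tau_slow,
                          g_inf) {
  G0 * (1 - f_fast + f_fast * exp(-lag_ms / tau_fast)) *
    (1 - f_slow + f_slow * exp(-lag_ms / tau_slow)) + g_inf
}

acf_model_one <- function(lag_ms, G0, tau, g_inf) {
  G0 * exp(-lag_ms / tau) + g_inf
}

#' Fit a binding model to an averaged autocorrelation function
#'
#' Weighted least squares (Levenberg-Marquardt with box bounds) of the
#' two-component binding model
#' \deqn{G(\tau) = G_0 (1 - f_f + f_f e^{-\tau/\tau_f})
#'                    (1 - f_s + f_s e^{-\tau/\tau_s}) + G_\infty}
#' or its one-component reduction (`f_fast = 1`, `f_slow = 0`) to a single
#' pixel's averaged ACF. Weights are `1/SEM^2` with SEM values below
#' `1e-6 * max(|G|)` floored to avoid infinite weights; unit weights are
#' used when no SEM is available. The reduced chi-squared is
#' `sum(weighted residuals^2) / (n_lags - n_params)`. Relaxation times are
#' relabeled after the fit so `tau_fast <= tau_slow`.
#'
#' Initialization: `G0` from the early-lag amplitude, relaxation times from
#' the lags where the ACF crosses 70% and 30% of the amplitude, weight
#' fractions 0.5; up to 3 jittered restarts on non-convergence.
#'
#' @param lag_ms lags in ms (or an `acf_record`; then `row`/`col` select
#'   the pixel).
#' @param g ACF values.
#' @param sem per-lag standard errors (optional).
#' @param model `"two_component"` or `"one_component"`.
#' @param tau_bounds_ms allowed relaxation-time range; defaults to
#'   `c(min(lag_ms), 10 * max(lag_ms))`.
#' @param g_inf_fixed optional numeric: pin the offset `G_inf` at this
#'   value instead of fitting it. With a free offset the product model has
#'   a near-degenerate direction (a small shift of the relaxation times
#'   can trade amplitude between the weights and the offset at numerically
#'   negligible cost), so amplitude/weight parameters are only sharply
#'   identified when the offset is known — e.g. zero for a fully decaying
#'   synthetic curve.
#' @param row,col pixel indices when an `acf_record` is supplied.
#' @return An object of class `tab_acf_fit`: coefficients `G0`,
#'   `tau_fast_ms`, `tau_slow_ms`, `f_fast`, `f_slow`, `g_inf`, plus
#'   `reduced_chi2`, `snr`, `converged`, `model`, `data`.
#' @seealso [predict.tab_acf_fit()], [fit_acf_pixels()]
#' @export
fit_acf <- function(lag_ms, g = NULL, sem = NULL,
                    model = c("two_component", "one_component"),
                    tau_bounds_ms = NULL, g_inf_fixed = NULL,
                    row = NULL, col = NULL) {
  model <- match.arg(model)
  if (inherits(lag_ms, "acf_record")) {
    rec <- lag_ms
    stopifnot(!is.null(row), !is.null(col))
    g <- rec$G[row, col, ]
    sem <- rec$sem[row, col, ]
    lag_ms <- rec$lags_ms
  }
  ok <- is.finite(lag_ms) & is.finite(g)
  lag_ms <- lag_ms[ok]; g <- g[ok]
  if (!is.null(sem)) sem <- sem[ok]
  n_par <- (if (model == "two_component") 6L else 3L) -
    (!is.null(g_inf_fixed))
  if (length(lag_ms) < n_par + 2L)
    stop("need at least ", n_par + 2L, " lags to fit the ", model, " model")
  if (!is.null(sem) && all(is.finite(sem))) {
    floor_ <- 1e-6 * max(abs(g), 1e-300)
    w <- 1 / pmax(sem, floor_)^2
  } else w <- rep(1, length(g))
  sw <- sqrt(w)
  snr <- if (length(g) >= 6L) estimate_snr(g) else NA_real_

  amp <- mean(g[1:min(3L, length(g))])
  if (!is.finite(amp) || amp <= 0) amp <- max(g, 1e-6)
  g_inf0 <- mean(g[max(1L, length(g) - 4L):length(g)])
  cross <- function(frac) {
    i <- which(g - g_inf0 <= frac * (amp - g_inf0))[1]
    if (is.na(i)) max(lag_ms) / 3 else lag_ms[i]
  }
  tb <- tau_bounds_ms %||% c(min(lag_ms), 10 * max(lag_ms))
  clamp <- function(x) pmin(pmax(x, tb[1] * 1.01), tb[2] * 0.99)
  t70 <- clamp(cross(0.7)); t30 <- clamp(cross(0.3))
  if (t30 <= t70) t30 <- clamp(t70 * 5)

  fixed_off <- !is.null(g_inf_fixed)
  off <- function(p) if (fixed_off) g_inf_fixed else p[length(p)]
  resid_fn <- if (model == "two_component") {
    function(p) sw * (acf_model_two(lag_ms, p[1], p[2], p[3], p[4], p[5],
                                    off(p)) - g)
  } else {
    function(p) sw * (acf_model_one(lag_ms, p[1], p[2], off(p)) - g)
  }
  if (model == "two_component") {
    p0 <- c(G0 = amp, f_fast = 0.5, tau_fast = t70, f_slow = 0.5,
            tau_slow = t30, g_inf = g_inf0)
    lower <- c(0, 0, tb[1], 0, tb[1], -Inf)
    upper <- c(Inf, 1, tb[2], 1, tb[2], Inf)
  } else {
    p0 <- c(G0 = amp, tau = clamp(cross(exp(-1))), g_inf = g_inf0)
    lower <- c(0, tb[1], -Inf)
    upper <- c(Inf, tb[2], Inf)
  }
  if (fixed_off) {
    keep_par <- seq_len(length(p0) - 1L)
    p0 <- p0[keep_par]; lower <- lower[keep_par]; upper <- upper[keep_par]
  }
  # deterministic multi-start: fixed relaxation-time rescalings, so a rerun
  # with the same inputs reproduces the same fit bit for bit
  jitter_factors <- list(c(1, 1), c(0.3, 3), c(3, 0.3), c(0.1, 10))
  best <- NULL
  for (try in 0:3) {
    p_start <- p0
    if (try > 0) {
      idx <- grepl("tau", names(p0))
      p_start[idx] <- clamp(p0[idx] *
                              jitter_factors[[try + 1L]][seq_len(sum(idx))])
    }
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(p_start, fn = resid_fn, lower = lower,
                           upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, maxfev = 5000,
                             ftol = 1e-12, ptol = 1e-10))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      conv <- fit$info %in% 1:4
      if (is.null(best) || (conv && sum(fit$fvec^2) < best$ss)) {
        best <- list(fit = fit, ss = sum(fit$fvec^2), conv = conv)
      }
      if (best$conv && try >= 1) break
      if (best$conv && try == 0) break
    }
  }
  if (is.null(best))
    return(structure(list(coefficients = rep(NA_real_, 6), reduced_chi2 = NA,
                          snr = snr, converged = FALSE, model = model,
                          message = "optimizer failure"),
                     class = "tab_acf_fit"))
  p <- best$fit$par
  if (fixed_off) p <- c(p, g_inf = g_inf_fixed)
  if (model == "two_component") {
    if (p[3] > p[5]) { p[c(3, 5)] <- p[c(5, 3)]; p[c(2, 4)] <- p[c(4, 2)] }
    cf <- c(G0 = unname(p[1]), tau_fast_ms = unname(p[3]),
            tau_slow_ms = unname(p[5]), f_fast = unname(p[2]),
            f_slow = unname(p[4]), g_inf = unname(p[6]))
  } else {
    cf <- c(G0 = unname(p[1]), tau_fast_ms = unname(p[2]),
            tau_slow_ms = NA_real_, f_fast = 1, f_slow = 0,
            g_inf = unname(p[3]))
  }
  chi2 <- best$ss / (length(g) - n_par)
  structure(list(coefficients = cf, reduced_chi2 = chi2, snr = snr,
                 converged = best$conv, model = model,
                 data = data.frame(lag_ms = lag_ms, G = g,
                                   sem = if (is.null(sem)) NA_real_ else sem,
                                   weight = w),
                 message = best$fit$message),
            class = "tab_acf_fit")
}

#' @export
print.tab_acf_fit <- function(x, ...) {
  cat(sprintf("<tab_acf_fit> %s binding model%s\n", x$model,
              if (x$converged) "" else " (NOT converged)"))
  cf <- x$coefficients
  cat(sprintf("  G0 = %.4g, G_inf = %.4g\n", cf["G0"], cf["g_inf"]))
  if (x$model == "two_component") {
    cat(sprintf("  tau_fast = %.3g ms (f = %.2f), tau_slow = %.3g ms (f = %.2f)\n",
                cf["tau_fast_ms"], cf["f_fast"], cf["tau_slow_ms"],
                cf["f_slow"]))
  } else {
    cat(sprintf("  tau = %.3g ms\n", cf["tau_fast_ms"]))
  }
  cat(sprintf("  reduced chi-squared = %.3g, SNR = %.3g\n", x$reduced_chi2,
              x$snr))
  invisible(x)
}

#' @export
coef.tab_acf_fit <- function(object, ...) object$coefficients

#' Predict the fitted ACF model at given lags
#' @param object a `tab_acf_fit`.
#' @param lag_ms lags (ms); defaults to the fitted lags.
#' @param ... unused.
#' @return Numeric vector of model values.
#' @export
predict.tab_acf_fit <- function(object, lag_ms = NULL, ...) {
  cf <- object$coefficients
  lag_ms <- lag_ms %||% object$data$lag_ms
  if (object$model == "two_component")
    acf_model_two(lag_ms, cf["G0"], cf["f_fast"], cf["tau_fast_ms"],
                  cf["f_slow"], cf["tau_slow_ms"], cf["g_inf"])
  else
    acf_model_one(lag_ms, cf["G0"], cf["tau_fast_ms"], cf["g_inf"])
}

#' @export
fitted.tab_acf_fit <- function(object, ...) predict(object)

#' @export
residuals.tab_acf_fit <- function(object, ...)
  object$data$G - predict(object)

#' @export
plot.tab_acf_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$lag_ms, d$G, log = "x", xlab = "lag (ms)", ylab = "G",
                 pch = 16, cex = 0.6, ...)
  if (!all(is.na(d$sem)))
    graphics::arrows(d$lag_ms, d$G - d$sem, d$lag_ms, d$G + d$sem,
                     angle = 90, code = 3, length = 0.02,
                     col = "gray50")
  ll <- exp(seq(log(min(d$lag_ms)), log(max(d$lag_ms)), length.out = 200))
  graphics::lines(ll, predict(x, ll), col = "red", lwd = 2)
  invisible(x)
}

#' Fit the binding model to every sufficiently strong pixel
#'
#' Runs [fit_acf()] on every pixel of an averaged ACF record whose SNR
#' exceeds `snr_gate` (strictly greater; ties at the gate are excluded).
#'
#' @param record an `acf_record` from [average_segments()].
#' @param model `"two_component"` or `"one_component"`.
#' @param snr_gate SNR gate (default 10).
#' @param tau_bounds_ms passed to [fit_acf()]; defaults to
#'   `c(frame time, segment duration)` expressed via the record's lag grid.
#' @return Data frame of class `acf_fit_table` with one row per gated
#'   pixel: `row`, `col`, coefficient columns, `reduced_chi2`, `snr`,
#'   `converged`; attribute `dim` carries the map shape and `snr` the full
#'   SNR matrix.
#' @export
fit_acf_pixels <- function(record, model = c("two_component",
                                             "one_component"),
                           snr_gate = 10, tau_bounds_ms = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(record, "acf_record"))
  snr <- estimate_snr(record)
  sel <- which(is.finite(snr) & snr > snr_gate, arr.ind = TRUE)
  rows <- vector("list", nrow(sel))
  for (i in seq_len(nrow(sel))) {
    r <- sel[i, 1]; c <- sel[i, 2]
    f <- tryCatch(fit_acf(record, row = r, col = c, model = model,
                          tau_bounds_ms = tau_bounds_ms),
                  error = function(e) NULL)
    if (is.null(f)) next
    cf <- coef(f)
    rows[[i]] <- data.frame(row = r, col = c, t(cf),
                            reduced_chi2 = f$reduced_chi2, snr = snr[r, c],
                            converged = f$converged)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(row = integer(0), col = integer(0), G0 = numeric(0),
                      tau_fast_ms = numeric(0), tau_slow_ms = numeric(0),
                      f_fast = numeric(0), f_slow = numeric(0),
                      g_inf = numeric(0), reduced_chi2 = numeric(0),
                      snr = numeric(0), converged = logical(0))
  structure(out, class = c("acf_fit_table", "data.frame"),
            dim_px = dim(record$G)[1:2], snr_matrix = snr,
            snr_gate = snr_gate, model = model)
}

#' Spatial maps of fitted binding parameters
#'
#' Rasters of the fast and slow relaxation times, the fraction of bound
#' molecules associated with the shorter relaxation time (computed as
#' `f_fast / (f_fast + f_slow)`), and the amplitude G0. Pixels with SNR at
#' or below the gate, or with non-converged fits, are invalid (`NA`), never
#' zero-filled.
#'
#' @param fits an `acf_fit_table` from [fit_acf_pixels()].
#' @param snr_gate SNR gate (default: the gate used for fitting).
#' @return A list of class `param_maps`: matrices `tau_fast_ms`,
#'   `tau_slow_ms`, `fast_fraction`, `G0`, logical `valid`.
#' @export
build_maps <- function(fits, snr_gate = attr(fits, "snr_gate") %||% 10) {
  stopifnot(inherits(fits, "acf_fit_table"))
  dm <- attr(fits, "dim_px")
  empty <- matrix(NA_real_, dm[1], dm[2])
  maps <- list(tau_fast_ms = empty, tau_slow_ms = empty,
               fast_fraction = empty, G0 = empty,
               valid = matrix(FALSE, dm[1], dm[2]))
  if (nrow(fits)) {
    use <- fits$converged & fits$snr > snr_gate
    idx <- cbind(fits$row[use], fits$col[use])
    maps$tau_fast_ms[idx] <- fits$tau_fast_ms[use]
    maps$tau_slow_ms[idx] <- fits$tau_slow_ms[use]
    denom <- fits$f_fast[use] + fits$f_slow[use]
    maps$fast_fraction[idx] <- ifelse(denom > 0,
                                      fits$f_fast[use] / denom, NA_real_)
    maps$G0[idx] <- fits$G0[use]
    maps$valid[idx] <- TRUE
  }
  structure(maps, class = "param_maps")
}

#' @export
print.param_maps <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<param_maps> %d x %d px, %d valid pixels\n",
              nrow(x$valid), ncol(x$valid), nv))
  if (nv) {
    cat(sprintf("  tau_fast median %.3g ms, tau_slow median %.3g ms\n",
                stats::median(x$tau_fast_ms[x$valid], na.rm = TRUE),
                stats::median(x$tau_slow_ms[x$valid], na.rm = TRUE)))
  }
  invisible(x)
}
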