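#' Generate a random field of fibril backbones with binding sites
#'
#' Fibril backbones are worm-like-chain polylines: fixed step length with
#' Gaussian heading increments of variance `step_nm / persistence_nm`,
#' clamped to the field of view. Binding sites are placed along the
#' backbones as a Poisson process of linear density `site_density_per_nm`.
#'
#' @param fov_nm numeric `c(height, width)` of the field of view in nm.
#' @param n_fibrils number of fibrils (>= 0).
#' @param site_density_per_nm binding sites per nm of backbone.
#' @param persistence_nm persistence length controlling curvature; large
#'   values give nearly straight fibrils (default 2000 nm, fairly straight
#'   fibrils like those extending away from cell bodies).
#' @param length_nm contour length per fibril (recycled); default 60% of the
#'   larger FOV side.
#' @param step_nm polyline step (default 25 nm).
#' @param seed RNG seed; fixed seed gives an identical field.
#' @return A list of class `fibril_field`: `segments` (list of n x 2
#'   matrices, columns x/y in nm), `sites` (matrix with columns
#'   `x_nm`, `y_nm`), `site_density_per_nm`, `fov_nm`.
#' @export
fibril_field <- function(fov_nm, n_fibrils, site_density_per_nm,
                         persistence_nm = 2000, length_nm = NULL,
                         step_nm = 25, seed = NULL) {
  if (any(fov_nm <= 0)) stop("FOV must be positive")
  if (n_fibrils < 0) stop("n_fibrils must be >= 0")
  length_nm <- length_nm %||% (0.6 * max(fov_nm))
  length_nm <- rep_len(length_nm, max(n_fibrils, 1L))
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "geometry"), {
    segments <- list()
    sites <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x_nm", "y_nm")))
    if (n_fibrils > 0) {
      for (i in seq_len(n_fibrils)) {
        n_steps <- max(2L, ceiling(length_nm[i] / step_nm))
        # start away from the border so fibrils mostly stay inside
        start <- c(stats::runif(1, 0.1, 0.9) * fov_nm[2],
                   stats::runif(1, 0.1, 0.9) * fov_nm[1])
        theta <- stats::runif(1, 0, 2 * pi) +
          cumsum(c(0, stats::rnorm(n_steps - 1, 0,
                                   sqrt(step_nm / persistence_nm))))
        pts <- cbind(start[1] + c(0, cumsum(step_nm * cos(theta[-1]))),
                     start[2] + c(0, cumsum(step_nm * sin(theta[-1]))))
        pts[, 1] <- pmin(pmax(pts[, 1], 0), fov_nm[2])
        pts[, 2] <- pmin(pmax(pts[, 2], 0), fov_nm[1])
        colnames(pts) <- c("x_nm", "y_nm")
        segments[[i]] <- pts
        seg_len <- sqrt(rowSums(diff(pts)^2))
        L <- sum(seg_len)
        n_sites <- stats::rpois(1, L * site_density_per_nm)
        if (n_sites > 0) {
          s <- sort(stats::runif(n_sites, 0, L))
          cum <- c(0, cumsum(seg_len))
          j <- findInterval(s, cum, rightmost.closed = TRUE)
          j <- pmin(j, length(seg_len))
          frac <- (s - cum[j]) / pmax(seg_len[j], 1e-12)
          xy <- pts[j, , drop = FALSE] +
            frac * (pts[j + 1L, , drop = FALSE] - pts[j, , drop = FALSE])
          sites <- rbind(sites, xy)
        }
      }
    }
    structure(list(segments = segments, sites = sites,
                   site_density_per_nm = site_density_per_nm,
                   fov_nm = as.numeric(fov_nm)),
              class = "fibril_field")
  })
}

#' @export
print.fibril_field <- function(x, ...) {
  cat(sprintf("<fibril_field> %d fibrils, %d binding sites, FOV %g x %g nm\n",
              length(x$segments), nrow(x$sites), x$fov_nm[1], x$fov_nm[2]))
  invisible(x)
}

#' Two-mode binding kinetics model
#'
#' Transient dye binding with Poisson arrivals per site and a two-component
#' exponential dwell mixture: each binding event draws its dwell from the
#' fast component (mean `tau_fast_ms`) with probability `f_fast`, otherwise
#' from the slow component. Defaults follow the relaxation-time magnitudes
#' measured for a fluorogenic amyloid probe on curli (fast ~23 ms, slow
#' ~482 ms).
#'
#' The default event-probability `f_fast = 0.95` makes the *bound
#' population* split its residence time about evenly between the two modes
#' (dwell-weighted fast fraction ~0.5), matching the comparable weight
#' fractions seen in fitted parameter maps; because slow events last ~20x
#' longer, comparable bound fractions require most *events* to be fast.
#'
#' @param arrival_rate_per_site_per_s Poisson arrival rate per binding
#'   site (default 2/s, a micromolar-dye regime with dense event
#'   statistics).
#' @param tau_fast_ms,tau_slow_ms dwell means (ms), `tau_fast_ms <
#'   tau_slow_ms`.
#' @param f_fast probability in `[0, 1]` that an event is a fast-mode event.
#' @return A list of class `kinetics_model`.
#' @export
kinetics_model <- function(arrival_rate_per_site_per_s = 2,
                           tau_fast_ms = 23, tau_slow_ms = 482,
                           f_fast = 0.95) {
  if (arrival_rate_per_site_per_s < 0) stop("arrival rate must be >= 0")
  if (tau_fast_ms >= tau_slow_ms) stop("tau_fast_ms must be < tau_slow_ms")
  if (f_fast < 0 || f_fast > 1) stop("f_fast must be in [0, 1]")
  structure(list(arrival_rate_per_site_per_s = arrival_rate_per_site_per_s,
                 tau_fast_ms = tau_fast_ms, tau_slow_ms = tau_slow_ms,
                 f_fast = f_fast),
            class = "kinetics_model")
}

#' Optics and camera model for movie rendering
#'
#' @param psf_sigma_nm Gaussian PSF standard deviation (nm); ~130 nm for a
#'   high-NA objective in the red.
#' @param mean_photons_per_frame mean detected photons per bound molecule
#'   per frame (690 at 30 ms frames is typical for this dye/camera; scale
#'   proportionally for shorter exposures).
#' @param brightness_cv coefficient of variation of the per-event log-normal
#'   brightness distribution (0.55 reproduces a 690 +/- 380 photon spread).
#' @param background_photons_per_pixel_per_frame uniform background level.
#' @param read_noise_e Gaussian read noise, rms electrons per pixel.
#' @return A list of class `optics_model`.
#' @export
optics_model <- function(psf_sigma_nm = 130, mean_photons_per_frame = 690,
                         brightness_cv = 0.55,
                         background_photons_per_pixel_per_frame = 2,
                         read_noise_e = 0) {
  if (psf_sigma_nm <= 0) stop("psf_sigma_nm must be > 0")
  if (brightness_cv < 0) stop("brightness_cv must be >= 0")
  structure(list(psf_sigma_nm = psf_sigma_nm,
                 mean_photons_per_frame = mean_photons_per_frame,
                 brightness_cv = brightness_cv,
                 background_photons_per_pixel_per_frame =
                   background_photons_per_pixel_per_frame,
                 read_noise_e = read_noise_e),
            class = "optics_model")
}

#' Simulate transient binding events on a fibril field
#'
#' Per site, arrival times are a homogeneous Poisson process; each event's
#' dwell is exponential with mean `tau_fast_ms` (probability `f_fast`) or
#' `tau_slow_ms`. Events at different sites may overlap in time. Arrivals
#' are generated from `-burnin_ms` onward and events that end before time
#' zero are discarded, so the bound-molecule occupancy is stationary from
#' the first frame (no warm-up ramp at the start of the movie).
#'
#' @param field a [fibril_field()].
#' @param kinetics a [kinetics_model()].
#' @param duration_ms movie duration in ms (> 0).
#' @param burnin_ms pre-observation arrival window (default five slow dwell
#'   times).
#' @param seed RNG seed.
#' @return A data frame of class `event_list`, sorted by onset time, with
#'   columns `site`, `x_nm`, `y_nm`, `t_on_ms`, `dwell_ms`, `component`
#'   (1 fast / 2 slow) and `photons_per_frame_mean` (`NA` until rendering
#'   draws per-event brightness).
#' @export
simulate_binding_events <- function(field, kinetics, duration_ms,
                                    burnin_ms = 5 * kinetics$tau_slow_ms,
                                    seed = NULL) {
  stopifnot(inherits(field, "fibril_field"),
            inherits(kinetics, "kinetics_model"))
  if (duration_ms <= 0) stop("duration_ms must be > 0")
  empty <- data.frame(site = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), t_on_ms = numeric(0),
                      dwell_ms = numeric(0), component = integer(0),
                      photons_per_frame_mean = numeric(0))
  class(empty) <- c("event_list", "data.frame")
  n_sites <- nrow(field$sites)
  if (n_sites == 0L || kinetics$arrival_rate_per_site_per_s == 0)
    return(empty)
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "kinetics"), {
    lambda <- kinetics$arrival_rate_per_site_per_s *
      (duration_ms + burnin_ms) / 1000
    n_ev <- stats::rpois(n_sites, lambda)
    total <- sum(n_ev)
    if (total == 0L) return(empty)
    site <- rep.int(seq_len(n_sites), n_ev)
    t_on <- stats::runif(total, -burnin_ms, duration_ms)
    comp <- ifelse(stats::runif(total) < kinetics$f_fast, 1L, 2L)
    dwell <- stats::rexp(total,
                         1 / ifelse(comp == 1L, kinetics$tau_fast_ms,
                                    kinetics$tau_slow_ms))
    keep <- t_on + dwell > 0
    if (!any(keep)) return(empty)
    site <- site[keep]; t_on <- t_on[keep]
    comp <- comp[keep]; dwell <- dwell[keep]
    o <- order(t_on)
    ev <- data.frame(site = site[o],
                     x_nm = field$sites[site[o], "x_nm"],
                     y_nm = field$sites[site[o], "y_nm"],
                     t_on_ms = t_on[o], dwell_ms = dwell[o],
                     component = comp[o],
                     photons_per_frame_mean = NA_real_)
    class(ev) <- c("event_list", "data.frame")
    ev
  })
}

#' Theoretical autocorrelation of the simulated binding process
#'
#' For Poisson arrivals with a two-component exponential dwell mixture the
#' bound-molecule number is an M/G/infinity-type process whose normalized
#' autocorrelation is an additive two-exponential curve,
#' `G(tau) = G0 * (w_f exp(-tau/tau_fast) + w_s exp(-tau/tau_slow)) +
#' G_inf`, with dwell-weighted (residence-time) weights
#' `w_f = f tau_fast / (f tau_fast + (1 - f) tau_slow)` and amplitude
#' `G0 = 1 / mean_occupancy`. This is the two-component binding model with
#' the event-probability `f_fast` of the simulator mapped to bound-fraction
#' weights; it reduces to a single exponential when one component is absent,
#' equals `G0 + G_inf` at zero lag and tends to `G_inf` at long lags.
#'
#' @param kinetics a [kinetics_model()].
#' @param mean_occupancy mean number of bound molecules per site (or per
#'   observation region), in `(0, 1)` for a single site.
#' @param lags_ms numeric vector of lags (ms).
#' @param g_inf offset (default 0).
#' @return Data frame with columns `lag_ms`, `G`.
#' @export
expected_acf <- function(kinetics, mean_occupancy, lags_ms, g_inf = 0) {
  stopifnot(inherits(kinetics, "kinetics_model"), mean_occupancy > 0)
  f <- kinetics$f_fast
  wf <- f * kinetics$tau_fast_ms /
    (f * kinetics$tau_fast_ms + (1 - f) * kinetics$tau_slow_ms)
  G0 <- 1 / mean_occupancy
  G <- G0 * (wf * exp(-lags_ms / kinetics$tau_fast_ms) +
               (1 - wf) * exp(-lags_ms / kinetics$tau_slow_ms)) + g_inf
  data.frame(lag_ms = lags_ms, G = G)
}

#' Sample apparent on-frame counts from a dwell-time mixture
#'
#' Draws dwell times from an exponential mixture and converts each to an
#' apparent number of consecutive "on" frames. With `phase = "none"`
#' (default) events are aligned to frame boundaries, `k = ceiling(dwell /
#' frame_ms)`, making each component's run-length law exactly geometric so
#' that counts follow `A * exp(-k * frame_ms / tau)`. With
#' `phase = "uniform"` a uniform arrival phase within the first frame is
#' added, which inflates the single-frame bin relative to that law.
#'
#' @param n number of events.
#' @param frame_ms frame time (ms).
#' @param tau_ms vector of dwell means (ms), one per component.
#' @param weights mixture probabilities (recycled, normalized).
#' @param phase `"none"` or `"uniform"`.
#' @param seed RNG seed.
#' @return Integer vector of on-frame counts (>= 1).
#' @export
sample_on_frame_counts <- function(n, frame_ms, tau_ms, weights = 1,
                                   phase = c("none", "uniform"),
                                   seed = NULL) {
  phase <- match.arg(phase)
  weights <- rep_len(weights, length(tau_ms))
  weights <- weights / sum(weights)
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "ontime"), {
    comp <- sample.int(length(tau_ms), n, replace = TRUE, prob = weights)
    d <- stats::rexp(n, 1 / tau_ms[comp])
    if (phase == "uniform") {
      u <- stats::runif(n, 0, frame_ms)
      as.integer(floor((d + u) / frame_ms) + 1 - (u == 0))
    } else {
      pmax(1L, as.integer(ceiling(d / frame_ms)))
    }
  })
}
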