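# Internal helpers: seeding, separable convolution, small numerics.

# Deterministic sub-stream seed derived from a master seed and a stream tag,
# kept inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(geometry = 11L, kinetics = 23L, brightness = 37L, noise = 53L,
               split = 71L, telegraph = 89L, ontime = 101L, frc = 131L,
               generic = 151L)
  off <- if (stream %in% names(offsets)) offsets[[stream]] else
    sum(utf8ToInt(as.character(stream))) %% 997L
  as.integer((abs(as.numeric(seed)) * 7919 + off * 104729) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# 1-D Gaussian kernel and its second derivative, truncated at `radius` pixels.
gauss_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

gauss_d2_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  k <- (x^2 - sigma^2) / sigma^4 * g
  # enforce a zero discrete sum so the response to a constant image vanishes
  k - mean(k)
}

# Banded Toeplitz matrix applying a 1-D kernel along a dimension of size n,
# with out-of-range kernel mass folded onto the boundary element (replicate
# padding), so convolution of a constant equals sum(kernel) everywhere.
conv_band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- seq_len(n)
    src <- pmin(pmax(idx + off, 1L), n)
    K[cbind(idx, src)] <- K[cbind(idx, src)] + kernel[j]
  }
  K
}

# Separable 2-D convolution via banded matrices: rows with kr, cols with kc.
conv2_sep <- function(img, kr, kc) {
  Kr <- conv_band_matrix(nrow(img), kr)
  Kc <- conv_band_matrix(ncol(img), kc)
  Kr %*% img %*% t(Kc)
}

# Fraction of a unit-integral 1-D Gaussian (sd sigma, mean mu) falling in
# pixels centered at integer coordinates `idx` (pixel i spans [i-.5, i+.5)).
pixel_gauss_1d <- function(idx, mu, sigma) {
  stats::pnorm(idx + 0.5, mu, sigma) - stats::pnorm(idx - 0.5, mu, sigma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
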