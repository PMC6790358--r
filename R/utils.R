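#' @keywords internal
"_PACKAGE"

#' Edge-corrected Gaussian smoothing of an evenly indexed signal
#'
#' Convolves `y` with a truncated Gaussian kernel of standard deviation
#' `sigma` (in sample steps), renormalising the kernel mass at the edges so
#' flat signals stay flat.
#'
#' @param y numeric vector.
#' @param sigma kernel standard deviation in sample steps.
#' @return smoothed numeric vector, same length as `y`.
#' @keywords internal
gaussian_smooth <- function(y, sigma) {
  n <- length(y)
  if (sigma <= 0 || n < 2) return(y)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  ypad <- c(rep(0, r), y, rep(0, r))
  wpad <- c(rep(0, r), rep(1, n), rep(0, r))
  num <- stats::filter(ypad, k, sides = 2)
  den <- stats::filter(wpad, k, sides = 2)
  as.numeric(num[(r + 1):(r + n)] / den[(r + 1):(r + n)])
}

# Indices of strict local maxima (plateaus credited to their first point).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  idx[y[idx] > 0]
}

local_minima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] <= y[1:(n - 2)] & y[2:(n - 1)] < y[3:n]) + 1L
}

# Pearson correlation that maps degenerate (constant) inputs to 0.
pearson_safe <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) return(0)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

# Linear resampling of a shape (rt, intensity) onto `npoints` over
# [center - half, center + half]; zero outside the shape's support.
resample_shape <- function(rt, intensity, center, half, npoints = 50L) {
  grid <- seq(center - half, center + half, length.out = npoints)
  if (length(rt) < 2) return(rep(0, npoints))
  stats::approx(rt, intensity, xout = grid, yleft = 0, yright = 0)$y
}

# Run code with a locally fixed RNG stream, restoring the caller's state.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
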