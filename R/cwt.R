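#' Morlet mother wavelet
#'
#' Complex plane wave modulated by a Gaussian,
#' `pi^(-1/4) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)`.
#' With `omega0 = 6` the function has (numerically) zero mean and satisfies
#' the admissibility condition.
#'
#' @param eta Nondimensional "time" argument (vectorised).
#' @param omega0 Nondimensional frequency (default 6).
#' @return Complex vector of wavelet values.
#' @examples
#' Re(morlet_mother(0))  # pi^(-1/4) = 0.7511
#' @export
morlet_mother <- function(eta, omega0 = 6) {
  pi^(-0.25) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
}

# Fourier transform of the (energy-normalised) Morlet daughter at scale s,
# sampled on angular frequencies omega: pi^(-1/4) sqrt(2 pi s) H(omega)
# exp(-(s omega - omega0)^2 / 2). Real and nonnegative.
morlet_fourier <- function(omega, s, omega0) {
  h <- as.numeric(omega > 0)
  pi^(-0.25) * sqrt(2 * pi * s) * h * exp(-(s * omega - omega0)^2 / 2)
}

#' Continuous wavelet transform of an intensity profile
#'
#' Decomposes the profile with Morlet daughter wavelets
#' `psi_(s,tau)(x) = s^(-1/2) psi0((x - tau)/s)` (L2 energy normalisation)
#' over a grid of scales, computed in the Fourier domain. The profile mean
#' is subtracted before the transform and stored for reconstruction. By
#' default the signal is extended by symmetric reflection to three times its
#' length and the transform cropped back, which suppresses wrap-around edge
#' artifacts; `pad = FALSE` gives the plain circular (periodic) transform.
#'
#' @param profile An intensity profile (object from [project_profile] or a
#'   numeric vector), length at least 4.
#' @param scales Strictly increasing vector of positive scales. The
#'   pipeline default is the integer grid `1:scale_grid_max`.
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @param pad Reflect-extend the profile before transforming (default TRUE).
#' @return An object of class `"cwt_decomp"`: complex `coefficients`
#'   (scales x positions), `scales`, `omega0`, `mean_amplitude` (mean
#'   coefficient modulus per scale), and the subtracted `profile_mean`.
#' @export
cwt_decompose <- function(profile, scales = 1:300, omega0 = 6, pad = TRUE) {
  x <- profile_values(profile)
  n <- length(x)
  if (n < 4L) stop("profile too short for a wavelet decomposition")
  if (any(scales <= 0)) stop("all scales must be positive")
  if (is.unsorted(scales, strictly = TRUE)) stop("scales must be strictly increasing")
  mu <- mean(x)
  x0 <- x - mu
  if (pad) {
    xe <- c(rev(x0), x0, rev(x0))
    off <- n
  } else {
    xe <- x0
    off <- 0L
  }
  N <- length(xe)
  xh <- stats::fft(xe)
  k <- 0:(N - 1L)
  omega <- 2 * pi * ifelse(k <= N / 2, k, k - N) / N
  W <- matrix(0i, length(scales), n)
  for (j in seq_along(scales)) {
    row <- stats::fft(xh * morlet_fourier(omega, scales[j], omega0),
                      inverse = TRUE) / N
    W[j, ] <- row[(off + 1L):(off + n)]
  }
  structure(
    list(coefficients = W,
         scales = as.numeric(scales),
         omega0 = omega0,
         mean_amplitude = rowMeans(Mod(W)),
         profile_mean = mu,
         profile = x),
    class = "cwt_decomp")
}

#' @export
print.cwt_decomp <- function(x, ...) {
  cat(sprintf("<cwt_decomp> %d scales (%g..%g) x %d positions, omega0 = %g\n",
              length(x$scales), min(x$scales), max(x$scales),
              ncol(x$coefficients), x$omega0))
  invisible(x)
}

#' Fourier period equivalent to a Morlet scale
#'
#' `lambda = 4 * pi * s / (omega0 + sqrt(2 + omega0^2))`; for `omega0 = 6`
#' the period is about 1.03 times the scale.
#'
#' @param s Scale (vectorised).
#' @param omega0 Morlet nondimensional frequency.
#' @return Fourier period in samples.
#' @export
morlet_period <- function(s, omega0 = 6) {
  4 * pi * s / (omega0 + sqrt(2 + omega0^2))
}

# Plateau-aware local extrema of a numeric vector. A run of equal values is
# a local maximum (minimum) when it is strictly greater (smaller) than both
# adjacent values; a run touching a signal end only needs to beat its one
# interior neighbour. Returns the run-midpoint indices (ties toward the
# lower index).
local_extrema_idx <- function(v, mode = c("max", "min")) {
  mode <- match.arg(mode)
  if (mode == "min") v <- -v
  n <- length(v)
  if (n == 0L) return(integer())
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer()
  for (i in seq_len(k)) {
    left_ok <- i == 1L || r$values[i] > r$values[i - 1L]
    right_ok <- i == k || r$values[i] > r$values[i + 1L]
    if (left_ok && right_ok && !(i == 1L && i == k))
      out <- c(out, starts[i] + (ends[i] - starts[i]) %/% 2L)
  }
  out
}

#' Select the adaptive reconstruction scale band
#'
#' Scans the mean coefficient amplitude per scale for its maximum inside the
#' predefined lane range (default scales 30--250). The lower cut-off is the
#' scale of the local minimum immediately before that maximum (or the
#' smallest computed scale). If a further local maximum exists at a higher
#' scale -- energy belonging to the profile baseline -- the upper cut-off is
#' the local minimum immediately after it; otherwise all higher scales are
#' kept and `max_was_open` is set.
#'
#' @param mean_amplitude Mean coefficient modulus per scale (from
#'   [cwt_decompose]).
#' @param scales Scale grid matching `mean_amplitude`.
#' @param search_range Length-2 vector, the lane scale range searched for
#'   the peak (default `c(30, 250)`).
#' @param ripple_fraction Extrema of the mean-amplitude curve with a
#'   relative dynamic below this fraction are numerical ripples, not range
#'   boundaries, and are ignored. The curve spans orders of magnitude
#'   between the noise floor and the lane peak, so significance is judged
#'   multiplicatively: the h-extrema suppression (the same transforms used
#'   for lane detection) is applied to the log of the curve with
#'   `h = log(1 + ripple_fraction)`. Default 0.05 (a 5% relative dip or
#'   bump is structure); 0 keeps every strict extremum.
#' @return An object of class `"scale_band"`: `cutoff_min`, `cutoff_max`,
#'   `search_range`, `peak_scale`, `max_was_open`.
#' @export
select_cutoffs <- function(mean_amplitude, scales, search_range = c(30, 250),
                           ripple_fraction = 0.05) {
  stopifnot(length(mean_amplitude) == length(scales), length(search_range) == 2L)
  if (search_range[1L] < min(scales) || search_range[2L] > max(scales))
    stop("search_range must lie within the computed scale grid")
  in_range <- which(scales >= search_range[1L] & scales <= search_range[2L])
  if (length(in_range) == 0L) stop("no computed scale inside search_range")
  peak <- in_range[which.max(mean_amplitude[in_range])]

  if (ripple_fraction > 0) {
    la <- log(pmax(mean_amplitude, max(mean_amplitude) * 1e-9))
    hs <- log1p(ripple_fraction)
    minima <- local_extrema_idx(h_minima(la, hs), "min")
    maxima <- local_extrema_idx(h_maxima(la, hs), "max")
  } else {
    minima <- local_extrema_idx(mean_amplitude, "min")
    maxima <- local_extrema_idx(mean_amplitude, "max")
  }

  below <- minima[minima < peak]
  i_min <- if (length(below)) max(below) else 1L

  higher_max <- maxima[maxima > peak]
  after <- if (length(higher_max)) minima[minima > min(higher_max)] else integer()
  # a higher maximum only closes the band when a minimum follows it; a
  # maximum truncated by the grid end is the rising baseline limb, and the
  # lane/baseline separation is then not straightforward (open band)
  open <- length(after) == 0L
  i_max <- if (open) length(scales) else min(after)
  if (i_min >= i_max) i_min <- 1L   # degenerate grid; keep band non-empty
  structure(
    list(cutoff_min = scales[i_min],
         cutoff_max = scales[i_max],
         search_range = search_range,
         peak_scale = scales[peak],
         max_was_open = open),
    class = "scale_band")
}

#' @export
print.scale_band <- function(x, ...) {
  cat(sprintf("<scale_band> [%g, %g]%s (peak at %g, searched [%g, %g])\n",
              x$cutoff_min, x$cutoff_max,
              if (x$max_was_open) " (upper cut-off open)" else "",
              x$peak_scale, x$search_range[1L], x$search_range[2L]))
  invisible(x)
}

# Delta-function reconstruction factor for the Morlet wavelet (C_delta =
# 0.776 at omega0 = 6); the log2 grid spacing of the dyadic formulation is
# converted to the linear scale grid through the 1/ln 2 Jacobian.
morlet_recon_factor <- function() {
  c_delta <- 0.776
  1 / (c_delta * pi^(-0.25) * log(2))
}

#' Reconstruct a smoothed profile from a scale band
#'
#' Inverts the redundant transform by summing the real part of the
#' coefficients over the scales inside `[cutoff_min, cutoff_max]`,
#' `K * sum_j Re(W(s_j, tau)) * ds_j / s_j^(3/2)`, where `K` is the Morlet
#' delta-reconstruction constant. The profile mean subtracted by
#' [cwt_decompose] is added back. Restricting the band to the lane range
#' removes both high-frequency noise and the baseline trend while, unlike a
#' moving average, preserving peak heights.
#'
#' When the band came out of [select_cutoffs] with `max_was_open` -- no
#' baseline range could be separated, so *all* scales above `cutoff_min`
#' are to be kept -- the profile is instead computed as the original minus
#' the reconstruction of the noise band below `cutoff_min`. This keeps
#' baseline content beyond the largest computed scale, which a truncated
#' coefficient sum would distort near the profile borders.
#'
#' @param decomp A `"cwt_decomp"` object.
#' @param band A `"scale_band"` object (or any list with `cutoff_min` and
#'   `cutoff_max`) lying within the decomposition's scale grid.
#' @return An `"intensity_profile"` with the smoothed values.
#' @export
reconstruct_profile <- function(decomp, band) {
  stopifnot(inherits(decomp, "cwt_decomp"))
  s <- decomp$scales
  ds <- diff(s)
  ds <- c(ds[1L], ds)                       # per-scale grid spacing
  band_sum <- function(idx) {
    wgt <- morlet_recon_factor() * ds[idx] / s[idx]^1.5
    as.numeric(crossprod(Re(decomp$coefficients[idx, , drop = FALSE]), wgt))
  }
  keep <- which(s >= band$cutoff_min & s <= band$cutoff_max)
  if (length(keep) == 0L) stop("no computed scale inside the reconstruction band")
  open_top <- isTRUE(band$max_was_open) && band$cutoff_max >= max(s)
  vals <- if (open_top) {
    noise <- which(s < band$cutoff_min)
    if (length(noise)) decomp$profile - band_sum(noise) else decomp$profile
  } else {
    band_sum(keep) + decomp$profile_mean
  }
  structure(
    list(values = vals,
         source_rows_used = c(NA_integer_, NA_integer_)),
    class = "intensity_profile")
}
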