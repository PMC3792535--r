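# Lane records are kept as a data.frame with 0-based, closed-interval
# column coordinates [left, right]; center is the lower-median column of
# the interval. This convention is shared by every module.
lane_df <- function(left = integer(), right = integer(),
                    intensity = numeric(), origin = character(),
                    validated = logical()) {
  left <- as.integer(left); right <- as.integer(right)
  data.frame(left = left,
             right = right,
             center = left + (right - left) %/% 2L,
             width = right - left + 1L,
             intensity = as.numeric(intensity),
             origin = as.character(origin),
             validated = as.logical(validated),
             stringsAsFactors = FALSE)
}

#' h-maxima transform of a 1-D profile
#'
#' Morphological reconstruction by dilation of the marker `f - h` under the
#' mask `f` (2-neighbour connectivity): every local maximum whose dynamic is
#' smaller than `h` is suppressed, all others are lowered by at most `h`.
#' The result satisfies `result <= f` and `f - result <= h` pointwise. In
#' one dimension geodesic paths are intervals, so the reconstruction is
#' computed exactly with one forward and one backward sweep.
#'
#' @param f Numeric vector or intensity profile.
#' @param h Nonnegative contrast threshold.
#' @return Numeric vector, the transformed profile.
#' @examples
#' h_maxima(c(0, 3, 1, 2, 0), 1.5)  # the peak at 2 is suppressed
#' @export
h_maxima <- function(f, h) {
  f <- profile_values(f)
  if (h < 0) stop("h must be nonnegative")
  reconstruct_dilation(f - h, f)
}

#' h-minima transform of a 1-D profile
#'
#' Dual of [h_maxima]: fills every local minimum whose dynamic is smaller
#' than `h`, computed as `-h_maxima(-f, h)`. The result satisfies
#' `result >= f` pointwise.
#'
#' @inheritParams h_maxima
#' @return Numeric vector, the transformed profile.
#' @export
h_minima <- function(f, h) {
  f <- profile_values(f)
  if (h < 0) stop("h must be nonnegative")
  -reconstruct_dilation(-f - h, -f)
}

# Exact 1-D morphological reconstruction by dilation of marker under mask
# (marker <= mask assumed). r[i] = max over j of min(marker[j], min mask on
# the interval between j and i); the interval path makes two sweeps exact.
reconstruct_dilation <- function(marker, mask) {
  n <- length(marker)
  L <- numeric(n)
  L[1L] <- min(marker[1L], mask[1L])
  if (n > 1L) {
    for (i in 2:n) L[i] <- min(mask[i], max(marker[i], L[i - 1L]))
  }
  R <- numeric(n)
  R[n] <- min(marker[n], mask[n])
  if (n > 1L) {
    for (i in (n - 1L):1L) R[i] <- min(mask[i], max(marker[i], R[i + 1L]))
  }
  pmax(L, R)
}

#' Regional extrema of a 1-D profile
#'
#' Marks maximal (resp. minimal) plateaus: runs of equal value strictly
#' greater (resp. smaller) than both neighbouring values. A run touching a
#' signal end only needs to beat its interior neighbour; a constant signal
#' is one whole-signal plateau and is marked everywhere.
#'
#' @param transformed Numeric vector or intensity profile (normally the
#'   output of [h_maxima] or [h_minima]).
#' @param mode `"max"` or `"min"`.
#' @return Logical vector of the profile's length.
#' @examples
#' regional_extrema(c(0, 2, 2, 1, 3, 0), "max")
#' @export
regional_extrema <- function(transformed, mode = c("max", "min")) {
  mode <- match.arg(mode)
  v <- profile_values(transformed)
  if (mode == "min") v <- -v
  r <- rle(v)
  k <- length(r$values)
  keep <- logical(k)
  for (i in seq_len(k)) {
    left_ok <- i == 1L || r$values[i] > r$values[i - 1L]
    right_ok <- i == k || r$values[i] > r$values[i + 1L]
    keep[i] <- left_ok && right_ok
  }
  rep(keep, r$lengths)
}

#' Initial candidate lane set from the smoothed profile
#'
#' Computes the h-maxima and h-minima transforms with
#' `h = h_fraction * max(smoothed)`, extracts their regional maxima and
#' minima, and combines them into a single mask that is true for regional
#' maxima not marked as minima -- the minima exclusion prevents very
#' low-intensity maxima from entering the candidate set. Each connected run
#' of the combined mask becomes one candidate lane whose center and width
#' are the middle point and length of the run and whose intensity is the
#' maximum of the smoothed profile inside the run.
#'
#' @param smoothed Smoothed intensity profile (from [reconstruct_profile]).
#' @param h_fraction Contrast threshold as a fraction of the profile
#'   maximum (default 0.05).
#' @return A lane data.frame (columns `left`, `right`, `center`, `width`,
#'   `intensity`, `origin`, `validated`), 0-based closed intervals, sorted
#'   by center. A constant profile yields zero rows with a warning.
#' @export
initial_lane_set <- function(smoothed, h_fraction = 0.05) {
  v <- profile_values(smoothed)
  if (max(v) == min(v)) {
    warning("constant profile: no lanes detected")
    return(lane_df())
  }
  h <- h_fraction * max(v)
  if (h <= 0) {
    warning("nonpositive h threshold: no lanes detected")
    return(lane_df())
  }
  maxima_mask <- regional_extrema(h_maxima(v, h), "max")
  minima_mask <- regional_extrema(h_minima(v, h), "min")
  combined <- maxima_mask & !minima_mask
  runs <- mask_runs(combined)
  if (nrow(runs) == 0L) return(lane_df())
  lane_df(left = runs$start - 1L, right = runs$end - 1L,
          intensity = vapply(seq_len(nrow(runs)), function(i)
            max(v[runs$start[i]:runs$end[i]]), numeric(1)),
          origin = rep("initial", nrow(runs)),
          validated = rep(FALSE, nrow(runs)))
}

# 1-based [start, end] intervals of TRUE runs in a logical vector.
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}
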