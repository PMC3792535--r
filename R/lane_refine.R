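pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Descriptive statistics of a lane set
#'
#' Computes the mean and (population) standard deviation of lane width,
#' lane center-to-center distance and lane intensity, the adaptive
#' reference values driving false-lane removal. Distances are measured
#' between consecutive lane centers; the gaps from the first/last lane
#' center to the image borders are reported separately (`border_gaps`) and
#' only enter the removal rule, not the distance statistics -- except when a
#' single lane leaves no center-to-center distance at all, in which case the
#' border gaps are the distance sample.
#'
#' @param lanes Lane data.frame (at least one lane), sorted by center.
#' @param profile_length Number of profile samples (image columns).
#' @return An object of class `"lane_stats"`: `m_w`, `std_w`, `m_d`,
#'   `std_d`, `m_i`, `std_i`, `distances`, `border_gaps`, `profile_length`.
#' @export
lane_statistics <- function(lanes, profile_length) {
  if (nrow(lanes) == 0L) stop("lane statistics require at least one lane")
  centers <- lanes$center
  if (is.unsorted(centers)) {
    lanes <- lanes[order(centers), ]
    centers <- lanes$center
  }
  distances <- diff(centers)
  border_gaps <- c(centers[1L], (profile_length - 1L) - centers[length(centers)])
  dsample <- if (length(distances) > 0L) distances else border_gaps
  structure(
    list(m_w = mean(lanes$width), std_w = pop_sd(lanes$width),
         m_d = mean(dsample), std_d = pop_sd(dsample),
         m_i = mean(lanes$intensity), std_i = pop_sd(lanes$intensity),
         distances = distances, border_gaps = border_gaps,
         profile_length = profile_length),
    class = "lane_stats")
}

#' @export
print.lane_stats <- function(x, ...) {
  cat(sprintf(paste0("<lane_stats> width %.1f +/- %.1f, distance %.1f +/- %.1f, ",
                     "intensity %.2f +/- %.2f\n"),
              x$m_w, x$std_w, x$m_d, x$std_d, x$m_i, x$std_i))
  invisible(x)
}

#' Remove false lanes from the candidate set
#'
#' A candidate lane is removed if and only if its intensity is below half
#' the mean lane intensity AND it is additionally anomalous in geometry:
#' its width falls outside `m_w +/- std_w`, or its distance to an adjacent
#' lane (or to the image border, for the outermost lanes) is below
#' `m_d - std_d`. The conjunction guarantees that no lane of at least
#' average-half intensity is ever removed. All decisions are evaluated in a
#' single pass against the statistics of the full candidate set; survivors
#' are marked validated.
#'
#' @param lanes Candidate lane data.frame, sorted by center.
#' @param stats `"lane_stats"` computed from the same lane set.
#' @return The surviving lanes with `validated = TRUE`.
#' @export
remove_false_lanes <- function(lanes, stats) {
  n <- nrow(lanes)
  if (n == 0L) return(lanes)
  centers <- lanes$center
  d_prev <- c(stats$border_gaps[1L], diff(centers))
  d_next <- c(diff(centers), stats$border_gaps[2L])
  min_dist <- pmin(d_prev, d_next)
  width_bad <- lanes$width < stats$m_w - stats$std_w |
               lanes$width > stats$m_w + stats$std_w
  dist_bad <- min_dist < stats$m_d - stats$std_d
  remove <- lanes$intensity < stats$m_i / 2 & (width_bad | dist_bad)
  out <- lanes[!remove, , drop = FALSE]
  out$validated <- TRUE
  rownames(out) <- NULL
  out
}

#' Derivative of the smoothed profile
#'
#' Central finite differences, with forward/backward differences at the two
#' endpoints; same length as the input.
#'
#' @param smoothed Intensity profile or numeric vector, length at least 3.
#' @return An `"intensity_profile"` holding the derivative values.
#' @export
profile_derivative <- function(smoothed) {
  v <- profile_values(smoothed)
  n <- length(v)
  if (n < 3L) stop("profile too short to differentiate")
  d <- numeric(n)
  d[1L] <- v[2L] - v[1L]
  d[n] <- v[n] - v[n - 1L]
  d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / 2
  structure(list(values = d, source_rows_used = c(NA_integer_, NA_integer_)),
            class = "intensity_profile")
}

#' Locate precise lane limits from the profile derivative
#'
#' A true lane produces a local maximum of the profile derivative on its
#' rising (left) side and a local minimum on its falling (right) side,
#' located at the inflection points of the intensity profile. Against
#' derivative fluctuations, the limits are taken as the positions of the
#' highest and the lowest derivative value on the two sides of the lane:
#' the left limit is searched from the window start to the end of the
#' candidate region, the right limit from the start of the candidate
#' region to the window end. Searching over the whole candidate region
#' (rather than splitting at its midpoint) re-centers candidates whose
#' region was smeared sideways across a shallow valley; if the two searches
#' cross, the lane is re-examined on either side of its center, and as a
#' last resort the candidate-region endpoints are kept. The window spans
#' from the previous lane's candidate region to the next one's, so limits
#' of adjacent lanes cannot invade each other's regions.
#'
#' @param lane One-row lane data.frame.
#' @param derivative Profile derivative (from [profile_derivative]).
#' @param search_window Length-2 vector of 0-based columns
#'   `c(window_left, window_right)` bracketing the lane.
#' @return The lane with updated `left`, `right`, `center`, `width`, and a
#'   logical `limit_fallback` set when a degenerate window forced a limit
#'   back to the candidate-region endpoint.
#' @export
detect_lane_limits <- function(lane, derivative, search_window) {
  d <- profile_values(derivative)
  n <- length(d)
  wl <- max(0L, as.integer(search_window[1L]))
  wr <- min(n - 1L, as.integer(search_window[2L]))
  ctr <- lane$center
  fallback <- FALSE
  search_limits <- function(lo_end, hi_start) {
    # left limit: strongest rise in [wl, lo_end]; right: strongest fall in
    # [hi_start, wr]
    l <- if (wl <= lo_end) wl + which.max(d[(wl + 1L):(lo_end + 1L)]) - 1L
         else NA_integer_
    r <- if (wr >= hi_start) hi_start + which.min(d[(hi_start + 1L):(wr + 1L)]) - 1L
         else NA_integer_
    c(l, r)
  }
  lim <- search_limits(min(lane$right, wr), max(lane$left, wl))
  if (anyNA(lim) || lim[1L] > lim[2L])
    lim <- search_limits(min(ctr, wr), max(ctr, wl))
  if (anyNA(lim) || lim[1L] > lim[2L]) {
    lim <- c(lane$left, lane$right)
    fallback <- TRUE
  }
  left <- lim[1L]; right <- lim[2L]
  lane$left <- as.integer(left)
  lane$right <- as.integer(right)
  lane$width <- lane$right - lane$left + 1L
  lane$center <- lane$left + (lane$width - 1L) %/% 2L
  lane$limit_fallback <- fallback
  lane
}

# Detect limits for every validated lane; windows run between adjacent
# candidate regions (or profile ends), additionally capped at the midpoint
# between adjacent lane centers so that a limit always lies closer to its
# own lane than to a neighbour (band-pass smoothing produces under- and
# overshoot lobes next to strong lanes that would otherwise capture the
# limits of a weak distant neighbour). Input/output sorted by center.
refine_limits <- function(lanes, derivative, profile_length) {
  n <- nrow(lanes)
  if (n == 0L) return(lanes)
  out <- lanes
  out$limit_fallback <- FALSE
  for (i in seq_len(n)) {
    wl <- if (i == 1L) 0L else
      max(lanes$right[i - 1L] + 1L,
          as.integer(floor((lanes$center[i - 1L] + lanes$center[i]) / 2)) + 1L)
    wr <- if (i == n) profile_length - 1L else
      min(lanes$left[i + 1L] - 1L,
          as.integer(floor((lanes$center[i] + lanes$center[i + 1L]) / 2)))
    out[i, ] <- detect_lane_limits(out[i, , drop = FALSE], derivative, c(wl, wr))
  }
  # adjacent refined limits may meet inside a shared gap; keep lanes disjoint
  for (i in seq_len(max(0L, n - 1L))) {
    if (out$right[i] >= out$left[i + 1L]) {
      mid <- (out$center[i] + out$center[i + 1L]) %/% 2L
      out$right[i] <- min(out$right[i], mid)
      out$left[i + 1L] <- max(out$left[i + 1L], mid + 1L)
    }
  }
  out$width <- out$right - out$left + 1L
  out$center <- out$left + (out$width - 1L) %/% 2L
  out
}

#' Reference values for subtle-lane recovery
#'
#' From the validated lanes with detected limits, computes the mean lane
#' width `mlw` and the mean amplitude difference `mla` between the
#' derivative values at the paired lane limits (derivative at the left
#' limit minus derivative at the right limit). Both act as adaptive
#' references when searching empty zones for low-intensity lanes.
#'
#' @param lanes Validated lane data.frame with detected limits.
#' @param derivative Profile derivative.
#' @return List with elements `mlw` and `mla`.
#' @export
reference_values <- function(lanes, derivative) {
  if (nrow(lanes) == 0L) stop("reference values require at least one lane")
  d <- profile_values(derivative)
  list(mlw = mean(lanes$width),
       mla = mean(d[lanes$left + 1L] - d[lanes$right + 1L]))
}

#' Empty zones of a profile
#'
#' Maximal column intervals not covered by any validated lane, the regions
#' searched during subtle-lane recovery.
#'
#' @param lanes Validated lane data.frame (0-based closed intervals).
#' @param profile_length Number of profile samples.
#' @return data.frame with 0-based `left`, `right`, `width`.
#' @export
empty_zones <- function(lanes, profile_length) {
  covered <- logical(profile_length)
  for (i in seq_len(nrow(lanes)))
    covered[(lanes$left[i] + 1L):(lanes$right[i] + 1L)] <- TRUE
  runs <- mask_runs(!covered)
  data.frame(left = runs$start - 1L, right = runs$end - 1L,
             width = runs$end - runs$start + 1L)
}

#' Recover subtle lanes from the profile derivative
#'
#' Searches every empty zone wider than the mean lane width `mlw` for
#' low-intensity lanes that escaped peak detection. Local maxima and minima
#' of the derivative inside the zone are paired left to right -- each local
#' maximum with the nearest following local minimum, a rise followed by a
#' fall -- and a pair is accepted as a lane when its width exceeds
#' `recovery_width_fraction * mlw` (default 60%) and its derivative
#' amplitude difference exceeds `recovery_amplitude_fraction * mla`
#' (default 30%). After an accepted pair, scanning resumes beyond it, so
#' several non-overlapping lanes can be recovered from one zone.
#'
#' Derivative extrema whose dynamic is below half the amplitude gate are
#' numerical ripples: they could never contribute an acceptable pair, but
#' left in place they would fragment the left-to-right pairing. They are
#' suppressed with the same h-extrema transforms used for lane detection
#' before the extrema are paired.
#'
#' @param zones Empty-zone data.frame (from [empty_zones]).
#' @param derivative Profile derivative.
#' @param mlw,mla Reference values (from [reference_values]).
#' @param params A [detection_params] object (recovery fractions).
#' @param smoothed Optional smoothed profile used to fill the intensity
#'   field of recovered lanes.
#' @return Lane data.frame of recovered lanes (`origin = "recovered"`,
#'   validated), possibly empty.
#' @export
recover_subtle_lanes <- function(zones, derivative, mlw, mla,
                                 params = detection_params(),
                                 smoothed = NULL) {
  d <- profile_values(derivative)
  sv <- if (is.null(smoothed)) NULL else profile_values(smoothed)
  res <- lane_df()
  for (z in seq_len(nrow(zones))) {
    if (zones$width[z] <= mlw) next
    zi <- (zones$left[z] + 1L):(zones$right[z] + 1L)
    seg <- d[zi]
    hd <- 0.5 * params$recovery_amplitude_fraction * mla
    segx <- if (hd > 0) h_maxima(seg, hd) else seg
    segn <- if (hd > 0) h_minima(seg, hd) else seg
    mx <- local_extrema_idx(segx, "max") + zones$left[z] - 1L  # 0-based absolute
    mn <- local_extrema_idx(segn, "min") + zones$left[z] - 1L
    if (length(mx) == 0L || length(mn) == 0L) next
    floor_pos <- -1L
    for (p in mx) {
      if (p <= floor_pos) next
      q <- mn[mn > p]
      if (length(q) == 0L) break
      q <- q[1L]
      cand_width <- q - p + 1L
      cand_amp <- d[p + 1L] - d[q + 1L]
      if (cand_width > params$recovery_width_fraction * mlw &&
          cand_amp > params$recovery_amplitude_fraction * mla) {
        res <- rbind(res, lane_df(
          left = p, right = q,
          intensity = if (is.null(sv)) NA_real_ else max(sv[(p + 1L):(q + 1L)]),
          origin = "recovered", validated = TRUE))
        floor_pos <- q
      }
    }
  }
  rownames(res) <- NULL
  res
}
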