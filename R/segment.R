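#' Segment the lanes of a TLC plate image
#'
#' Runs the full three-phase lane segmentation pipeline on a plate ROI:
#'
#' 1. **Preparation** -- grayscale conversion, rescaling to a fixed row
#'    count, background removal by morphological closing (which inverts
#'    lane polarity), and column projection to an intensity profile
#'    excluding the noisy top rows.
#' 2. **Smoothing** -- Morlet CWT decomposition of the profile and
#'    reconstruction over an adaptively selected scale band that retains
#'    lane-scale structure while discarding noise and baseline.
#' 3. **Segmentation** -- phase 1 detects candidate lanes via the
#'    h-maxima/h-minima transforms; phase 2 removes false lanes by adaptive
#'    statistical rules on width, spacing and intensity; phase 3 locates
#'    precise lane limits at the derivative extrema and recovers subtle
#'    low-contrast lanes from empty zones.
#'
#' The method requires neither the number of lanes nor a regular spacing,
#' and tolerates empty lanes between occupied ones.
#'
#' @param image A [plate_image], a numeric matrix / RGB array with
#'   intensities in \[0, 255\], or a path to a PNG/TIFF/JPEG file.
#' @param params A [detection_params] object.
#' @param crop Optional crop rectangle passed to [read_plate] when `image`
#'   is a file path.
#' @return An object of class `"tlc_lanes"`; see [print.tlc_lanes],
#'   [summary.tlc_lanes], [plot.tlc_lanes], [as.data.frame.tlc_lanes].
#'   Main elements: `lanes` (final lane data.frame, 0-based closed column
#'   intervals in the rescaled frame), `phase1`, `phase2` (intermediate
#'   sets), `profile`, `smoothed`, `derivative`, `band`, `stats`,
#'   `reference` (`mlw`, `mla`), `counts`, `params`, `rescale_factor`.
#' @examples
#' spec <- plate_spec(n_lanes = 6, seed = 42)
#' plate <- generate_plate(spec)
#' fit <- segment_lanes(plate$image)
#' fit
#' @export
segment_lanes <- function(image, params = detection_params(), crop = NULL) {
  validate_params(params)
  img <- if (is.character(image)) read_plate(image, crop = crop)
         else as_plate_image(image)

  gray <- rgb_to_gray(img)
  gray <- rescale_image(gray, params$target_rows)
  enhanced <- remove_background(gray, params$se_fraction)
  profile <- project_profile(enhanced, params$top_exclusion)

  decomp <- cwt_decompose(profile, scales = seq_len(params$scale_grid_max),
                          omega0 = params$omega0)
  band <- select_cutoffs(decomp$mean_amplitude, decomp$scales,
                         c(params$scale_search_min, params$scale_search_max))
  smoothed <- reconstruct_profile(decomp, band)
  m <- length(smoothed$values)

  phase1 <- initial_lane_set(smoothed, params$h_fraction)

  if (nrow(phase1) == 0L) {
    warning("no candidate lanes detected")
    empty <- lane_df()
    return(new_tlc_lanes(empty, phase1, empty, profile, smoothed, NULL, band,
                         NULL, NULL, params, gray$rescale_factor,
                         c(gray$n_rows, gray$n_cols)))
  }

  stats <- lane_statistics(phase1, m)
  phase2 <- remove_false_lanes(phase1, stats)
  deriv <- profile_derivative(smoothed)

  if (nrow(phase2) == 0L) {
    return(new_tlc_lanes(phase2, phase1, phase2, profile, smoothed, deriv,
                         band, stats, NULL, params, gray$rescale_factor,
                         c(gray$n_rows, gray$n_cols)))
  }

  refined <- refine_limits(phase2, deriv, m)
  ref <- reference_values(refined, deriv)
  zones <- empty_zones(refined, m)
  recovered <- recover_subtle_lanes(zones, deriv, ref$mlw, ref$mla, params,
                                    smoothed = smoothed)
  final <- rbind(refined, if (nrow(recovered))
    cbind(recovered, limit_fallback = FALSE))
  final <- final[order(final$center), , drop = FALSE]
  rownames(final) <- NULL

  new_tlc_lanes(final, phase1, phase2, profile, smoothed, deriv, band,
                stats, ref, params, gray$rescale_factor,
                c(gray$n_rows, gray$n_cols))
}

new_tlc_lanes <- function(lanes, phase1, phase2, profile, smoothed, deriv,
                          band, stats, reference, params, rescale_factor,
                          dims) {
  structure(
    list(lanes = lanes,
         phase1 = phase1,
         phase2 = phase2,
         profile = profile,
         smoothed = smoothed,
         derivative = deriv,
         band = band,
         stats = stats,
         reference = reference,
         params = params,
         rescale_factor = rescale_factor,
         image_dims = dims,
         counts = c(phase1 = nrow(phase1), phase2 = nrow(phase2),
                    phase3 = nrow(lanes))),
    class = "tlc_lanes")
}

#' @export
print.tlc_lanes <- function(x, ...) {
  cat(sprintf("TLC lane segmentation: %d lane(s)\n", nrow(x$lanes)))
  cat(sprintf("  image: %d x %d (rescale factor %.4g)\n",
              x$image_dims[1L], x$image_dims[2L], x$rescale_factor))
  if (!is.null(x$band))
    cat(sprintf("  reconstruction band: scales [%g, %g]%s\n",
                x$band$cutoff_min, x$band$cutoff_max,
                if (x$band$max_was_open) " (open)" else ""))
  cat(sprintf("  lanes per phase: %d -> %d -> %d\n",
              x$counts["phase1"], x$counts["phase2"], x$counts["phase3"]))
  if (nrow(x$lanes)) {
    cat("  centers:", paste(x$lanes$center, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.tlc_lanes <- function(object, ...) {
  x <- object
  print(x)
  if (nrow(x$lanes)) {
    cat("\nLane table (0-based columns, rescaled frame):\n")
    print(as.data.frame(x), row.names = FALSE)
    if (!is.null(x$reference))
      cat(sprintf("\nReference values: mlw = %.1f, mla = %.3f\n",
                  x$reference$mlw, x$reference$mla))
  }
  invisible(x)
}

#' Lane table of a segmentation result
#'
#' @param x A `"tlc_lanes"` object.
#' @param row.names,optional Ignored (S3 signature).
#' @param frame `"rescaled"` (default) reports coordinates in the
#'   1024-row normalised frame; `"original"` maps them back to the input
#'   image through the stored rescale factor; `"both"` includes both.
#' @param ... Ignored.
#' @return data.frame with one row per detected lane.
#' @export
as.data.frame.tlc_lanes <- function(x, row.names = NULL, optional = FALSE,
                                    frame = c("rescaled", "original", "both"),
                                    ...) {
  frame <- match.arg(frame)
  ln <- x$lanes
  out <- data.frame(lane_index = seq_len(nrow(ln)) - 1L,
                    left = ln$left, right = ln$right, center = ln$center,
                    width = ln$width, intensity = ln$intensity,
                    origin = ln$origin, stringsAsFactors = FALSE)
  if (frame != "rescaled") {
    f <- x$rescale_factor
    orig <- data.frame(left_orig = as.integer(round(ln$left / f)),
                       right_orig = as.integer(round(ln$right / f)),
                       center_orig = as.integer(round(ln$center / f)))
    out <- if (frame == "original")
      cbind(out[, c("lane_index"), drop = FALSE], orig,
            out[, c("width", "intensity", "origin")])
    else cbind(out, orig)
  }
  out
}

#' Plot a lane segmentation result
#'
#' Draws the raw and smoothed intensity profiles with the detected lane
#' limits; recovered lanes are marked in a different colour.
#'
#' @param x A `"tlc_lanes"` object.
#' @param ... Passed to [graphics::plot].
#' @export
plot.tlc_lanes <- function(x, ...) {
  p <- x$profile$values
  s <- x$smoothed$values
  graphics::plot(seq_along(p) - 1L, p, type = "l", col = "grey60",
                 xlab = "column", ylab = "intensity",
                 main = sprintf("%d lane(s)", nrow(x$lanes)), ...)
  graphics::lines(seq_along(s) - 1L, s, col = "black", lwd = 2)
  if (nrow(x$lanes)) {
    cols <- ifelse(x$lanes$origin == "recovered", "red", "blue")
    graphics::abline(v = x$lanes$left, col = cols, lty = 3)
    graphics::abline(v = x$lanes$right, col = cols, lty = 3)
    graphics::abline(v = x$lanes$center, col = cols, lty = 1)
  }
  invisible(x)
}
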