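#' Write lane records to CSV and/or JSON
#'
#' Serialises the lane table of a segmentation result. CSV and JSON carry
#' identical records (header `lane_index,left,right,center,width,
#' intensity,origin` plus, when the image was rescaled, the same
#' coordinates mapped back to the original frame).
#'
#' @param fit A `"tlc_lanes"` object.
#' @param csv,json Output paths (either may be `NULL` to skip).
#' @param frame Coordinate frame(s) to report; see
#'   [as.data.frame.tlc_lanes].
#' @return The written data.frame, invisibly.
#' @export
write_lanes <- function(fit, csv = NULL, json = NULL, frame = "both") {
  df <- as.data.frame(fit, frame = frame)
  if (!is.null(csv))
    utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  if (!is.null(json))
    jsonlite::write_json(df, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  invisible(df)
}

#' Write a plate image to a PNG/TIFF/JPEG file
#'
#' @param img A [plate_image] (grayscale or RGB, intensities 0--255).
#' @param path Output path; the format follows the file extension.
#' @return `path`, invisibly.
#' @export
write_plate <- function(img, path) {
  img <- as_plate_image(img)
  dat <- if (img$n_channels == 3L) {
    a <- array(0, c(img$n_cols, img$n_rows, 3L))
    for (k in 1:3) a[, , k] <- t(img$pixels[, , k]) / 255
    a
  } else t(img$pixels) / 255
  EBImage::writeImage(EBImage::Image(dat,
    colormode = if (img$n_channels == 3L) "Color" else "Grayscale"), path)
  invisible(path)
}

#' Write an annotated overlay image of a segmentation result
#'
#' Renders the (grayscale, rescaled) plate with lane boundaries and centers
#' drawn as vertical lines: blue boundaries, red center lines for lanes
#' recovered in the third phase.
#'
#' @param fit A `"tlc_lanes"` object.
#' @param image The plate image that was segmented (used as backdrop; it is
#'   converted and rescaled the same way as during segmentation).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(fit, image, path) {
  img <- rescale_image(rgb_to_gray(as_plate_image(image)),
                       fit$params$target_rows)
  g <- img$pixels / 255
  rgb <- array(rep(g, 3L), c(dim(g), 3L))
  mark <- function(col0, channel) {
    cc <- col0 + 1L
    if (cc >= 1L && cc <= ncol(g)) {
      rgb[, cc, ] <<- 0
      rgb[, cc, channel] <<- 1
    }
  }
  for (i in seq_len(nrow(fit$lanes))) {
    ch <- if (fit$lanes$origin[i] == "recovered") 1L else 3L
    mark(fit$lanes$left[i], ch)
    mark(fit$lanes$right[i], ch)
  }
  write_plate(plate_image(rgb * 255), path)
}

#' Write ground truth to a JSON file
#'
#' @param truth A `"ground_truth"` object (from [generate_plate]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(lane_centers = truth$lane_centers,
         lane_limits = apply(truth$lane_limits, 1L, identity, simplify = FALSE),
         lane_widths = truth$lane_widths,
         subtle_flags = truth$subtle_flags),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read ground truth from a JSON file
#'
#' @param path JSON path written by [write_truth].
#' @return A `"ground_truth"` object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lim <- x$lane_limits
  if (is.list(lim)) lim <- do.call(rbind, lim)
  if (is.null(lim) || length(lim) == 0L) lim <- matrix(numeric(), 0L, 2L)
  colnames(lim) <- c("left", "right")
  structure(
    list(lane_centers = as.numeric(x$lane_centers),
         lane_limits = lim,
         lane_widths = as.numeric(x$lane_widths),
         subtle_flags = as.logical(x$subtle_flags)),
    class = "ground_truth")
}
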