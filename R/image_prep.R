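#' Plate image container
#'
#' Light wrapper around a pixel raster of a TLC plate region of interest
#' (ROI). Pixels are stored rows x columns (x columns x 3 for RGB) with
#' intensities on the 0--255 scale; values are kept as reals throughout the
#' pipeline so that later fractional thresholds are not perturbed by
#' quantisation.
#'
#' @param pixels Numeric matrix (grayscale) or 3-d array with third
#'   dimension 3 (RGB), intensities in \[0, 255\].
#' @param rescale_factor Ratio applied during row normalisation (1 for an
#'   image in its native size).
#' @return An object of class `"plate_image"` with elements `pixels`,
#'   `n_rows`, `n_cols`, `n_channels`, `rescale_factor`.
#' @export
plate_image <- function(pixels, rescale_factor = 1) {
  if (is.null(dim(pixels)) || length(dim(pixels)) > 3L)
    stop("'pixels' must be a matrix or a rows x cols x 3 array")
  if (length(dim(pixels)) == 3L && dim(pixels)[3L] != 3L)
    stop("multi-channel images must have exactly 3 planes (RGB)")
  if (length(pixels) == 0L)
    stop("empty image")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  structure(
    list(pixels = pixels,
         n_rows = dim(pixels)[1L],
         n_cols = dim(pixels)[2L],
         n_channels = if (length(dim(pixels)) == 3L) 3L else 1L,
         rescale_factor = rescale_factor),
    class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %d x %d, %d channel(s), rescale_factor = %.4g\n",
              x$n_rows, x$n_cols, x$n_channels, x$rescale_factor))
  invisible(x)
}

as_plate_image <- function(x) {
  if (inherits(x, "plate_image")) x else plate_image(x)
}

#' Read a TLC plate image from file
#'
#' Reads PNG, TIFF or JPEG rasters through EBImage. 8-bit and 16-bit inputs
#' are accepted; intensities are mapped linearly to \[0, 255\].
#'
#' @param path Path to the image file.
#' @param crop Optional crop rectangle `c(row0, row1, col0, col1)`, 0-based
#'   half-open (rows `row0 <= r < row1`), applied after reading. Used to
#'   extract the ROI manually when the plate border is present.
#' @return A [plate_image].
#' @export
read_plate <- function(path, crop = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  nd <- length(dim(dat))
  if (nd == 2L) {
    px <- t(dat) * 255           # EBImage stores x (col) first
  } else {
    nch <- dim(dat)[3L]
    if (nch < 3L) {
      px <- t(dat[, , 1L]) * 255
    } else {
      px <- array(0, c(dim(dat)[2L], dim(dat)[1L], 3L))
      for (k in 1:3) px[, , k] <- t(dat[, , k]) * 255
    }
  }
  px[px < 0] <- 0; px[px > 255] <- 255
  out <- plate_image(px)
  if (!is.null(crop)) {
    stopifnot(length(crop) == 4L)
    r <- (crop[1L] + 1L):crop[2L]
    cl <- (crop[3L] + 1L):crop[4L]
    px <- if (out$n_channels == 3L) out$pixels[r, cl, , drop = FALSE]
          else out$pixels[r, cl, drop = FALSE]
    out <- plate_image(px)
  }
  out
}

#' Convert an RGB plate image to grayscale
#'
#' Luminance conversion `0.30 R + 0.59 G + 0.11 B`. A grayscale input is
#' passed through unchanged.
#'
#' @param img A [plate_image].
#' @return A single-channel [plate_image].
#' @examples
#' px <- array(c(200, 100, 50), c(1, 1, 3))
#' rgb_to_gray(plate_image(px))$pixels  # 124.5
#' @export
rgb_to_gray <- function(img) {
  img <- as_plate_image(img)
  if (img$n_channels == 1L) return(img)
  g <- 0.30 * img$pixels[, , 1L, drop = TRUE] +
       0.59 * img$pixels[, , 2L, drop = TRUE] +
       0.11 * img$pixels[, , 3L, drop = TRUE]
  plate_image(matrix(g, img$n_rows, img$n_cols),
              rescale_factor = img$rescale_factor)
}

# Cubic-convolution (Keys, a = -0.5) interpolation weights from n_in input
# pixel centres to n_out output pixel centres, with reflected borders.
# Returns a dense n_out x n_in matrix; rows sum to 1.
cubic_weights <- function(n_in, n_out) {
  a <- -0.5
  kern <- function(t) {
    t <- abs(t)
    ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
           ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
  }
  u <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5   # input coordinate
  i0 <- floor(u)
  W <- matrix(0, n_out, n_in)
  for (off in -1:2) {
    idx <- i0 + off
    w <- kern(u - idx)
    # reflect out-of-range taps about the borders
    idx[idx < 1L] <- 1L - idx[idx < 1L] + 1L
    idx[idx > n_in] <- 2L * n_in - idx[idx > n_in]
    idx[idx < 1L] <- 1L      # degenerate (n_in == 1)
    for (j in seq_len(n_out)) W[j, idx[j]] <- W[j, idx[j]] + w[j]
  }
  W
}

#' Normalise plate height by bicubic rescaling
#'
#' Rescales the plate to a fixed number of rows (default 1024 via
#' [detection_params]) while keeping the columns:rows ratio constant, so
#' that lane and band sizes become comparable across acquisitions of
#' different resolution. Intensities are obtained by bicubic (cubic
#' convolution) interpolation and clipped to \[0, 255\]. An image already at
#' the target height is returned untouched.
#'
#' @param img A [plate_image] (grayscale or RGB).
#' @param target_rows Desired number of rows.
#' @return A [plate_image] with `target_rows` rows,
#'   `round(n_cols * target_rows / n_rows)` columns, and the applied
#'   `rescale_factor` recorded.
#' @export
rescale_image <- function(img, target_rows = 1024L) {
  img <- as_plate_image(img)
  target_rows <- as.integer(target_rows)
  stopifnot(target_rows >= 1L)
  if (img$n_rows == target_rows) return(img)
  f <- target_rows / img$n_rows
  n_cols_out <- max(1L, as.integer(round(img$n_cols * f)))
  Wr <- cubic_weights(img$n_rows, target_rows)
  Wc <- cubic_weights(img$n_cols, n_cols_out)
  resize1 <- function(m) {
    out <- Wr %*% m %*% t(Wc)
    out[out < 0] <- 0; out[out > 255] <- 255
    out
  }
  px <- if (img$n_channels == 3L) {
    arr <- array(0, c(target_rows, n_cols_out, 3L))
    for (k in 1:3) arr[, , k] <- resize1(img$pixels[, , k])
    arr
  } else resize1(img$pixels)
  plate_image(px, rescale_factor = f * img$rescale_factor)
}

reflect_pad <- function(m, k) {
  stopifnot(k < nrow(m), k < ncol(m))
  ri <- c(rev(seq_len(k)), seq_len(nrow(m)), nrow(m) + 1L - seq_len(k))
  ci <- c(rev(seq_len(k)), seq_len(ncol(m)), ncol(m) + 1L - seq_len(k))
  m[ri, ci, drop = FALSE]
}

#' Remove the plate background (and invert lane polarity)
#'
#' The slowly varying background is estimated by a grayscale morphological
#' closing with a flat square structuring element whose side is
#' `round(se_fraction * n_rows)` (forced odd, at least 3), large enough to
#' wipe out the bands. The returned image is `closing(I) - I`, pointwise and
#' clipped at 0: background structure is removed and the dark lanes of the
#' plate become bright, so the later column projection is maximal over
#' lanes. Borders are reflect-padded, which avoids an artificial dark frame
#' that would create spurious edge lanes.
#'
#' @param gray A single-channel [plate_image].
#' @param se_fraction Structuring-element side as a fraction of the row
#'   count (default 0.10).
#' @return A single-channel [plate_image] with nonnegative intensities.
#' @export
remove_background <- function(gray, se_fraction = 0.10) {
  gray <- as_plate_image(gray)
  if (gray$n_channels != 1L) stop("remove_background expects a grayscale image")
  side <- round(se_fraction * gray$n_rows)
  side <- max(3L, as.integer(side))
  if (side %% 2L == 0L) side <- side + 1L
  m <- min(gray$n_rows, gray$n_cols)
  if (side >= m) {
    side <- if ((m - 1L) %% 2L == 1L) m - 1L else m - 2L
    side <- max(3L, side)
    warning("structuring element larger than image; clamped to side ", side)
  }
  pad <- side - 1L               # shields both passes of the closing
  pad <- min(pad, gray$n_rows - 1L, gray$n_cols - 1L)
  p <- reflect_pad(gray$pixels, pad) / 255
  cl <- EBImage::closing(p, EBImage::makeBrush(side, shape = "box"))
  cl <- cl[(pad + 1L):(pad + gray$n_rows),
           (pad + 1L):(pad + gray$n_cols), drop = FALSE] * 255
  out <- cl - gray$pixels
  out[out < 0] <- 0
  plate_image(out, rescale_factor = gray$rescale_factor)
}

#' Project a plate image to its intensity profile
#'
#' Averages grey levels over each image column, excluding a fraction of top
#' rows where TLC plates accumulate compound debris. Applied to the
#' background-removed image, the profile is maximal over lanes and minimal
#' over empty zones.
#'
#' @param enhanced A single-channel [plate_image] (normally the output of
#'   [remove_background]).
#' @param top_exclusion Fraction of top rows excluded (default 0.25;
#'   0 averages every row).
#' @return An object of class `"intensity_profile"`: list with `values`
#'   (one per column) and `source_rows_used` (1-based row interval
#'   averaged).
#' @export
project_profile <- function(enhanced, top_exclusion = 0.25) {
  enhanced <- as_plate_image(enhanced)
  if (enhanced$n_channels != 1L) stop("project_profile expects a grayscale image")
  if (top_exclusion >= 1 || top_exclusion < 0)
    stop("top_exclusion must lie in [0, 1)")
  first <- floor(top_exclusion * enhanced$n_rows) + 1L
  rows <- first:enhanced$n_rows
  structure(
    list(values = colMeans(enhanced$pixels[rows, , drop = FALSE]),
         source_rows_used = c(first, enhanced$n_rows)),
    class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples, rows %d..%d, range [%.3g, %.3g]\n",
              length(x$values), x$source_rows_used[1L], x$source_rows_used[2L],
              min(x$values), max(x$values)))
  invisible(x)
}

profile_values <- function(p) {
  if (inherits(p, "intensity_profile")) p$values else as.numeric(p)
}
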