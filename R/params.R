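#' Detection parameters for TLC lane segmentation
#'
#' Bundles every tunable of the segmentation pipeline. The defaults are the
#' settings used for plates of the DB1 kind (urine/blood chromatograms of
#' variable size and lane count); for plates with many subtle lanes a higher
#' `h_fraction` (0.10) is appropriate.
#'
#' @param target_rows Number of image rows after normalisation. All plates
#'   are rescaled to this height so that lane and band sizes become
#'   comparable across acquisitions. Default 1024.
#' @param se_fraction Side of the square structuring element used for
#'   background estimation, as a fraction of the number of image rows.
#'   Default 0.10; the element must be larger than any band.
#' @param top_exclusion Fraction of top image rows excluded from the column
#'   projection. The top of a TLC plate accumulates compound debris that
#'   corrupts the profile and carries no biomarker information. Default 0.25.
#' @param h_fraction Contrast threshold of the h-maxima/h-minima transforms,
#'   as a fraction of the maximum of the smoothed intensity profile.
#'   Default 0.05.
#' @param omega0 Nondimensional frequency of the Morlet mother wavelet.
#'   Default 6, which satisfies the admissibility condition.
#' @param scale_search_min,scale_search_max Scale interval (the "lane
#'   range") searched for the adaptive reconstruction cut-offs. Defaults 30
#'   and 250, set from the typical spatial distance between lanes.
#' @param scale_grid_max Largest scale actually computed; must be at least
#'   `scale_search_max` so that a local minimum beyond a high-scale maximum
#'   can be located. Default 300.
#' @param recovery_width_fraction Minimum width of a recovered lane as a
#'   fraction of the mean lane width `mlw`. Default 0.60.
#' @param recovery_amplitude_fraction Minimum derivative amplitude swing of
#'   a recovered lane as a fraction of the mean lane amplitude `mla`.
#'   Default 0.30.
#'
#' @return An object of class `"tlc_params"` (a named list).
#' @examples
#' p <- detection_params(h_fraction = 0.10)
#' p$h_fraction
#' @export
detection_params <- function(target_rows = 1024L,
                             se_fraction = 0.10,
                             top_exclusion = 0.25,
                             h_fraction = 0.05,
                             omega0 = 6,
                             scale_search_min = 30,
                             scale_search_max = 250,
                             scale_grid_max = 300,
                             recovery_width_fraction = 0.60,
                             recovery_amplitude_fraction = 0.30) {
  p <- list(
    target_rows = as.integer(target_rows),
    se_fraction = se_fraction,
    top_exclusion = top_exclusion,
    h_fraction = h_fraction,
    omega0 = omega0,
    scale_search_min = scale_search_min,
    scale_search_max = scale_search_max,
    scale_grid_max = scale_grid_max,
    recovery_width_fraction = recovery_width_fraction,
    recovery_amplitude_fraction = recovery_amplitude_fraction
  )
  validate_params(p)
  class(p) <- "tlc_params"
  p
}

validate_params <- function(p) {
  stopifnot(
    p$target_rows >= 1L,
    p$se_fraction > 0, p$se_fraction < 1,
    p$top_exclusion >= 0, p$top_exclusion < 1,
    p$h_fraction > 0, p$h_fraction < 1,
    p$omega0 > 0,
    p$scale_search_min > 0,
    p$scale_search_min < p$scale_search_max,
    p$scale_search_max <= p$scale_grid_max,
    p$recovery_width_fraction > 0,
    p$recovery_amplitude_fraction > 0
  )
  invisible(p)
}

#' @export
print.tlc_params <- function(x, ...) {
  cat("TLC lane detection parameters\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
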