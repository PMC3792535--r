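#' Specification of a synthetic TLC plate
#'
#' Describes a synthetic plate: dark lanes of Gaussian cross-section on a
#' light background, each modulated along the vertical axis by Gaussian
#' band blobs, plus a smooth horizontal illumination gradient, i.i.d.
#' sensor noise, and the stronger compound-debris noise typical of the top
#' rows of real plates. When called with `n_lanes` (and no explicit
#' `lanes`), a randomised but seed-reproducible plate layout is drawn:
#' jittered lane slots at roughly regular spacing, a run of empty lane
#' slots (`n_empty_gaps`), and `n_subtle` low-contrast lanes.
#'
#' @param n_lanes Number of occupied lanes to draw (ignored when `lanes`
#'   is given).
#' @param seed Integer seed; the generated image is fully determined by
#'   the spec, including this seed.
#' @param n_rows,n_cols Image size in pixels. `n_cols` defaults to
#'   `(n_slots + 1) * lane_spacing`.
#' @param lane_spacing Nominal center-to-center lane distance (columns).
#' @param lane_sigma Range of lane cross-section standard deviations
#'   (columns).
#' @param contrast Range of lane contrasts (fraction of full scale) for
#'   regular lanes.
#' @param n_subtle Number of subtle (low-contrast) lanes among `n_lanes`.
#' @param subtle_contrast Contrast range for subtle lanes; a lane with
#'   contrast below 0.3 is flagged subtle in the ground truth.
#' @param n_empty_gaps Number of empty lane slots inserted between
#'   occupied lanes (emulating samples that failed to run).
#' @param background_level Background gray value (0--255).
#' @param gradient_amplitude Peak-to-peak amplitude of the horizontal
#'   illumination gradient (gray values).
#' @param noise_sigma Standard deviation of the i.i.d. noise (gray values).
#' @param top_noise_sigma Additional noise standard deviation applied to
#'   the top 25% of rows.
#' @param texture_amplitude Standard deviation (gray values) of the
#'   column-correlated streak texture: chromatographic development leaves
#'   fine vertical streaks that survive column averaging, giving real
#'   intensity profiles their high-frequency content. Default 3.
#' @param texture_scale Correlation length of the streak texture in
#'   columns. Default 4.
#' @param lanes Optional explicit lane list overriding the randomised
#'   layout; each element is a list with `center` (0-based column),
#'   `sigma`, `contrast`, and `bands` (list of `list(row, sigma,
#'   amplitude)` blobs; amplitudes in \[0, 1\]).
#' @param allow_overlap Permit lanes whose +/- 2 sigma extents overlap.
#' @return An object of class `"plate_spec"`.
#' @export
plate_spec <- function(n_lanes = 10, seed = 1, n_rows = 768, n_cols = NULL,
                       lane_spacing = 90, lane_sigma = c(10, 16),
                       contrast = c(0.6, 1), n_subtle = 1,
                       subtle_contrast = c(0.15, 0.3), n_empty_gaps = 1,
                       background_level = 220, gradient_amplitude = 15,
                       noise_sigma = 2, top_noise_sigma = 20,
                       texture_amplitude = 3, texture_scale = 4,
                       lanes = NULL, allow_overlap = FALSE) {
  empty_gaps <- list()
  if (is.null(lanes)) {
    lanes <- if (n_lanes == 0L) list() else with_seed(seed, {
      n_slots <- n_lanes + n_empty_gaps
      if (is.null(n_cols)) n_cols <- as.integer((n_slots + 1) * lane_spacing)
      slot_centers <- lane_spacing * seq_len(n_slots) +
        round(stats::runif(n_slots, -0.08, 0.08) * lane_spacing)
      gap_at <- if (n_empty_gaps > 0 && n_slots > 2)
        sample(2:(n_slots - 1), n_empty_gaps) else integer()
      occ <- setdiff(seq_len(n_slots), gap_at)
      subtle_at <- if (n_subtle > 0) sample(seq_along(occ), n_subtle) else integer()
      lapply(seq_along(occ), function(i) {
        ctr <- slot_centers[occ[i]]
        sg <- stats::runif(1, lane_sigma[1L], lane_sigma[2L])
        con <- if (i %in% subtle_at)
          stats::runif(1, subtle_contrast[1L], subtle_contrast[2L])
        else stats::runif(1, contrast[1L], contrast[2L])
        nb <- sample(3:5, 1)
        rows <- sort(stats::runif(nb, 0.30, 0.90)) * n_rows
        list(center = ctr, sigma = sg, contrast = con,
             bands = lapply(seq_len(nb), function(b)
               list(row = rows[b],
                    sigma = stats::runif(1, 15, 30),
                    amplitude = stats::runif(1, 0.6, 1))))
      })
    })
    if (is.null(n_cols)) n_cols <- as.integer((n_lanes + n_empty_gaps + 1) * lane_spacing)
  } else if (is.null(n_cols)) {
    n_cols <- as.integer(max(vapply(lanes, function(l)
      l$center + 4 * l$sigma, numeric(1))) + lane_spacing)
  }
  sp <- structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         lanes = lanes, empty_gaps = empty_gaps,
         background_level = background_level,
         gradient_amplitude = gradient_amplitude,
         noise_sigma = noise_sigma, top_noise_sigma = top_noise_sigma,
         texture_amplitude = texture_amplitude,
         texture_scale = texture_scale,
         seed = as.integer(seed), allow_overlap = allow_overlap),
    class = "plate_spec")
  validate_plate_spec(sp)
  sp
}

validate_plate_spec <- function(sp) {
  for (l in sp$lanes) {
    if (l$center < 0 || l$center >= sp$n_cols)
      stop("lane center outside the image")
    if (l$contrast <= 0 || l$contrast > 1)
      stop("lane contrast must lie in (0, 1]")
  }
  if (!sp$allow_overlap && length(sp$lanes) > 1L) {
    ctr <- vapply(sp$lanes, `[[`, numeric(1), "center")
    sg <- vapply(sp$lanes, `[[`, numeric(1), "sigma")
    o <- order(ctr)
    lo <- ctr[o] - 2 * sg[o]
    hi <- ctr[o] + 2 * sg[o]
    if (any(hi[-length(hi)] >= lo[-1L]))
      stop("overlapping lanes; set allow_overlap = TRUE to permit them")
  }
  invisible(sp)
}

# Gaussian smoothing of a vector (reflected borders), kernel sd in samples.
smooth_1d <- function(x, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  xe <- c(rev(x[seq_len(min(r, n))]), x, rev(x[(n - min(r, n) + 1L):n]))
  as.numeric(stats::filter(xe, k, sides = 2))[(r + 1L):(r + n)]
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic TLC plate image with ground truth
#'
#' Renders the plate described by a [plate_spec]: light background with a
#' smooth horizontal gradient, minus one Gaussian stripe per lane modulated
#' by its band blobs, plus i.i.d. noise everywhere and stronger noise in
#' the top quarter of rows; intensities are clipped to \[0, 255\]. The
#' image is fully determined by the spec (including its seed).
#'
#' @param spec A [plate_spec].
#' @return List with `image` (a [plate_image]) and `truth` (class
#'   `"ground_truth"`: 0-based `lane_centers`, `lane_limits` matrix of
#'   +/- 2 sigma extents, `lane_widths`, `subtle_flags`).
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  validate_plate_spec(spec)
  nr <- spec$n_rows; nc <- spec$n_cols
  x <- 0:(nc - 1L); y <- 0:(nr - 1L)
  grad <- if (nc > 1L) spec$gradient_amplitude * ((x / (nc - 1L)) - 0.5) else 0
  img <- matrix(rep(spec$background_level + grad, each = nr), nr, nc)
  for (l in spec$lanes) {
    stripe <- exp(-(x - l$center)^2 / (2 * l$sigma^2))
    modul <- rep(0, nr)
    for (b in l$bands)
      modul <- modul + b$amplitude * exp(-(y - b$row)^2 / (2 * b$sigma^2))
    modul <- pmin(modul, 1)
    img <- img - 255 * l$contrast * outer(modul, stripe)
  }
  img <- img + with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
    top <- seq_len(floor(0.25 * nr))
    if (length(top) && spec$top_noise_sigma > 0)
      noise[top, ] <- noise[top, ] +
        stats::rnorm(length(top) * nc, 0, spec$top_noise_sigma)
    if (spec$texture_amplitude > 0) {
      # vertical development streaks: column-correlated fine-grained
      # texture, constant down each column so it survives the profile
      # projection. High-pass filtered so its energy sits at the fine
      # scales (the "noise range") below the lane scales, as in real
      # scanned plates.
      streak <- stats::rnorm(nc)
      streak <- streak - smooth_1d(streak, spec$texture_scale)
      streak <- streak / stats::sd(streak) * spec$texture_amplitude
      noise <- noise + matrix(streak, nr, nc, byrow = TRUE)
    }
    noise
  })
  img[img < 0] <- 0; img[img > 255] <- 255
  truth_lanes <- Filter(function(l) !isTRUE(l$artifact), spec$lanes)
  centers <- vapply(truth_lanes, `[[`, numeric(1), "center")
  sigmas <- vapply(truth_lanes, `[[`, numeric(1), "sigma")
  contrasts <- vapply(truth_lanes, `[[`, numeric(1), "contrast")
  o <- order(centers)
  limits <- cbind(left = round(centers - 2 * sigmas),
                  right = round(centers + 2 * sigmas))[o, , drop = FALSE]
  truth <- structure(
    list(lane_centers = round(centers[o]),
         lane_limits = limits,
         lane_widths = limits[, "right"] - limits[, "left"] + 1,
         subtle_flags = contrasts[o] < 0.3),
    class = "ground_truth")
  list(image = plate_image(img), truth = truth)
}

#' Match detected lanes against ground truth
#'
#' Greedy one-to-one matching of detected lane centers to ground-truth
#' centers: candidate pairs within `tol` columns are assigned in order of
#' increasing distance, each detection and each truth lane being used at
#' most once. Reports the detection counts together with recall, precision
#' and the F-measure (beta = 1).
#'
#' @param detected A `"tlc_lanes"` object, a lane data.frame, or a numeric
#'   vector of detected centers.
#' @param truth A `"ground_truth"` object or numeric vector of true
#'   centers.
#' @param tol Matching tolerance in columns (default: half the mean
#'   ground-truth lane width, the evaluation convention used throughout).
#' @return An object of class `"lane_match"`: `true_detected`, `missed`,
#'   `false_detected`, `recall`, `precision`, `f1`, and the index pairing.
#' @export
match_lanes <- function(detected, truth, tol = NULL) {
  det <- if (inherits(detected, "tlc_lanes")) detected$lanes$center
         else if (is.data.frame(detected)) detected$center
         else as.numeric(detected)
  tru <- if (inherits(truth, "ground_truth")) truth$lane_centers
         else as.numeric(truth)
  if (is.null(tol)) {
    if (!inherits(truth, "ground_truth"))
      stop("tol is required when truth does not carry lane widths")
    tol <- mean(truth$lane_widths) / 2
  }
  stopifnot(tol > 0)
  nd <- length(det); nt <- length(tru)
  pairs <- NULL
  if (nd > 0L && nt > 0L) {
    dist <- abs(outer(det, tru, `-`))
    cand <- which(dist <= tol, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(dist[cand]), , drop = FALSE]
      used_d <- logical(nd); used_t <- logical(nt)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        r <- cand[i, 1L]; c <- cand[i, 2L]
        if (!used_d[r] && !used_t[c]) {
          used_d[r] <- TRUE; used_t[c] <- TRUE; keep[i] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  recall <- if (nt > 0L) tp / nt else NA_real_
  precision <- if (nd > 0L) tp / nd else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && (recall + precision) > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(
    list(true_detected = tp, missed = nt - tp, false_detected = nd - tp,
         recall = recall, precision = precision, f1 = f1,
         pairs = pairs, tol = tol),
    class = "lane_match")
}

#' @export
print.lane_match <- function(x, ...) {
  cat(sprintf(paste0("<lane_match> TP %d / missed %d / FP %d  ",
                     "(recall %.1f%%, precision %.1f%%, F1 %.1f%%)\n"),
              x$true_detected, x$missed, x$false_detected,
              100 * x$recall, 100 * x$precision, 100 * x$f1))
  invisible(x)
}

#' Subtle-lane fixture plate
#'
#' A nine-lane plate dominated by one intense lane (one sample much more
#' concentrated than the rest, a common situation on real plates), with a
#' very low-contrast lane right next to it. The contrast threshold `h` is
#' keyed to the profile maximum -- here set by the dominant lane -- so the
#' faint neighbour falls below it and is absent from the initial candidate
#' set, while the recovery gates, keyed to the lane-set means, accept it in
#' the third phase. Segment this plate with `h_fraction = 0.10` (the
#' setting for subtle-lane-rich plates); the subtle lane is the fourth
#' from the left.
#'
#' @param seed Integer seed for the rendering noise.
#' @return A [plate_spec]; the subtle lane's true center is
#'   `attr(spec, "subtle_center")`.
#' @export
subtle_plate_spec <- function(seed = 11) {
  lanes <- lapply(1:9, function(i) {
    con <- if (i == 3) 0.85 else if (i == 4) 0.08 else 0.25
    list(center = 90 * i, sigma = 13, contrast = con,
         bands = lapply(c(0.35, 0.5, 0.65, 0.8), function(fr)
           list(row = fr * 768, sigma = 22, amplitude = 0.85)))
  })
  sp <- plate_spec(lanes = lanes, seed = seed, n_rows = 768, n_cols = 900)
  attr(sp, "subtle_center") <- 360
  sp
}

#' Spurious-peak fixture plate
#'
#' A regular nine-lane plate with a faint, narrow smear injected midway
#' between two lanes -- the kind of artifact (spilled sample, plate defect)
#' that produces a false candidate. The smear is strong enough to enter
#' the initial candidate set but is removed by the false-lane rules: its
#' intensity is below half the mean lane intensity and its distance to the
#' adjacent lanes is below the adaptive distance threshold. (The
#' derivative-based recovery step may later re-admit it: a smear shaped
#' like a faint lane is indistinguishable from one in the derivative,
#' which is why a small number of false lanes can survive the full
#' pipeline.) The smear is tagged as an artifact and therefore not part
#' of the ground truth.
#'
#' @param seed Integer seed for the rendering noise; the lane layout and
#'   the smear geometry are fixed.
#' @return A [plate_spec]; the smear's center column is
#'   `attr(spec, "spurious_center")`.
#' @export
spurious_plate_spec <- function(seed = 13) {
  base <- plate_spec(n_lanes = 9, seed = 13, n_empty_gaps = 0, n_subtle = 0)
  ctrs <- sort(vapply(base$lanes, `[[`, numeric(1), "center"))
  pos <- round((ctrs[4] + ctrs[5]) / 2)
  inj <- list(center = pos, sigma = 11, contrast = 0.24,
              bands = lapply(c(0.4, 0.55, 0.7, 0.82), function(fr)
                list(row = fr * 768, sigma = 22, amplitude = 0.85)),
              artifact = TRUE)
  sp <- plate_spec(lanes = c(base$lanes, list(inj)), seed = seed,
                   n_cols = base$n_cols, allow_overlap = TRUE)
  attr(sp, "spurious_center") <- pos
  sp
}

#' Standard battery of synthetic validation plates
#'
#' A reproducible set of plate specifications covering the conditions the
#' segmenter is meant to handle: 8--20 lanes per plate, an empty lane slot
#' on each plate, and one subtle (contrast below 0.3, at least 0.15) lane
#' per plate.
#'
#' @param n_plates Number of plates (default 20).
#' @param seed Integer seed controlling the whole battery.
#' @return List of [plate_spec] objects.
#' @export
fixture_battery <- function(n_plates = 20, seed = 1) {
  n_lanes <- with_seed(seed, sample(8:20, n_plates, replace = TRUE))
  lapply(seq_len(n_plates), function(i)
    plate_spec(n_lanes = n_lanes[i], seed = seed * 1000L + i))
}
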