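# Independent brute-force oracles used across the suite.

# Morphological reconstruction by dilation: iterate elementary geodesic
# dilations (2-neighbour) of the marker under the mask until a fixpoint.
oracle_reconstruction <- function(marker, mask) {
  m <- pmin(marker, mask)
  repeat {
    n <- length(m)
    dil <- pmax(m, c(-Inf, m[-n]), c(m[-1L], -Inf))
    m2 <- pmin(dil, mask)
    if (identical(m2, m)) return(m2)
    m <- m2
  }
}

oracle_h_maxima <- function(f, h) oracle_reconstruction(f - h, f)

# Grayscale closing with a flat square structuring element and reflected
# borders, by direct dilation-then-erosion loops. Small images only.
oracle_closing <- function(img, side) {
  hw <- (side - 1L) %/% 2L
  pad <- function(m, k) {
    ri <- c(rev(seq_len(k)), seq_len(nrow(m)), nrow(m) + 1L - seq_len(k))
    ci <- c(rev(seq_len(k)), seq_len(ncol(m)), ncol(m) + 1L - seq_len(k))
    m[ri, ci, drop = FALSE]
  }
  p <- pad(img, 2L * hw)
  nr <- nrow(img); nc <- ncol(img)
  dil <- matrix(NA_real_, nr + 2L * hw, nc + 2L * hw)
  for (i in seq_len(nrow(dil))) for (j in seq_len(ncol(dil)))
    dil[i, j] <- max(p[i:(i + side - 1L), j:(j + side - 1L)])
  ero <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    ero[i, j] <- min(dil[i:(i + side - 1L), j:(j + side - 1L)])
  ero
}

# Gaussian bump profile on 0-based columns 0..n-1.
gauss_profile <- function(n, centers, heights, sigmas) {
  x <- 0:(n - 1L)
  v <- numeric(n)
  for (i in seq_along(centers))
    v <- v + heights[i] * exp(-(x - centers[i])^2 / (2 * sigmas[i]^2))
  v
}

# One-row lane data.frame in the package's 0-based convention.
make_lane <- function(left, right, intensity = 1, origin = "initial",
                      validated = TRUE) {
  left <- as.integer(left); right <- as.integer(right)
  data.frame(left = left, right = right,
             center = left + (right - left) %/% 2L,
             width = right - left + 1L,
             intensity = intensity, origin = origin, validated = validated,
             stringsAsFactors = FALSE)
}

make_lanes <- function(lefts, rights, intensities = rep(1, length(lefts)),
                       ...) {
  do.call(rbind, lapply(seq_along(lefts), function(i)
    make_lane(lefts[i], rights[i], intensities[i], ...)))
}
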