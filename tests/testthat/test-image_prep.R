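test_that("rgb_to_gray applies the luminance weights", {
  px <- function(r, g, b) plate_image(array(c(r, g, b), c(1, 1, 3)))
  expect_equal(rgb_to_gray(px(255, 255, 255))$pixels[1, 1], 255)
  expect_equal(rgb_to_gray(px(100, 100, 100))$pixels[1, 1], 100)
  expect_equal(rgb_to_gray(px(200, 100, 50))$pixels[1, 1], 124.5)
  gray <- plate_image(matrix(7, 3, 3))
  expect_identical(rgb_to_gray(gray), gray)
  expect_error(plate_image(array(1, c(2, 2, 2))), "3 planes")
})

test_that("plate_image validates its invariants", {
  expect_error(plate_image(matrix(numeric(), 0, 0)), "empty")
  expect_error(plate_image(matrix(-1, 2, 2)), "0, 255")
  expect_error(plate_image(matrix(256, 2, 2)), "0, 255")
})

test_that("rescale_image reaches the target size and preserves content", {
  img <- plate_image(matrix(77, 512, 300))
  out <- rescale_image(img, 1024)
  expect_equal(out$n_rows, 1024L)
  expect_equal(out$n_cols, 600L)
  expect_equal(max(abs(out$pixels - 77)), 0, tolerance = 1e-10)
  expect_equal(out$rescale_factor, 2)

  # an image already at the target height passes through untouched
  same <- plate_image(matrix(runif(1024 * 50) * 255, 1024, 50))
  expect_identical(rescale_image(same, 1024), same)

  # downscaling halves both dimensions
  big <- plate_image(matrix(runif(256 * 100) * 255, 256, 100))
  small <- rescale_image(big, 128)
  expect_equal(dim(small$pixels), c(128L, 50L))
})

test_that("bicubic interpolation is exact on linear ramps", {
  ramp <- outer(seq(0, 200, length.out = 64), seq(0, 1, length.out = 40), `+`)
  out <- rescale_image(plate_image(ramp), 128)
  # interior of the rescaled ramp must still be a plane
  expect_lt(max(abs(diff(out$pixels[5:124, 20], 1, 2))), 1e-8)
  expect_equal(out$pixels[64, 10] - out$pixels[60, 10],
               out$pixels[60, 10] - out$pixels[56, 10], tolerance = 1e-8)
})

test_that("rescale_image preserves the aspect ratio to within one column", {
  for (nr in c(300, 700, 1500)) for (nc in c(211, 640)) {
    out <- rescale_image(plate_image(matrix(0, nr, nc)), 1024)
    expect_lte(abs(out$n_cols - nc * 1024 / nr), 1)
  }
})

test_that("remove_background matches a brute-force closing oracle", {
  set.seed(42)
  img <- matrix(runif(40 * 60) * 255, 40, 60)
  se_fraction <- 0.12                       # round(0.12 * 40) = 5, already odd
  out <- remove_background(plate_image(img), se_fraction)
  ref <- oracle_closing(img, 5L) - img
  ref[ref < 0] <- 0
  expect_equal(out$pixels, ref, tolerance = 1e-10)
})

test_that("background removal inverts a dark stripe and flattens ramps", {
  # constant image is its own closing
  expect_equal(max(remove_background(plate_image(matrix(80, 50, 50)))$pixels), 0)

  # dark vertical stripe narrower than the SE becomes bright, rest ~ 0
  img <- matrix(200, 60, 80)
  img[, 40:42] <- 40
  out <- remove_background(plate_image(img), 0.10)   # SE side 7
  expect_true(all(out$pixels[, 40:42] == 160))
  expect_equal(max(out$pixels[, -(37:45)]), 0)

  # slow horizontal illumination ramp leaves residual below one gray level
  # (the reflected border turns the ramp end into a shallow V whose fill is
  # bounded by slope times half the SE side)
  ramp <- matrix(rep(seq(100, 118, length.out = 90), each = 70), 70, 90)
  expect_lt(max(remove_background(plate_image(ramp), 0.10)$pixels), 1)

  # closing commutes with additive constants
  set.seed(7)
  base <- matrix(runif(50 * 50) * 100, 50, 50)
  a <- remove_background(plate_image(base), 0.1)$pixels
  b <- remove_background(plate_image(base + 50), 0.1)$pixels
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("oversized structuring elements are clamped with a warning", {
  img <- plate_image(matrix(runif(12 * 300) * 255, 12, 300))
  expect_warning(remove_background(img, 0.99), "clamped")
})

test_that("project_profile averages the retained rows", {
  expect_equal(project_profile(plate_image(matrix(13, 40, 7)), 0.25)$values,
               rep(13, 7))

  # the excluded top row carries the only mass
  col4 <- plate_image(matrix(c(10, 0, 0, 0), 4, 1))
  expect_equal(project_profile(col4, 0.25)$values, 0)
  expect_equal(project_profile(col4, 0)$values, 2.5)

  set.seed(9)
  img <- matrix(runif(100 * 50) * 255, 100, 50)
  p <- project_profile(plate_image(img), 0)
  expect_equal(p$values, apply(img, 2, mean))
  expect_equal(p$source_rows_used, c(1L, 100L))

  p25 <- project_profile(plate_image(img), 0.25)
  expect_equal(p25$values, apply(img[26:100, ], 2, mean))

  expect_error(project_profile(plate_image(img), 1), "top_exclusion")
})

test_that("projection is linear in the image", {
  set.seed(3)
  i1 <- matrix(runif(40 * 30) * 100, 40, 30)
  i2 <- matrix(runif(40 * 30) * 100, 40, 30)
  p <- function(m) project_profile(plate_image(m), 0.25)$values
  expect_equal(p(2 * i1 + 0.5 * i2), 2 * p(i1) + 0.5 * p(i2),
               tolerance = 1e-12)
})
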