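test_that("morlet_mother matches its closed form", {
  expect_equal(Re(morlet_mother(0)), pi^(-0.25))
  expect_equal(Im(morlet_mother(0)), 0)
  eta <- seq(-4, 4, by = 0.37)
  for (w0 in c(5, 6, 8))
    expect_equal(Mod(morlet_mother(eta, w0)), pi^(-0.25) * exp(-eta^2 / 2))
  # unit energy (Gaussian normalisation), by quadrature
  en <- stats::integrate(function(e) Mod(morlet_mother(e))^2, -8, 8)$value
  expect_equal(en, 1, tolerance = 1e-6)
})

test_that("cwt_decompose is linear and localises sinusoid scales", {
  z <- cwt_decompose(rep(0, 64), scales = 1:20)
  expect_true(all(Mod(z$coefficients) == 0))
  expect_true(all(z$mean_amplitude == 0))

  x <- 0:999
  for (lam in c(60, 100, 160)) {
    d <- cwt_decompose(cos(2 * pi * x / lam), scales = 1:250)
    s_hat <- d$scales[which.max(d$mean_amplitude)]
    s_pred <- lam * (6 + sqrt(2 + 6^2)) / (4 * pi)
    expect_lt(abs(s_hat - s_pred) / s_pred, 0.10)
  }

  set.seed(5)
  p1 <- runif(128); p2 <- runif(128)
  d1 <- cwt_decompose(p1, 5:40); d2 <- cwt_decompose(p2, 5:40)
  d12 <- cwt_decompose(3 * p1 + 2 * p2, 5:40)
  # transform linearity applies to the mean-removed signals
  expect_equal(d12$coefficients, 3 * d1$coefficients + 2 * d2$coefficients,
               tolerance = 1e-9)

  expect_error(cwt_decompose(runif(64), c(0, 1, 2)), "positive")
  expect_error(cwt_decompose(runif(64), c(3, 2, 5)), "increasing")
  expect_error(cwt_decompose(runif(2), 1:5), "too short")
})

test_that("the periodic transform commutes with circular shifts", {
  set.seed(8)
  x <- runif(64)
  k <- 11L
  xs <- c(x[(64 - k + 1):64], x[1:(64 - k)])
  d <- cwt_decompose(x, 2:30, pad = FALSE)
  ds <- cwt_decompose(xs, 2:30, pad = FALSE)
  shifted <- cbind(d$coefficients[, (64 - k + 1):64], d$coefficients[, 1:(64 - k)])
  expect_equal(ds$coefficients, shifted, tolerance = 1e-9)
  expect_equal(ds$mean_amplitude, d$mean_amplitude, tolerance = 1e-9)
})

test_that("select_cutoffs follows the peak/minimum rules", {
  scales <- 1:500
  # unimodal peak at 120 inside the search range, no further maximum
  uni <- exp(-(scales - 120)^2 / (2 * 40^2))
  b <- select_cutoffs(uni, scales, c(30, 250))
  expect_equal(b$peak_scale, 120)
  expect_equal(b$cutoff_max, 500)
  expect_true(b$max_was_open)
  expect_lt(b$cutoff_min, 120)

  # bimodal: peaks near 100 and 400 separated by a minimum near 60/300
  bim <- exp(-(scales - 100)^2 / (2 * 18^2)) +
         0.6 * exp(-(scales - 400)^2 / (2 * 30^2)) +
         0.9 * exp(-(scales - 20)^2 / (2 * 12^2))
  b2 <- select_cutoffs(bim, scales, c(30, 250))
  expect_equal(b2$peak_scale, 100)
  expect_false(b2$max_was_open)
  # cutoff_min at the dip between the low-scale bump and the main peak
  expect_true(b2$cutoff_min > 20 && b2$cutoff_min < 100)
  # second maximum at 400 only decreases to the grid end afterwards
  expect_equal(b2$cutoff_max, 500)

  # strictly decreasing curve: no interior extrema at all
  b3 <- select_cutoffs(rev(scales) / 500, scales, c(30, 250))
  expect_equal(b3$peak_scale, 30)
  expect_equal(b3$cutoff_min, 1)
  expect_equal(b3$cutoff_max, 500)

  expect_error(select_cutoffs(uni, scales, c(30, 600)), "within")
})

test_that("select_cutoffs is deterministic and always orders its cut-offs", {
  set.seed(12)
  scales <- 1:300
  for (i in 1:20) {
    curve <- abs(stats::filter(rnorm(340), rep(1 / 41, 41), sides = 2))
    curve <- curve[!is.na(curve)][1:300]
    b1 <- select_cutoffs(curve, scales, c(30, 250))
    b2 <- select_cutoffs(curve, scales, c(30, 250))
    expect_identical(b1, b2)
    expect_lt(b1$cutoff_min, b1$cutoff_max)
  }
})

test_that("reconstruction recovers band-limited profiles", {
  t <- 0:799
  x <- 3 * sin(2 * pi * t / 120) + 2 * cos(2 * pi * t / 60) +
       sin(2 * pi * t / 200 + 1) + 50
  d <- cwt_decompose(x, 1:300)
  r <- reconstruct_profile(d, list(cutoff_min = 1, cutoff_max = 300))
  expect_gte(stats::cor(r$values, x), 0.95)

  # a matched band returns a 50-sample sinusoid with its phase and
  # amplitude (within 15%)
  x2 <- sin(2 * pi * t / 50) + 10
  d2 <- cwt_decompose(x2, 1:300)
  r2 <- reconstruct_profile(d2, list(cutoff_min = 30, cutoff_max = 70))
  expect_gte(stats::cor(r2$values, x2), 0.98)
  expect_lt(abs(diff(range(r2$values)) / diff(range(x2)) - 1), 0.15)

  # zero decomposition reconstructs the stored mean
  dz <- cwt_decompose(rep(4, 64), 1:30)
  rz <- reconstruct_profile(dz, list(cutoff_min = 1, cutoff_max = 30))
  expect_equal(rz$values, rep(4, 64), tolerance = 1e-9)

  expect_error(reconstruct_profile(d, list(cutoff_min = 400, cutoff_max = 500)),
               "band")
})

test_that("smoothing a broad bump never invents extra candidate maxima", {
  # the lane band of a single-peak profile has no baseline range to
  # separate, so the upper cut-off is open and all higher scales are kept
  band <- list(cutoff_min = 30, cutoff_max = 300, max_was_open = TRUE)
  for (sigma in c(15, 20, 30, 45)) for (ctr in c(180, 260, 300, 410)) {
    prof <- gauss_profile(600, ctr, 60, sigma) + 5
    d <- cwt_decompose(prof, 1:300)
    lanes <- initial_lane_set(reconstruct_profile(d, band), 0.05)
    expect_equal(nrow(lanes), 1L)
    expect_lt(abs(lanes$center - ctr), sigma)
  }
})
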