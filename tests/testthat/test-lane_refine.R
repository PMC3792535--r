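test_that("lane_statistics matches direct formulas", {
  one <- make_lane(40, 59)
  s1 <- lane_statistics(one, 200)
  expect_equal(s1$m_w, 20)
  expect_equal(s1$std_w, 0)
  expect_equal(s1$border_gaps, c(49, 150))     # center 49 to both ends
  expect_equal(s1$m_d, mean(c(49, 150)))       # border gaps stand in

  three <- make_lanes(c(45, 145, 245), c(55, 155, 255))
  s3 <- lane_statistics(three, 400)
  expect_equal(s3$m_d, 100)
  expect_equal(s3$std_d, 0)

  set.seed(20)
  lanes <- make_lanes(seq(10, 410, by = 100) + sample(0:9, 5),
                      seq(30, 430, by = 100) + sample(0:9, 5),
                      runif(5, 10, 60))
  s <- lane_statistics(lanes, 500)
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(s$m_w, mean(lanes$width))
  expect_equal(s$std_w, psd(lanes$width))
  expect_equal(s$m_i, mean(lanes$intensity))
  expect_equal(s$std_i, psd(lanes$intensity))
  expect_equal(s$m_d, mean(diff(lanes$center)))
  expect_equal(s$std_d, psd(diff(lanes$center)))

  expect_error(lane_statistics(make_lane(1, 2)[0, ], 100), "at least one")
})

test_that("false-lane removal requires low intensity AND a geometry violation", {
  # identical lanes: nothing can fall below half the mean intensity
  reg <- make_lanes(seq(0, 450, 50), seq(20, 470, 50), rep(40, 10))
  st <- lane_statistics(reg, 500)
  expect_equal(nrow(remove_false_lanes(reg, st)), 10L)

  # a faint lane squeezed against a neighbour is removed
  lanes <- rbind(make_lanes(seq(0, 400, 50), seq(20, 420, 50), rep(40, 9)),
                 make_lane(422, 428, 0.2 * 40))
  lanes <- lanes[order(lanes$center), ]
  st2 <- lane_statistics(lanes, 500)
  out <- remove_false_lanes(lanes, st2)
  expect_equal(nrow(out), 9L)
  expect_false(428 %in% out$right)
  expect_true(all(out$validated))

  # faint but with typical width and spacing: kept (conjunction); the
  # faint lane sits in the interior so no border gap shortens its distance
  lanes3 <- make_lanes(seq(0, 450, 50), seq(20, 470, 50),
                       c(rep(40, 4), 5, rep(40, 5)))
  st3 <- lane_statistics(lanes3, 500)
  expect_equal(nrow(remove_false_lanes(lanes3, st3)), 10L)
})

test_that("no lane at or above half the mean intensity is ever removed", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    lefts <- sort(sample(seq(0, 900, 10), n))
    lanes <- make_lanes(lefts, lefts + sample(5:40, n, replace = TRUE),
                        runif(n, 1, 100))
    st <- lane_statistics(lanes, 1000)
    kept <- remove_false_lanes(lanes, st)
    strong <- lanes$center[lanes$intensity >= st$m_i / 2]
    expect_true(all(strong %in% kept$center))
  }
})

test_that("profile_derivative uses central differences", {
  expect_equal(profile_derivative(rep(3, 10))$values, rep(0, 10))
  expect_equal(profile_derivative(2.5 * (0:9))$values, rep(2.5, 10))
  x <- seq(0, 4 * pi, length.out = 400)
  dx <- x[2] - x[1]
  d <- profile_derivative(sin(x))$values / dx
  expect_equal(d[2:399], cos(x[2:399]), tolerance = dx^2 * 2)
  expect_error(profile_derivative(c(1, 2)), "too short")
})

test_that("lane limits land on the inflection points of a Gaussian lane", {
  sigma <- 15
  prof <- gauss_profile(300, 150, 100, sigma)
  d <- profile_derivative(prof)
  lane <- make_lane(140, 160)
  out <- detect_lane_limits(lane, d, c(60, 240))
  expect_lte(abs(out$left - (150 - sigma)), 1)
  expect_lte(abs(out$right - (150 + sigma)), 1)
  expect_lte(abs(out$center - 150), 1)
  expect_false(out$limit_fallback)

  # degenerate window falls back to the candidate region
  out2 <- detect_lane_limits(make_lane(0, 8), profile_derivative(rep(1, 50)),
                             c(30, 20))
  expect_true(out2$limit_fallback)
})

test_that("limits of adjacent overlapping bumps stay in their own windows", {
  prof <- gauss_profile(400, c(170, 230), c(90, 80), c(20, 20))
  d <- profile_derivative(prof)
  lanes <- make_lanes(c(160, 222), c(180, 240))
  out <- tlcseg:::refine_limits(lanes, d, 400)
  expect_lt(out$right[1], out$left[2])
  expect_true(all(out$left <= out$center & out$center <= out$right))
})

test_that("reference values average widths and derivative swings", {
  lanes <- make_lanes(c(10, 100), c(49, 159))
  d <- rep(0, 300)
  d[c(10, 100) + 1] <- c(2, 4)          # derivative at left limits
  d[c(49, 159) + 1] <- c(-2, -2)        # derivative at right limits
  rv <- reference_values(lanes, d)
  expect_equal(rv$mlw, 50)
  expect_equal(rv$mla, mean(c(2 - (-2), 4 - (-2))))
  expect_error(reference_values(lanes[0, ], d), "at least one")
})

test_that("empty_zones complements the validated lanes", {
  z <- empty_zones(make_lanes(c(10, 60), c(20, 80)), 100)
  expect_equal(z$left, c(0, 21, 81))
  expect_equal(z$right, c(9, 59, 99))
  expect_equal(z$width, c(10, 39, 19))
})

test_that("subtle-lane recovery applies both fractional gates", {
  mlw <- 40; mla <- 10
  params <- detection_params()
  base <- gauss_profile(400, 330, 100, 15)   # a strong lane outside the zone

  # faint bump: derivative swing 1.21*A/sigma = 5 (half of mla), distance
  # between derivative extrema 2*sigma = 0.8*mlw -> recovered
  bump <- base + gauss_profile(400, 150, 66, 16)
  d <- profile_derivative(bump)
  zones <- data.frame(left = 80, right = 230, width = 151)
  rec <- recover_subtle_lanes(zones, d, mlw, mla, params, smoothed = bump)
  expect_equal(nrow(rec), 1L)
  expect_lte(abs(rec$center - 150), 3)
  expect_equal(rec$origin, "recovered")
  swing <- d$values[rec$left + 1] - d$values[rec$right + 1]
  expect_gt(swing, 0.3 * mla)
  expect_gt(rec$width, 0.6 * mlw)

  # low-amplitude wiggles below the amplitude gate: nothing recovered
  set.seed(30)
  noise <- base + stats::filter(rnorm(400, 0, 0.5), rep(0.2, 5), circular = TRUE)
  dn <- profile_derivative(as.numeric(noise))
  expect_equal(nrow(recover_subtle_lanes(zones, dn, mlw, mla, params)), 0L)

  # two qualifying bumps in one zone: both recovered
  two <- base + gauss_profile(400, c(120, 200), c(66, 75), c(14, 14))
  d2 <- profile_derivative(two)
  rec2 <- recover_subtle_lanes(zones, d2, mlw, mla, params, smoothed = two)
  expect_equal(nrow(rec2), 2L)
  expect_lt(rec2$right[1], rec2$left[2])

  # zones narrower than mlw are never searched
  expect_equal(nrow(recover_subtle_lanes(
    data.frame(left = 80, right = 110, width = 31), d, mlw, mla, params)), 0L)
})

test_that("recovery is monotone in bump contrast", {
  mlw <- 40; mla <- 10
  params <- detection_params()
  zones <- data.frame(left = 50, right = 250, width = 201)
  recovered <- vapply(seq(20, 80, by = 10), function(a) {
    prof <- gauss_profile(400, 150, a, 16)
    nrow(recover_subtle_lanes(zones, profile_derivative(prof), mlw, mla,
                              params, smoothed = prof)) > 0
  }, logical(1))
  expect_true(all(diff(recovered) >= 0))   # once recovered, stays recovered
})
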