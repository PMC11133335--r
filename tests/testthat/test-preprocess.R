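test_that("moving-average smoothing follows the truncated-window convention", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(smooth_moving_average(x, 1), x)                 # identity
  expect_equal(smooth_moving_average(x, 3), x)                 # linear data
  expect_equal(smooth_moving_average(rep(7, 10), 5), rep(7, 10))

  # interior = centred mean, ends symmetrically truncated
  y <- c(4, 0, 2, 8, 1)
  expect_equal(smooth_moving_average(y, 3), c(4, 2, 10 / 3, 11 / 3, 1))
  expect_equal(smooth_moving_average(y, 5),
               c(4, 2, 3, 11 / 3, 1))

  expect_error(smooth_moving_average(x, 2), "odd")
  expect_error(smooth_moving_average(x, 0), "integer")
  expect_error(smooth_moving_average(x, 7), "length")

  # contraction: smoothed values stay within the input range
  set.seed(31)
  z <- rnorm(500)
  for (w in c(3, 9, 33)) {
    sm <- smooth_moving_average(z, w)
    expect_gte(min(sm), min(z))
    expect_lte(max(sm), max(z))
    expect_length(sm, length(z))
  }

  # tibble interface smooths each channel independently
  rec <- dplyr::bind_rows(
    tibble::tibble(time = 0:4 / 10, channel = "a", value = x),
    tibble::tibble(time = 0:4 / 10, channel = "b", value = y))
  sm <- smooth_moving_average(rec, 3)
  expect_equal(sm$value[sm$channel == "a"], x)
  expect_equal(sm$value[sm$channel == "b"], c(4, 2, 10 / 3, 11 / 3, 1))
})

test_that("change-point detection recovers piecewise-linear structure exactly", {
  # straight line: endpoints only
  line <- generate_piecewise_linear(c(0, 2), c(1, 5), rate = 100)
  cps <- detect_change_points(line, penalty = 0.01)
  expect_equal(nrow(cps), 2)
  expect_equal(cps$time, c(0, 2))

  # single interior knot (V shape)
  v <- generate_piecewise_linear(c(0, 1, 2), c(0, 1, -1), rate = 100)
  cpv <- detect_change_points(v, penalty = 1e-6)
  expect_equal(cpv$time, c(0, 1, 2))
  expect_equal(cpv$value, c(0, 1, -1))

  # 17 grid-aligned knots recovered exactly, zero residual
  fx <- grid_knot_fixture(17, rate = 200, span = 10, seed = 5)
  cp17 <- detect_change_points(fx$data, penalty = 1e-8)
  expect_equal(sort(cp17$time), sort(fx$times), tolerance = 1e-12)
  refit <- approx(cp17$time, cp17$value, xout = fx$data$time)$y
  expect_lt(max(abs(refit - fx$data$value)), 1e-10)

  expect_error(
    detect_change_points(tibble::tibble(time = 0, channel = "a", value = 1),
                         penalty = 1),
    "2 samples")
})

test_that("change-point count is monotone in penalty and bounded", {
  noisy <- generate_piecewise_linear(c(0, 3, 5, 10), c(0, 4, -2, 1),
                                     rate = 100, noise_sd = 0.3, seed = 9)
  counts <- vapply(c(0.01, 0.1, 1, 10, 100), function(pen) {
    nrow(detect_change_points(noisy, penalty = pen))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  capped <- detect_change_points(noisy, penalty = 0.01, max_cps = 7)
  expect_lte(nrow(capped), 7 + 2)
  expect_lte(nrow(detect_change_points(noisy, penalty = 1e-9)),
             nrow(noisy))
})

test_that("interpolation to a shared uniform grid is exact for linear signals", {
  cp <- tibble::tibble(channel = "a", time = c(0, 0.5, 1), value = c(0, 1, 2))
  uni <- interpolate_to_uniform(cp, target_points = 5)
  expect_equal(uni$value, seq(0, 2, by = 0.5))
  expect_equal(attr(uni, "rate"), 4)

  # knots already on the grid are reproduced exactly
  cpg <- tibble::tibble(channel = "a", time = c(0, 0.25, 0.5, 0.75, 1),
                        value = c(1, -3, 0, 2, 5))
  unig <- interpolate_to_uniform(cpg, target_points = 5)
  expect_equal(unig$value, cpg$value)

  # disjoint CP times across channels still give one shared grid
  cp2 <- dplyr::bind_rows(
    tibble::tibble(channel = "a", time = c(0, 0.3, 1), value = c(0, 1, 0)),
    tibble::tibble(channel = "b", time = c(0, 0.7, 1), value = c(2, 0, 2)))
  uni2 <- interpolate_to_uniform(cp2, target_points = 11)
  expect_equal(sum(uni2$channel == "a"), 11)
  expect_equal(sum(uni2$channel == "b"), 11)
  expect_equal(unique(uni2$time[uni2$channel == "a"]),
               unique(uni2$time[uni2$channel == "b"]))

  bad <- dplyr::bind_rows(
    tibble::tibble(channel = "a", time = c(0, 1), value = c(0, 1)),
    tibble::tibble(channel = "b", time = c(0, 2), value = c(0, 1)))
  expect_error(interpolate_to_uniform(bad, 5), "span")
})

test_that("segment + interpolate round-trips noise-free piecewise-linear signals", {
  knot_counts <- c(5, 11, 17)
  for (seed in 1:3) {
    fx <- grid_knot_fixture(knot_counts[[seed]], rate = 150, span = 8, seed = seed)
    cps <- detect_change_points(fx$data, penalty = 1e-8)
    uni <- interpolate_to_uniform(cps, target_points = 400)
    truth <- approx(fx$times, fx$values, xout = unique(uni$time))$y
    expect_lt(max(abs(uni$value - truth)), 1e-10)
    # compression: tens of knots represent thousands of samples
    expect_lt(nrow(cps), nrow(fx$data) / 10)
  }
})
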