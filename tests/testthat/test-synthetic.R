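test_that("stable system construction honours order, radius and seed", {
  # scalar case is forced exactly
  s1 <- generate_state_space_system(1, 1, 1, spectral_radius = 0.5, seed = 99)
  expect_equal(s1$A, matrix(0.5, 1, 1))

  s4 <- generate_state_space_system(4, 2, 3, spectral_radius = 0.9, seed = 7)
  expect_equal(dim(s4$A), c(4L, 4L))
  expect_equal(dim(s4$B), c(4L, 2L))
  expect_equal(dim(s4$C), c(3L, 4L))
  expect_lte(max(Mod(eigen(s4$A)$values)), 0.9 + 1e-12)

  # seed determinism
  again <- generate_state_space_system(4, 2, 3, spectral_radius = 0.9, seed = 7)
  expect_identical(s4, again)

  expect_error(generate_state_space_system(0, 1, 1, 0.5), "order")
  expect_error(generate_state_space_system(2, 1, 1, 1.2), "spectral_radius")
  expect_error(generate_state_space_system(2, 1, 1, 0), "spectral_radius")
})

test_that("prescribed-eigenvalue systems have modal impulse responses", {
  lambdas <- c(0.9, 0.5, 0.1)
  sys <- state_space_system(diag(lambdas), matrix(1, 3, 1), matrix(1, 1, 3))
  y <- impulse_response(sys, 10, as_matrix = TRUE)
  expect_equal(drop(y), modal_sum_response(lambdas, 10), tolerance = 1e-12)
  # independent brute-force matrix powers agree too
  expect_equal(y, matrix_power_response(sys$A, sys$B, sys$C, 10),
               ignore_attr = TRUE, tolerance = 1e-12)

  # eigenvalue placement used through the generator
  g <- generate_state_space_system(3, 1, 1, seed = 5, eigenvalues = lambdas)
  expect_equal(sort(Re(eigen(g$A)$values)), sort(lambdas), tolerance = 1e-12)
})

test_that("impulse response follows the zero-at-k0 convention", {
  s1 <- state_space_system(matrix(0.5), matrix(1), matrix(1))
  expect_equal(drop(impulse_response(s1, 4, as_matrix = TRUE)),
               c(0, 1, 0.5, 0.25))

  sz <- state_space_system(matrix(0, 2, 2), matrix(1:2, 2, 1),
                           matrix(c(1, 0, 0, 1), 2, 2))
  y <- impulse_response(sz, 5, as_matrix = TRUE)
  expect_equal(unname(y[, 1]), c(0, 0))
  expect_equal(unname(y[, 2]), drop(sz$C %*% sz$B))
  expect_true(all(y[, 3:5] == 0))
})

test_that("synthetic LFP generator enforces the phase schedule", {
  zero_cfg <- synthetic_lfp_config(
    n_channels = 2, rate = 50, phase_duration = 2, n_phases = 2,
    true_order_schedule = c(3, 2), amplitude_schedule = c(0, 0),
    noise_sd = 0, trend_knot_count = 0, seed = 4)
  rec <- generate_synthetic_lfp(zero_cfg)
  expect_true(all(rec$value == 0))
  # sample count per phase is exact
  expect_equal(sum(rec$channel == "ch1" & rec$phase == 0), round(50 * 2))
  expect_equal(attr(rec, "phase_boundaries"), c(100, 200))

  cfg <- synthetic_lfp_config(
    n_channels = 2, rate = 100, phase_duration = 4, n_phases = 4,
    true_order_schedule = c(8, 6, 4, 2),
    amplitude_schedule = c(1, 0.6, 0.3, 0.1),
    noise_sd = 0, trend_knot_count = 2, seed = 12)
  rec2 <- generate_synthetic_lfp(cfg)
  rms <- rec2 %>%
    dplyr::group_by(phase) %>%
    dplyr::summarise(rms = sqrt(mean(value^2))) %>%
    dplyr::pull(rms)
  expect_true(all(diff(rms) < 0))

  # bit-identical under the same config
  expect_identical(rec2, generate_synthetic_lfp(cfg))

  expect_error(synthetic_lfp_config(n_phases = 3,
                                    true_order_schedule = c(2, 2),
                                    amplitude_schedule = c(1, 1, 1)),
               "schedules")
})

test_that("phase systems match the schedule and feed the generator deterministically", {
  cfg <- synthetic_lfp_config(
    n_channels = 3, rate = 20, phase_duration = 1, n_phases = 3,
    true_order_schedule = c(6, 4, 2), amplitude_schedule = c(1, 1, 1),
    noise_sd = 0, trend_knot_count = 0, seed = 8)
  sys <- phase_systems(cfg)
  expect_equal(vapply(sys, function(s) s$order, integer(1)), c(6L, 4L, 2L))
  expect_true(all(vapply(sys, function(s)
    max(Mod(eigen(s$A)$values)), numeric(1)) <= cfg$spectral_radius + 1e-12))
  expect_identical(sys, phase_systems(cfg))
})

test_that("piecewise-linear generator interpolates knots exactly", {
  line <- generate_piecewise_linear(c(0, 1), c(0, 1), rate = 10)
  expect_equal(line$value, seq(0, 1, by = 0.1))

  # collinear interior knot changes nothing
  three <- generate_piecewise_linear(c(0, 0.5, 1), c(0, 0.5, 1), rate = 10)
  expect_equal(three$value, line$value)

  fx <- grid_knot_fixture(17, rate = 100, span = 5, seed = 2)
  truth <- approx(fx$times, fx$values, xout = fx$data$time)$y
  expect_equal(fx$data$value, truth, tolerance = 1e-14)

  expect_error(generate_piecewise_linear(c(1, 0), c(0, 1), 10), "increasing")
  # noisy version is seeded
  n1 <- generate_piecewise_linear(c(0, 1), c(0, 1), 10, noise_sd = 0.1, seed = 3)
  n2 <- generate_piecewise_linear(c(0, 1), c(0, 1), 10, noise_sd = 0.1, seed = 3)
  expect_identical(n1, n2)
})

test_that("impulse-response Hankel matrices have numerical rank equal to the order", {
  for (n in c(1, 3, 5)) {
    sys <- generate_state_space_system(n, 1, 1, 0.85, seed = n)
    y <- impulse_response(sys, 6 * n + 1, as_matrix = TRUE)[, -1, drop = FALSE]
    hp <- build_hankel_pair(y, s = 2 * n)
    d <- svd(hp$H, nu = 0, nv = 0)$d
    expect_equal(sum(d > 1e-10 * d[[1]]), n)
  }
})
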