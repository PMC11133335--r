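make_uniform_recording <- function(minutes, rate = 10, channels = c("ch1", "ch2")) {
  m <- round(minutes * 60 * rate)
  out <- tibble::tibble(
    time = rep((seq_len(m) - 1) / rate, each = length(channels)),
    channel = rep(channels, m),
    value = 0)
  attr(out, "rate") <- rate
  out
}

test_that("recordings partition into 5-minute phases", {
  rec35 <- make_uniform_recording(35)
  ph <- partition_phases(rec35)
  expect_equal(sort(unique(ph$phase)), 0:6)           # Pre-CO2 + 6 phases
  expect_true(all(!ph$partial))
  expect_equal(attr(ph, "phase_length"), 3000)
  counts <- table(ph$phase[ph$channel == "ch1"])
  expect_true(all(counts == 3000))

  # a remainder shorter than half a phase is dropped
  ph12 <- partition_phases(make_uniform_recording(12))
  expect_equal(sort(unique(ph12$phase)), 0:1)

  # a longer remainder is kept and flagged
  ph13 <- partition_phases(make_uniform_recording(13))
  expect_equal(sort(unique(ph13$phase)), 0:2)
  expect_true(all(ph13$partial[ph13$phase == 2]))
  expect_false(any(ph13$partial[ph13$phase < 2]))

  # shorter than one phase: single flagged segment
  ph2 <- partition_phases(make_uniform_recording(2))
  expect_equal(unique(ph2$phase), 0L)
  expect_true(all(ph2$partial))
})

test_that("Mann-Whitney enumeration matches theory and brute force", {
  # complete ties: U sits at its mean, p = 1
  tied <- mann_whitney_u(rep(3, 5), rep(3, 5))
  expect_equal(tied$p_value, 1)

  # full separation of 5 vs 5: U = 0, exact p = 2/252
  sep <- mann_whitney_u(1:5, 6:10)
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 2 / 252, tolerance = 1e-12)

  # exact enumeration agrees with an independent brute-force oracle,
  # with and without ties, across group sizes up to 8
  set.seed(66)
  cases <- list(
    list(x = rnorm(4), y = rnorm(6)),
    list(x = rnorm(8), y = rnorm(5) + 1),
    list(x = round(rnorm(6) * 2) / 2, y = round(rnorm(6) * 2) / 2),  # ties
    list(x = c(1, 1, 2, 3), y = c(1, 2, 2, 4))                        # ties
  )
  for (cs in cases) {
    expect_equal(mann_whitney_u(cs$x, cs$y)$p_value,
                 brute_force_mwu_p(cs$x, cs$y), tolerance = 1e-12)
  }

  # no-ties case also agrees with the standard exact test
  x <- c(0.3, 1.2, -0.5, 2.2, 0.9); y <- c(1.9, 2.8, 3.3, 0.1, 2.4)
  expect_equal(mann_whitney_u(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)

  # rank-based: invariant under strictly monotone transforms
  expect_equal(mann_whitney_u(x, y)$p_value,
               mann_whitney_u(exp(x), exp(y))$p_value)

  # large samples switch to the tie-corrected normal approximation
  set.seed(9)
  big <- mann_whitney_u(rnorm(15), rnorm(15) + 2)
  expect_match(big$method, "normal")
  expect_lt(big$p_value, 0.01)
})

test_that("Welch's t-test handles separation, symmetry and degeneracy", {
  set.seed(5)
  jit <- rnorm(4, sd = 1e-6)
  strong <- welch_t(c(0, 0, 0, 0) + jit, c(1, 1, 1, 1) + rnorm(4, sd = 1e-6))
  expect_lt(strong$p_value, 0.001)

  a <- rnorm(6); b <- rnorm(6) + 0.5
  ab <- welch_t(a, b); ba <- welch_t(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$statistic, -ba$statistic)

  deg <- welch_t(rep(2, 4), rep(2, 4))
  expect_true(is.na(deg$p_value))
  expect_match(deg$method, "undefined")
})

test_that("group comparisons run both tests on a phase table", {
  tab <- make_phase_table(mean_a = 60, mean_b = 40, sd = 5, seed = 2)
  res <- compare_groups(tab, phase = 1)
  expect_equal(sort(res$test), c("mann_whitney_u", "welch_t"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(unique(res$phase), 1)

  expect_error(compare_groups(tab[tab$group == "AW", ], phase = 1), "2 groups")
})

test_that("phase-difference test detects differential NS drops", {
  # AN drops by ~100, AW by ~10
  set.seed(77)
  rows <- list()
  for (i in 1:5) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      subject = sprintf("AW%d", i), group = "AW",
      phase = c(1, 2), ns = c(200, 190) + round(rnorm(2, sd = 2)))
    rows[[length(rows) + 1]] <- tibble::tibble(
      subject = sprintf("AN%d", i), group = "AN",
      phase = c(1, 2), ns = c(200, 100) + round(rnorm(2, sd = 2)))
  }
  tab <- dplyr::bind_rows(rows)
  res <- phase_difference_test(tab, 1, 2)
  expect_lt(res$p_value, 0.05)

  # symmetric under group relabelling
  tab2 <- dplyr::mutate(tab, group = ifelse(group == "AW", "AN", "AW"))
  res2 <- phase_difference_test(tab2, 1, 2)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(res2$statistic, -res$statistic, tolerance = 1e-12)

  # identical phases degenerate to an undefined report
  flat <- dplyr::mutate(tab, ns = 100)
  resf <- phase_difference_test(flat, 1, 2)
  expect_true(is.na(resf$p_value))

  expect_error(phase_difference_test(tab[-1, ], 1, 2), "missing phase")
})

test_that("a large NS gap is detected with high power at n = 5 per group", {
  # 4-pooled-SD gap, 5 vs 5: exact two-sided MWU p <= 0.01 in most replicates
  n_rep <- 200
  hits <- 0
  for (seed in seq_len(n_rep)) {
    tab <- make_phase_table(mean_a = 60, mean_b = 40, sd = 5,
                            phases = 1, seed = seed)
    p <- compare_groups(tab, phase = 1)
    hits <- hits + (p$p_value[p$test == "mann_whitney_u"] <= 0.01)
  }
  expect_gte(hits / n_rep, 0.8)
})
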