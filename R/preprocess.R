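#' Moving-average smoothing
#'
#' Centred moving-average filter applied independently to each channel.
#' Every interior point becomes the mean of the odd-length window centred
#' on it; near the boundaries the window is symmetrically truncated to the
#' largest centred odd window that fits, so the first and last samples are
#' returned unchanged and the output length equals the input length.
#'
#' @param data A long recording tibble (`time`, `channel`, `value`) or a
#'   numeric vector.
#' @param window Odd positive window length in samples.
#' @return The same container with smoothed values.
#' @export
smooth_moving_average <- function(data, window = 5) {
  window <- check_count(window, "window")
  if (window %% 2 == 0) abort("`window` must be odd")
  if (is.numeric(data) && is.null(dim(data))) {
    return(ma_smooth_vec(data, window))
  }
  if (!is.data.frame(data)) abort("`data` must be a tibble or numeric vector")
  out <- data %>%
    group_by(.data$channel) %>%
    arrange(.data$time, .by_group = TRUE) %>%
    mutate(value = ma_smooth_vec(.data$value, window)) %>%
    ungroup()
  for (a in c("rate", "phase_boundaries")) {
    attr(out, a) <- attr(data, a)
  }
  out
}

ma_smooth_vec <- function(x, window) {
  m <- length(x)
  if (window > m) abort("`window` cannot exceed the series length")
  if (window == 1) return(x)
  h <- (window - 1) %/% 2
  i <- seq_len(m)
  hi <- pmin(h, i - 1L, m - i)
  cs <- c(0, cumsum(x))
  (cs[i + hi + 1L] - cs[i - hi]) / (2 * hi + 1)
}

#' Detect change points by penalized piecewise-linear segmentation
#'
#' Approximates each channel with a continuous piecewise-linear function
#' whose knots are observed samples ("change points"), targeting the
#' penalized cost `RSS + penalty * (number of interior knots)` by greedy
#' top-down splitting: each segment is a chord between its end knots, the
#' candidate split is the sample with maximum absolute deviation from the
#' chord (earliest sample on ties), and the worst-fitting segment is split
#' first, as long as its chord RSS exceeds the penalty (a segment already
#' fitting better than one knot's cost is never split). The first and last
#' samples are always knots.
#'
#' This is a deterministic stand-in for Bayesian segmented-regression
#' change-point detectors: only knot locations and values are retained, so
#' a long noisy series is compressed to a handful of (time, value) pairs.
#'
#' @param data Long recording tibble (`time`, `channel`, `value`).
#' @param penalty Positive cost per interior knot, in squared signal units.
#' @param max_cps Maximum number of interior knots per channel.
#' @return A tibble of knots with columns `channel`, `time`, `value`,
#'   carrying a named `source_length` attribute (original samples per
#'   channel).
#' @export
detect_change_points <- function(data, penalty, max_cps = Inf) {
  check_positive_scalar(penalty, "penalty")
  if (!is.data.frame(data)) abort("`data` must be a long recording tibble")
  channels <- unique(data$channel)
  src <- integer(0)
  out <- vector("list", length(channels))
  for (ci in seq_along(channels)) {
    d <- data[data$channel == channels[[ci]], ]
    d <- d[order(d$time), ]
    if (nrow(d) < 2) abort("each channel needs at least 2 samples")
    idx <- segment_greedy(d$time, d$value, penalty, max_cps)
    out[[ci]] <- tibble(channel = channels[[ci]],
                        time = d$time[idx], value = d$value[idx])
    src[[as.character(channels[[ci]])]] <- nrow(d)
  }
  res <- bind_rows(out)
  attr(res, "source_length") <- src
  res
}

# Greedy top-down chord splitting, best-first by segment misfit; returns
# sorted knot indices. A segment is split at its maximum-|deviation|
# sample (earliest on ties) while its chord RSS exceeds the penalty: on a
# noise-free piecewise-linear signal the deviation from any chord peaks at
# a true knot, so recursion recovers the knots exactly, and the split
# schedule is penalty-independent, making the knot count monotone in the
# penalty.
segment_greedy <- function(t, y, penalty, max_cps) {
  m <- length(y)
  seg_info <- function(a, b) {
    if (b - a < 2) return(list(a = a, b = b, split = NA_integer_, rss = -Inf))
    ti <- t[a:b]; yi <- y[a:b]
    chord <- yi[1] + (yi[length(yi)] - yi[1]) * (ti - ti[1]) / (ti[length(ti)] - ti[1])
    dev <- yi - chord
    k <- which.max(abs(dev[-c(1, length(dev))])) + 1L  # interior, earliest tie
    list(a = a, b = b, split = a + k - 1L, rss = sum(dev^2))
  }
  infos <- list(seg_info(1L, m))
  knots <- c(1L, m)
  n_interior <- 0L
  while (n_interior < max_cps) {
    rsss <- vapply(infos, function(z) z$rss, numeric(1))
    best <- which.max(rsss)
    if (length(best) == 0 || rsss[[best]] <= penalty) break
    a <- infos[[best]]$a; b <- infos[[best]]$b
    s <- infos[[best]]$split
    knots <- c(knots, s)
    n_interior <- n_interior + 1L
    infos[[best]] <- seg_info(a, s)
    infos[[length(infos) + 1L]] <- seg_info(s, b)
  }
  sort(knots)
}

#' Interpolate per-channel change points to one shared uniform grid
#'
#' Linearly interpolates each channel between its knots and samples all
#' channels on one common uniform grid spanning the shared time interval,
#' yielding the coarse, channel-consistent discretisation consumed by the
#' realization stage. All channels must span the same interval.
#'
#' @param cp_tbl Knot tibble from [detect_change_points()] (columns
#'   `channel`, `time`, `value`).
#' @param target_points Number of uniform grid points (>= 2). The default
#'   3000 gives a 10 Hz grid on a 5-minute phase.
#' @return A long tibble (`time`, `channel`, `value`) with attributes
#'   `rate` (coarse rate in Hz) and `cp_counts` (knots per channel).
#' @export
interpolate_to_uniform <- function(cp_tbl, target_points = 3000) {
  target_points <- check_count(target_points, "target_points", min = 2)
  channels <- unique(cp_tbl$channel)
  spans <- vapply(channels, function(ch) {
    tt <- cp_tbl$time[cp_tbl$channel == ch]
    range(tt)
  }, numeric(2))
  tol <- 1e-9 * max(1, max(abs(spans)))
  if (max(abs(spans[1, ] - spans[1, 1])) > tol ||
      max(abs(spans[2, ] - spans[2, 1])) > tol) {
    abort("all channels must span the same time interval")
  }
  grid <- seq(spans[1, 1], spans[2, 1], length.out = target_points)
  out <- purrr::map(channels, function(ch) {
    d <- cp_tbl[cp_tbl$channel == ch, ]
    tibble(time = grid, channel = ch,
           value = approx(d$time, d$value, xout = grid)$y)
  }) %>% bind_rows() %>% arrange(.data$time, match(.data$channel, channels))
  attr(out, "rate") <- unname((target_points - 1) / (spans[2, 1] - spans[1, 1]))
  attr(out, "cp_counts") <- vapply(
    channels, function(ch) sum(cp_tbl$channel == ch), integer(1))
  out
}
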