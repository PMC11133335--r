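#' Partition a recording into fixed-duration phases
#'
#' Splits a recording into consecutive non-overlapping phases of
#' `phase_duration_s` seconds (phase 0 is the pre-exposure baseline). A
#' trailing remainder shorter than half a phase is dropped; a longer one
#' is kept as an extra phase flagged `partial`. A recording shorter than
#' one phase yields a single flagged segment.
#'
#' @param data Long recording tibble (`time`, `channel`, `value`).
#' @param rate Sampling rate in Hz; taken from the `rate` attribute or
#'   inferred from time stamps when omitted.
#' @param phase_duration_s Phase length in seconds (default 300).
#' @return The input tibble with `phase` (integer, from 0) and `partial`
#'   (logical) columns; dropped remainder samples are removed. The number
#'   of samples per full phase is stored in the `phase_length` attribute.
#' @export
partition_phases <- function(data, rate = NULL, phase_duration_s = 300) {
  if (!is.data.frame(data)) abort("`data` must be a long recording tibble")
  if (is.null(rate)) {
    rate <- attr(data, "rate")
    if (is.null(rate)) rate <- infer_rate(data)
  }
  check_positive_scalar(rate, "rate")
  channels <- unique(data$channel)
  data <- dplyr::arrange(data, .data$time, match(.data$channel, channels))
  m <- nrow(data) / length(channels)
  if (m != round(m)) abort("all channels must have the same number of samples")
  m <- as.integer(m)
  phase_len <- as.integer(round(rate * phase_duration_s))
  n_full <- m %/% phase_len
  rem <- m - n_full * phase_len
  if (n_full == 0) {
    phase_of <- rep(0L, m)
    partial_of <- rep(TRUE, m)
    keep <- rep(TRUE, m)
  } else {
    phase_of <- pmin((seq_len(m) - 1L) %/% phase_len, n_full)  # remainder -> n_full
    partial_of <- phase_of == n_full & rem > 0
    keep <- if (rem > 0 && rem < phase_len / 2) phase_of < n_full else rep(TRUE, m)
  }
  # expand per-sample assignment to the interleaved long layout
  idx <- rep(seq_len(m), each = length(channels))
  out <- data
  out$phase <- phase_of[idx]
  out$partial <- partial_of[idx]
  out <- out[keep[idx], ]
  attr(out, "rate") <- rate
  attr(out, "phase_length") <- phase_len
  out
}

#' Exact-enumeration Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U test using midranks for ties. For combined
#' sample sizes up to `exact_limit` the null distribution of U is obtained
#' by full enumeration of all group assignments (so the p-value is exact
#' even under ties); above that a normal approximation with tie-corrected
#' variance is used. The two-sided p-value is the null probability of a U
#' at least as far from its mean as the observed one.
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact_limit Maximum combined size for exact enumeration
#'   (default 20).
#' @return A one-row tibble: `test`, `statistic` (U for `x`), `p_value`,
#'   `n1`, `n2`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 20) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) abort("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))                        # midranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_limit) {
    picks <- combn(n, n1)
    u_all <- colSums(matrix(r[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      p <- min(1, 2 * stats::pnorm(-abs(u_obs - mu) / sqrt(sigma2)))
    }
    method <- "normal approximation (tie-corrected)"
  }
  tibble(test = "mann_whitney_u", statistic = u_obs, p_value = p,
         n1 = n1, n2 = n2, method = method)
}

#' Welch's unequal-variance t-test (tidy wrapper)
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom.
#' When both groups are essentially constant the test is undefined and
#' reported with `NA` statistics rather than a number.
#'
#' @param x,y Numeric samples for the two groups (>= 2 each).
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `df`,
#'   `n1`, `n2`, `method`.
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) abort("Welch's t-test needs >= 2 values per group")
  res <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    return(tibble(test = "welch_t", statistic = NA_real_, p_value = NA_real_,
                  df = NA_real_, n1 = length(x), n2 = length(y),
                  method = "undefined (essentially constant data)"))
  }
  tibble(test = "welch_t", statistic = unname(res$statistic),
         p_value = res$p.value, df = unname(res$parameter),
         n1 = length(x), n2 = length(y), method = "Welch two-sample t-test")
}

#' Compare groups on a phase-table metric within one phase
#'
#' Runs both the Mann-Whitney U test and Welch's t-test on a per-subject
#' metric (by default the selected Number of Stacks) between the two
#' groups of a phase table.
#'
#' @param phase_table Tibble with columns `subject`, `group`, `phase` and
#'   the metric column.
#' @param phase Phase index to compare.
#' @param metric Metric column name (default `"ns"`).
#' @return A two-row tibble (one per test) with `phase` and `metric`
#'   columns prepended.
#' @export
compare_groups <- function(phase_table, phase, metric = "ns") {
  d <- phase_table[phase_table$phase == phase, ]
  groups <- sort(unique(as.character(d$group)))
  if (length(groups) != 2) abort("the phase table must contain exactly 2 groups")
  x <- d[[metric]][d$group == groups[[1]]]
  y <- d[[metric]][d$group == groups[[2]]]
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty in this phase")
  out <- bind_rows(
    mann_whitney_u(x, y),
    if (length(x) >= 2 && length(y) >= 2) welch_t(x, y)
  )
  out$phase <- phase
  out$metric <- metric
  dplyr::relocate(out, "phase", "metric")
}

#' Between-group test on per-subject phase differences
#'
#' Computes `|metric(phase_a) - metric(phase_b)|` for every subject and
#' compares the two groups on those absolute differences with Welch's
#' t-test — the drop in complexity between two phases compared across
#' groups.
#'
#' @param phase_table Tibble with `subject`, `group`, `phase` and the
#'   metric column; every subject must have both phases.
#' @param phase_a,phase_b Phase indices.
#' @param metric Metric column name (default `"ns"`).
#' @return A one-row tibble as from [welch_t()], with `phase_a`,
#'   `phase_b`, `metric` columns.
#' @export
phase_difference_test <- function(phase_table, phase_a, phase_b, metric = "ns") {
  subjects <- unique(phase_table$subject)
  diffs <- purrr::map(subjects, function(s) {
    a <- phase_table[[metric]][phase_table$subject == s & phase_table$phase == phase_a]
    b <- phase_table[[metric]][phase_table$subject == s & phase_table$phase == phase_b]
    if (length(a) != 1 || length(b) != 1) {
      abort(sprintf("subject %s is missing phase %s or %s", s, phase_a, phase_b))
    }
    g <- unique(phase_table$group[phase_table$subject == s])
    tibble(subject = s, group = g, diff = abs(a - b))
  }) %>% bind_rows()
  groups <- sort(unique(as.character(diffs$group)))
  if (length(groups) != 2) abort("the phase table must contain exactly 2 groups")
  out <- welch_t(diffs$diff[diffs$group == groups[[1]]],
                 diffs$diff[diffs$group == groups[[2]]])
  out$phase_a <- phase_a
  out$phase_b <- phase_b
  out$metric <- metric
  dplyr::relocate(out, "phase_a", "phase_b", "metric")
}
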