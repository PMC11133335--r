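# Internal helpers shared across modules.

# Run `code` with a private RNG stream derived from `seed`; the caller's
# .Random.seed is untouched.
with_rng <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Coerce a recording to a q x m numeric matrix (channels in rows).
#
# Accepts either a numeric matrix (returned as-is, channels assumed in rows)
# or a long tibble with columns `channel` and `value` (and optionally `time`,
# used only for ordering within channel). Channel order follows first
# appearance in the data.
as_series_matrix <- function(data) {
  if (is.matrix(data)) {
    if (!is.numeric(data)) abort("series matrix must be numeric")
    return(data)
  }
  if (is.numeric(data) && is.null(dim(data))) {
    return(matrix(data, nrow = 1))
  }
  if (!is.data.frame(data)) {
    abort("expected a numeric matrix/vector or a data frame with columns `channel` and `value`")
  }
  if (!all(c("channel", "value") %in% names(data))) {
    abort("data frame recording must have columns `channel` and `value`")
  }
  channels <- unique(data$channel)
  if ("time" %in% names(data)) {
    data <- dplyr::arrange(data, match(.data$channel, channels), .data$time)
  }
  counts <- table(factor(data$channel, levels = channels))
  if (length(unique(as.integer(counts))) != 1) {
    abort("all channels must have the same number of samples")
  }
  m <- as.integer(counts[[1]])
  out <- matrix(data$value, nrow = length(channels), ncol = m, byrow = TRUE)
  rownames(out) <- as.character(channels)
  out
}

# Long-format tibble from a q x m matrix.
series_to_tibble <- function(samples, rate, channels = rownames(samples),
                             t0 = 0) {
  q <- nrow(samples)
  m <- ncol(samples)
  if (is.null(channels)) channels <- paste0("ch", seq_len(q))
  tibble(
    time = rep(t0 + (seq_len(m) - 1) / rate, each = q),
    channel = rep(channels, m),
    value = as.vector(samples)
  )
}

# Infer the sampling rate (Hz) from the time stamps of one channel.
infer_rate <- function(data) {
  t <- sort(unique(data$time[data$channel == data$channel[[1]]]))
  if (length(t) < 2) abort("cannot infer a sampling rate from fewer than 2 samples")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    abort("time stamps are not uniformly spaced; supply `rate` explicitly")
  }
  1 / stats::median(dt)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
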