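#' Relative reconstruction error
#'
#' Joint relative Frobenius error over all channels:
#' `||observed - reconstructed||_F / ||observed||_F`. One value per phase,
#' matching the single RelErr annotation reported alongside a selected
#' Number of Stacks.
#'
#' @param observed,reconstructed Same-shape series (matrix or long tibble).
#' @return A non-negative scalar; 0 iff the reconstruction is exact.
#' @export
relative_error <- function(observed, reconstructed) {
  obs <- as_series_matrix(observed)
  rec <- as_series_matrix(reconstructed)
  if (!all(dim(obs) == dim(rec))) abort("observed and reconstructed shapes differ")
  denom <- sqrt(sum(obs^2))
  if (denom == 0) abort("relative error is undefined for an all-zero observed series")
  sqrt(sum((obs - rec)^2)) / denom
}

#' Per-channel reconstruction metrics
#'
#' Mean squared error and Pearson correlation between observed and
#' reconstructed samples, one row per channel. A zero-variance channel has
#' no defined correlation and is reported as `NA` with a note.
#'
#' @param observed,reconstructed Same-shape series (matrix or long tibble).
#' @return A tibble with columns `channel`, `mse`, `corr`, `note`.
#' @export
channel_metrics <- function(observed, reconstructed) {
  obs <- as_series_matrix(observed)
  rec <- as_series_matrix(reconstructed)
  if (!all(dim(obs) == dim(rec))) abort("observed and reconstructed shapes differ")
  labels <- rownames(obs)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(obs)))
  purrr::map(seq_len(nrow(obs)), function(i) {
    o <- obs[i, ]; r <- rec[i, ]
    if (var(o) == 0 || var(r) == 0) {
      tibble(channel = labels[[i]], mse = mean((o - r)^2),
             corr = NA_real_, note = "zero-variance channel: corr undefined")
    } else {
      tibble(channel = labels[[i]], mse = mean((o - r)^2),
             corr = stats::cor(o, r), note = NA_character_)
    }
  }) %>% bind_rows()
}

#' Reconstruction report for one phase
#'
#' Bundles the selected Number of Stacks, rank, strategy, AIC and error
#' metrics of a phase reconstruction into one tidy row plus per-channel
#' detail.
#'
#' @param selection An [select_ns()] result.
#' @param observed The series the selection was run on.
#' @return A `reconstruction_report` list with `summary` (one-row tibble)
#'   and `per_channel` (tibble from [channel_metrics()]).
#' @export
reconstruction_report <- function(selection, observed) {
  stopifnot(inherits(selection, "ns_selection"))
  obs <- as_series_matrix(observed)
  fit <- era_fitted(selection$realization, ncol(obs))
  rownames(fit) <- rownames(obs)
  structure(
    list(
      summary = tibble(
        ns = selection$ns_selected, rank = selection$rank_used,
        strategy = selection$strategy, rel_err = selection$rel_err,
        aic = selection$aic
      ),
      per_channel = channel_metrics(obs, fit)
    ),
    class = "reconstruction_report"
  )
}

#' @export
print.reconstruction_report <- function(x, ...) {
  print(x$summary)
  print(x$per_channel)
  invisible(x)
}

#' Sliding-window power spectrum
#'
#' Splits each channel into sliding windows, removes the window mean, and
#' computes a one-sided rectangular-window periodogram per window, with
#' power also expressed in dB (`10 log10(power + 1e-12)`). Power is
#' normalised so that the sum over frequency bins equals the mean-removed
#' signal energy in the window (Parseval).
#'
#' @param data Long recording tibble or `q x m` matrix.
#' @param rate Sampling rate in Hz; inferred from the `time` column when
#'   omitted.
#' @param window_s Window length in seconds (default 30).
#' @param hop_s Hop between window starts in seconds (default 15, i.e.
#'   50% overlap).
#' @return An `lfp_spectrogram`: a tibble with columns `channel`,
#'   `window`, `time` (window centre, s), `freq` (Hz), `power`,
#'   `power_db`, with `window_s`, `hop_s` and `rate` attributes.
#' @export
windowed_power_spectrum <- function(data, rate = NULL, window_s = 30,
                                    hop_s = window_s / 2) {
  Y <- as_series_matrix(data)
  if (is.null(rate)) {
    rate <- attr(data, "rate")
    if (is.null(rate) && is.data.frame(data)) rate <- infer_rate(data)
    if (is.null(rate)) abort("supply `rate` for matrix input")
  }
  check_positive_scalar(rate, "rate")
  L <- as.integer(round(window_s * rate))
  hop <- max(1L, as.integer(round(hop_s * rate)))
  m <- ncol(Y)
  if (L > m) abort("window is longer than the series")
  if (L < 2) abort("window must contain at least 2 samples")
  starts <- seq(1L, m - L + 1L, by = hop)
  labels <- rownames(Y)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(Y)))
  nyq_bin <- L %/% 2
  freqs <- (0:nyq_bin) * rate / L
  out <- purrr::map(seq_len(nrow(Y)), function(ch) {
    purrr::map(seq_along(starts), function(w) {
      x <- Y[ch, starts[[w]]:(starts[[w]] + L - 1L)]
      x <- x - mean(x)
      X2 <- Mod(fft(x))^2 / L
      pow <- X2[1:(nyq_bin + 1)]
      if (L %% 2 == 0) {
        if (nyq_bin >= 2) pow[2:nyq_bin] <- 2 * pow[2:nyq_bin]  # Nyquist bin not doubled
      } else if (nyq_bin >= 1) {
        pow[2:(nyq_bin + 1)] <- 2 * pow[2:(nyq_bin + 1)]
      }
      tibble(channel = labels[[ch]], window = w,
             time = (starts[[w]] - 1 + (L - 1) / 2) / rate,
             freq = freqs, power = pow,
             power_db = 10 * log10(pow + 1e-12))
    }) %>% bind_rows()
  }) %>% bind_rows()
  attr(out, "window_s") <- window_s
  attr(out, "hop_s") <- hop_s
  attr(out, "rate") <- rate
  class(out) <- c("lfp_spectrogram", class(out))
  out
}

#' Average a spectrogram over windows and/or channels
#'
#' Convenience reduction producing the mean power (recomputed in dB) by
#' frequency, optionally keeping the channel and/or window dimensions.
#'
#' @param spec An [windowed_power_spectrum()] result.
#' @param by Grouping columns kept besides `freq` (default none: average
#'   over both channels and windows).
#' @return A tibble with `freq`, any `by` columns, `power`, `power_db`.
#' @export
summarise_spectrogram <- function(spec, by = character()) {
  spec %>%
    as_tibble() %>%
    group_by(across(all_of(c(by, "freq")))) %>%
    summarise(power = mean(.data$power), .groups = "drop") %>%
    mutate(power_db = 10 * log10(.data$power + 1e-12))
}
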