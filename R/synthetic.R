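#' Construct a discrete-time linear state-space system
#'
#' Bundles the matrices of the system `x[k+1] = A x[k] + B u[k]`,
#' `y[k] = C x[k]` after checking their dimensions for mutual consistency.
#' The state dimension (the system order) is `nrow(A)`.
#'
#' @param A State matrix, `n x n`.
#' @param B Input matrix, `n x p`.
#' @param C Output matrix, `q x n`.
#' @return An object of class `state_space_system` with elements `A`, `B`,
#'   `C`, `order`, `n_inputs`, `n_outputs`.
#' @export
state_space_system <- function(A, B, C) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  if (nrow(A) != ncol(A)) abort("`A` must be square")
  n <- nrow(A)
  if (n < 1) abort("system order must be >= 1")
  if (nrow(B) != n) abort("`B` must have as many rows as `A`")
  if (ncol(C) != n) abort("`C` must have as many columns as `A`")
  structure(
    list(A = A, B = B, C = C,
         order = n, n_inputs = ncol(B), n_outputs = nrow(C)),
    class = "state_space_system"
  )
}

#' @export
print.state_space_system <- function(x, ...) {
  cat(sprintf(
    "<state_space_system> order %d, %d input(s), %d output(s), spectral radius %.4f\n",
    x$order, x$n_inputs, x$n_outputs, max(Mod(eigen(x$A, only.values = TRUE)$values))
  ))
  invisible(x)
}

#' Generate a random stable state-space system
#'
#' Draws a random system whose state matrix has spectral radius exactly
#' `spectral_radius` (strictly inside the unit circle), so that its impulse
#' response decays. The state matrix is a standard-normal draw rescaled by
#' its own spectral radius; `B` and `C` are standard-normal. When
#' `eigenvalues` is supplied, `A` is built by direct eigenvalue placement
#' instead: real eigenvalues become diagonal entries and complex-conjugate
#' pairs become 2x2 rotation-scaling blocks.
#'
#' For `order = 1` the state matrix is exactly `spectral_radius` (the only
#' stable scalar up to sign; the positive root is taken).
#'
#' @param order State dimension, integer >= 1.
#' @param n_inputs,n_outputs Input/output dimensions p and q.
#' @param spectral_radius Target spectral radius, in (0, 1).
#' @param seed Integer seed; identical seeds give identical systems.
#' @param eigenvalues Optional numeric or complex vector of length `order`
#'   (complex values must come in conjugate pairs) overriding the random
#'   state matrix.
#' @return A [state_space_system()].
#' @export
generate_state_space_system <- function(order, n_inputs = 1, n_outputs = 1,
                                        spectral_radius = 0.9, seed = 1,
                                        eigenvalues = NULL) {
  order <- check_count(order, "order")
  n_inputs <- check_count(n_inputs, "n_inputs")
  n_outputs <- check_count(n_outputs, "n_outputs")
  if (!is.numeric(spectral_radius) || length(spectral_radius) != 1 ||
      spectral_radius <= 0 || spectral_radius >= 1) {
    abort("`spectral_radius` must lie strictly between 0 and 1")
  }
  with_rng(seed, {
    if (!is.null(eigenvalues)) {
      if (length(eigenvalues) != order) {
        abort("`eigenvalues` must have length `order`")
      }
      A <- place_eigenvalues(eigenvalues)
    } else if (order == 1) {
      A <- matrix(spectral_radius, 1, 1)
    } else {
      A0 <- matrix(rnorm(order * order), order, order)
      rho <- max(Mod(eigen(A0, only.values = TRUE)$values))
      A <- A0 * (spectral_radius / rho)
    }
    B <- matrix(rnorm(order * n_inputs), order, n_inputs)
    C <- matrix(rnorm(n_outputs * order), n_outputs, order)
    state_space_system(A, B, C)
  })
}

# Real block matrix with the prescribed eigenvalues: real values on the
# diagonal, complex-conjugate pairs as [[re, im], [-im, re]] blocks.
place_eigenvalues <- function(eigenvalues) {
  n <- length(eigenvalues)
  A <- matrix(0, n, n)
  i <- 1L
  used <- rep(FALSE, n)
  pos <- 1L
  ev <- as.complex(eigenvalues)
  while (pos <= n) {
    if (used[pos]) { pos <- pos + 1L; next }
    lam <- ev[pos]
    if (abs(Im(lam)) < 1e-12) {
      A[i, i] <- Re(lam)
      used[pos] <- TRUE
      i <- i + 1L
    } else {
      conj_idx <- which(!used & abs(ev - Conj(lam)) < 1e-10)
      conj_idx <- setdiff(conj_idx, pos)
      if (length(conj_idx) == 0) {
        abort("complex eigenvalues must come in conjugate pairs")
      }
      A[i, i] <- Re(lam); A[i, i + 1L] <- Im(lam)
      A[i + 1L, i] <- -Im(lam); A[i + 1L, i + 1L] <- Re(lam)
      used[c(pos, conj_idx[[1]])] <- TRUE
      i <- i + 2L
    }
  }
  A
}

#' Markov parameters of a state-space system
#'
#' Returns the matrix impulse-response sequence `C A^(k-1) B` for
#' `k = 1, ..., n_steps`, computed by iterated state propagation.
#'
#' @param system A [state_space_system()] or an [era_realize()] result
#'   (any object carrying conformable `A`, `B`, `C`).
#' @param n_steps Number of Markov parameters.
#' @return A numeric array of dimension `q x p x n_steps`.
#' @export
markov_parameters <- function(system, n_steps) {
  if (inherits(system, "era_realization")) {
    system <- state_space_system(system$A, system$B, system$C)
  }
  stopifnot(inherits(system, "state_space_system"))
  n_steps <- check_count(n_steps, "n_steps")
  out <- array(0, dim = c(system$n_outputs, system$n_inputs, n_steps))
  X <- system$B                       # A^(k-1) B at step k
  for (k in seq_len(n_steps)) {
    out[, , k] <- system$C %*% X
    X <- system$A %*% X
  }
  out
}

#' Impulse response of a state-space system
#'
#' Applies a unit impulse on every input channel at `k = 0` with zero
#' initial state, so the output is the zero vector at `k = 0` and
#' `C A^(k-1) B 1` (the Markov parameters summed over inputs) for
#' `k >= 1`.
#'
#' @param system A [state_space_system()].
#' @param m Total number of output samples, covering `k = 0 .. m-1`.
#' @param as_matrix Return a bare `q x m` matrix instead of a tibble.
#' @return A long tibble with columns `time` (the step index k), `channel`
#'   and `value`, or a `q x m` matrix when `as_matrix = TRUE`.
#' @export
impulse_response <- function(system, m, as_matrix = FALSE) {
  stopifnot(inherits(system, "state_space_system"))
  m <- check_count(m, "m")
  q <- system$n_outputs
  Y <- matrix(0, q, m)
  if (m > 1) {
    mk <- markov_parameters(system, m - 1L)
    ones <- rep(1, system$n_inputs)
    for (k in seq_len(m - 1L)) {
      Y[, k + 1L] <- matrix(mk[, , k], nrow = q) %*% ones
    }
  }
  rownames(Y) <- paste0("ch", seq_len(q))
  if (as_matrix) return(Y)
  series_to_tibble(Y, rate = 1)
}

#' Configuration for the synthetic LFP generator
#'
#' Describes a phased multi-channel surrogate recording: an experiment is
#' a sequence of `n_phases` contiguous phases (phase 0 is the pre-exposure
#' baseline) of `phase_duration` seconds each, sampled at `rate` Hz on
#' `n_channels` channels. Each phase is generated as state-space-filtered
#' white noise of the phase's `true_order_schedule` order plus a random
#' piecewise-linear trend, jointly normalised to unit RMS per channel,
#' scaled by the phase's `amplitude_schedule` entry, and finally corrupted
#' with i.i.d. Gaussian measurement noise of standard deviation `noise_sd`.
#'
#' Defaults emulate the study conditions this generator stands in for:
#' 4 channels at 3000 Hz, seven 5-minute phases, with per-phase system
#' order and amplitude both decaying across the exposure.
#'
#' @param n_channels Number of recorded channels.
#' @param rate Sampling rate in Hz.
#' @param phase_duration Phase length in seconds.
#' @param n_phases Number of phases (baseline included).
#' @param true_order_schedule Integer vector, one system order per phase.
#' @param amplitude_schedule Non-negative per-phase RMS scale.
#' @param noise_sd Measurement-noise standard deviation (signal units).
#' @param trend_knot_count Interior knots of the per-phase piecewise-linear
#'   trend; 0 disables the trend.
#' @param trend_scale Relative weight of the trend against the filtered
#'   noise before normalisation.
#' @param spectral_radius Spectral radius of the per-phase generating
#'   systems.
#' @param seed Integer seed fixing all randomness.
#' @return A `synthetic_lfp_config` list.
#' @export
synthetic_lfp_config <- function(n_channels = 4,
                                 rate = 3000,
                                 phase_duration = 300,
                                 n_phases = 7,
                                 true_order_schedule = c(12, 11, 9, 7, 5, 4, 3),
                                 amplitude_schedule = c(1, 0.85, 0.65, 0.45,
                                                        0.3, 0.18, 0.1),
                                 noise_sd = 0.05,
                                 trend_knot_count = 8,
                                 trend_scale = 0.5,
                                 spectral_radius = 0.95,
                                 seed = 1) {
  n_channels <- check_count(n_channels, "n_channels")
  check_positive_scalar(rate, "rate")
  check_positive_scalar(phase_duration, "phase_duration")
  n_phases <- check_count(n_phases, "n_phases")
  if (length(true_order_schedule) != n_phases ||
      length(amplitude_schedule) != n_phases) {
    abort("order and amplitude schedules must have length `n_phases`")
  }
  if (any(true_order_schedule < 1) ||
      any(true_order_schedule != round(true_order_schedule))) {
    abort("`true_order_schedule` entries must be integers >= 1")
  }
  if (any(amplitude_schedule < 0)) {
    abort("`amplitude_schedule` entries must be >= 0")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0")
  check_count(trend_knot_count, "trend_knot_count", min = 0)
  structure(
    list(n_channels = n_channels, rate = rate,
         phase_duration = phase_duration, n_phases = n_phases,
         true_order_schedule = as.integer(true_order_schedule),
         amplitude_schedule = as.numeric(amplitude_schedule),
         noise_sd = noise_sd,
         trend_knot_count = as.integer(trend_knot_count),
         trend_scale = trend_scale,
         spectral_radius = spectral_radius,
         seed = as.integer(seed)),
    class = "synthetic_lfp_config"
  )
}

#' Ground-truth systems behind a synthetic recording
#'
#' The stable state-space system generating each phase of a
#' [generate_synthetic_lfp()] recording, drawn from a seeded stream so the
#' generative "complexity schedule" is recoverable for parameter-recovery
#' studies without regenerating the signal itself.
#'
#' @param config A [synthetic_lfp_config()].
#' @return A list of `n_phases` [state_space_system()] objects (with
#'   `q = p = n_channels`).
#' @export
phase_systems <- function(config) {
  stopifnot(inherits(config, "synthetic_lfp_config"))
  q <- config$n_channels
  with_rng(config$seed, {
    purrr::map(seq_len(config$n_phases), function(ph) {
      n <- config$true_order_schedule[[ph]]
      A0 <- matrix(rnorm(n * n), n)
      rho <- max(Mod(eigen(A0, only.values = TRUE)$values))
      state_space_system(
        A0 * (config$spectral_radius / max(rho, .Machine$double.eps)),
        matrix(rnorm(n * q), n, q),
        matrix(rnorm(q * n), q, n)
      )
    })
  })
}

#' Generate a phased synthetic multi-channel LFP recording
#'
#' See [synthetic_lfp_config()] for the generative model. The per-phase
#' generating systems are the ones returned by [phase_systems()] on the
#' same configuration. The output is reproducible: identical
#' configurations give bit-identical samples.
#'
#' @param config A [synthetic_lfp_config()].
#' @return A long tibble with columns `time` (s), `channel`, `value` and
#'   `phase` (integer, 0 = baseline), with `rate` and `phase_boundaries`
#'   (sample indices delimiting phases) stored as attributes.
#' @export
generate_synthetic_lfp <- function(config) {
  stopifnot(inherits(config, "synthetic_lfp_config"))
  q <- config$n_channels
  m_phase <- as.integer(round(config$rate * config$phase_duration))
  systems <- phase_systems(config)
  signal_seed <- as.integer((as.numeric(config$seed) + 1) %% .Machine$integer.max)
  with_rng(signal_seed, {
    phases <- vector("list", config$n_phases)
    for (ph in seq_len(config$n_phases)) {
      amp <- config$amplitude_schedule[[ph]]
      Y <- matrix(0, q, m_phase)
      if (amp > 0) {
        Y <- filter_white_noise(systems[[ph]], m_phase)
        if (config$trend_knot_count > 0) {
          Y <- Y + config$trend_scale * random_trend(
            q, m_phase, config$trend_knot_count)
        }
        rms <- sqrt(rowMeans(Y^2))
        rms[rms == 0] <- 1
        Y <- amp * Y / rms
      }
      if (config$noise_sd > 0) {
        Y <- Y + matrix(rnorm(q * m_phase, sd = config$noise_sd), q, m_phase)
      }
      phases[[ph]] <- Y
    }
    samples <- do.call(cbind, phases)
    rownames(samples) <- paste0("ch", seq_len(q))
    out <- series_to_tibble(samples, rate = config$rate)
    out$phase <- rep(rep(seq_len(config$n_phases) - 1L, each = m_phase), each = q)
    attr(out, "rate") <- config$rate
    attr(out, "phase_boundaries") <- m_phase * seq_len(config$n_phases)
    out
  })
}

# State-space-filtered white noise: x[k+1] = A x[k] + B w[k], y[k] = C x[k],
# w ~ N(0, I), x[1] = 0.
filter_white_noise <- function(system, m) {
  q <- system$n_outputs
  W <- matrix(rnorm(system$n_inputs * m), system$n_inputs, m)
  Y <- matrix(0, q, m)
  x <- numeric(system$order)
  A <- system$A; B <- system$B; C <- system$C
  for (k in seq_len(m)) {
    Y[, k] <- C %*% x
    x <- A %*% x + B %*% W[, k]
  }
  Y
}

# Per-channel piecewise-linear trend through random interior knots.
random_trend <- function(q, m, n_knots) {
  out <- matrix(0, q, m)
  grid <- seq_len(m)
  for (ch in seq_len(q)) {
    kt <- sort(sample(seq(2L, m - 1L), min(n_knots, m - 2L)))
    kt <- unique(c(1L, kt, m))
    kv <- rnorm(length(kt))
    out[ch, ] <- approx(kt, kv, xout = grid)$y
  }
  out
}

#' Generate a noisy piecewise-linear single-channel signal
#'
#' Samples the continuous piecewise-linear function through the given
#' knots on a uniform grid at `rate` Hz spanning the knot interval, and
#' optionally adds i.i.d. Gaussian noise. Used as ground truth for the
#' change-point stage.
#'
#' @param knot_times Strictly increasing knot times in seconds (>= 2).
#' @param knot_values Knot values, same length.
#' @param rate Sampling rate in Hz.
#' @param noise_sd Gaussian noise standard deviation (0 = noise-free).
#' @param seed Integer seed for the noise.
#' @return A long tibble with columns `time`, `channel`, `value`.
#' @export
generate_piecewise_linear <- function(knot_times, knot_values, rate,
                                      noise_sd = 0, seed = 1) {
  if (length(knot_times) < 2 || length(knot_times) != length(knot_values)) {
    abort("need >= 2 knots with matching times and values")
  }
  if (any(diff(knot_times) <= 0)) abort("`knot_times` must be strictly increasing")
  check_positive_scalar(rate, "rate")
  t_grid <- seq(knot_times[[1]], knot_times[[length(knot_times)]], by = 1 / rate)
  y <- approx(knot_times, knot_values, xout = t_grid)$y
  if (noise_sd > 0) {
    y <- y + with_rng(seed, rnorm(length(y), sd = noise_sd))
  }
  tibble(time = t_grid, channel = "ch1", value = y)
}
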