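# Independent oracles and fixture builders used across the suite.

# Impulse response of a diagonalisable system with unit B and C as a sum of
# geometric modes: y_k = sum_i lambda_i^(k-1), k >= 1 (0 at k = 0).
modal_sum_response <- function(lambdas, m) {
  vapply(seq_len(m) - 1, function(k) {
    if (k == 0) 0 else sum(lambdas^(k - 1))
  }, numeric(1))
}

# Brute-force matrix-power impulse response (independent of the package's
# iterated-state implementation).
matrix_power_response <- function(A, B, C, m) {
  q <- nrow(C)
  out <- matrix(0, q, m)
  Ak <- diag(nrow(A))
  for (k in seq_len(m - 1)) {
    out[, k + 1] <- C %*% Ak %*% B %*% rep(1, ncol(B))
    Ak <- Ak %*% A
  }
  out
}

# Two-sided Mann-Whitney p by brute-force enumeration using direct pairwise
# counting (no ranks): U = #{(i,j): x_i > y_j} + 0.5 #{ties}.
brute_force_mwu_p <- function(x, y) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- u_stat(x, y)
  picks <- utils::combn(length(pooled), n1)
  u_all <- apply(picks, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Greedy multiset match distance between two (possibly complex) eigenvalue
# sets: max over matched pairs of |a - b|.
eig_multiset_error <- function(a, b) {
  a <- as.complex(a); b <- as.complex(b)
  worst <- 0
  for (i in seq_along(a)) {
    j <- which.min(Mod(b - a[[i]]))
    worst <- max(worst, Mod(b[[j]] - a[[i]]))
    b <- b[-j]
  }
  worst
}

# A grid-aligned multi-knot piecewise-linear fixture: knots fall exactly on
# the sampling grid so the sampled sequence is piecewise-linear in the
# discrete sense.
grid_knot_fixture <- function(n_knots, rate = 200, span = 10, seed = 1) {
  stopifnot(n_knots >= 2)
  withr::with_seed(seed, {
    interior <- sort(sample(seq_len(span * rate - 1), n_knots - 2)) / rate
    kt <- c(0, interior, span)
    kv <- rnorm(n_knots)
    list(times = kt, values = kv,
         data = generate_piecewise_linear(kt, kv, rate = rate))
  })
}

# Synthetic phase table for two groups with a prescribed NS gap.
make_phase_table <- function(mean_a, mean_b, sd = 5, n = 5, phases = 0:2,
                             seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (ph in phases) {
      for (i in seq_len(n)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = sprintf("A%d", i), group = "AW", phase = ph,
          ns = round(rnorm(1, mean_a, sd)))
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = sprintf("B%d", i), group = "AN", phase = ph,
          ns = round(rnorm(1, mean_b, sd)))
      }
    }
    dplyr::bind_rows(rows)
  })
}
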