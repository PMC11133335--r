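#' Build the shifted block-Hankel pair of a measurement sequence
#'
#' Organises the samples `y_1, ..., y_m` (the leading `k = 0` sample is a
#' structural zero and is never included) into the two block-Hankel
#' matrices used by the Eigensystem Realization Algorithm: block `(i, j)`
#' of `H` is `y_(i+j-1)` and of `H'` is `y_(i+j)`, for `i = 1..s` block
#' rows ("stacks") and `j = 1..m-s` block columns.
#'
#' @param data A recording — long tibble (`time`, `channel`, `value`) or
#'   `q x m` numeric matrix (each sample a `q x 1` block) — or a
#'   `q x p x m` array of matrix Markov parameters.
#' @param s Number of stacks (block rows), `1 <= s <= m - 2`.
#' @return A `hankel_pair` with elements `H`, `H_shift`, `s`, `q`, `p`, `m`.
#' @export
build_hankel_pair <- function(data, s) {
  if (is.array(data) && length(dim(data)) == 3) {
    Y <- data
  } else {
    Ymat <- as_series_matrix(data)
    Y <- array(Ymat, dim = c(nrow(Ymat), 1L, ncol(Ymat)))
  }
  q <- dim(Y)[1]; p <- dim(Y)[2]; m <- dim(Y)[3]
  s <- check_count(s, "s")
  if (s > m - 2) {
    abort(sprintf("`s` must lie in [1, %d] for a series of %d samples", m - 2, m))
  }
  Yflat <- matrix(Y, nrow = q)          # q x (p*m), block k in cols (k-1)p+1..kp
  ncols <- m - s
  H <- matrix(0, s * q, ncols * p)
  Hs <- matrix(0, s * q, ncols * p)
  for (i in seq_len(s)) {
    rows <- (i - 1L) * q + seq_len(q)
    H[rows, ] <- Yflat[, ((i - 1L) * p + 1L):((i - 1L + ncols) * p), drop = FALSE]
    Hs[rows, ] <- Yflat[, (i * p + 1L):((i + ncols) * p), drop = FALSE]
  }
  structure(list(H = H, H_shift = Hs, s = s, q = q, p = p, m = m),
            class = "hankel_pair")
}

#' @export
print.hankel_pair <- function(x, ...) {
  cat(sprintf("<hankel_pair> s = %d stacks, H is %d x %d (q = %d, p = %d, m = %d)\n",
              x$s, nrow(x$H), ncol(x$H), x$q, x$p, x$m))
  invisible(x)
}

#' Eigensystem Realization Algorithm
#'
#' Computes the rank-`r` truncated SVD `H ~ U_r S_r V_r'` of the Hankel
#' matrix and the reduced realization
#' `A_r = S_r^(-1/2) U_r' H' V_r S_r^(-1/2)`,
#' `B_r` = first `p` columns of `S_r^(1/2) V_r'`,
#' `C_r` = first `q` rows of `U_r S_r^(1/2)`.
#' The SVD sign convention is fixed (largest-magnitude entry of every left
#' singular vector made non-negative) so identical inputs give identical
#' realizations.
#'
#' @param hankel_pair A [build_hankel_pair()] result.
#' @param r Truncation rank. `NULL` (default) uses the numerical rank of
#'   `H` — the number of singular values above `rank_tol` times the
#'   largest — optionally capped by `r_max`. An explicit `r` above the
#'   numerical rank is an error.
#' @param rank_tol Relative singular-value tolerance for the numerical rank.
#' @param r_max Optional cap on the automatic rank.
#' @return An `era_realization` with elements `A`, `B`, `C`, `r`, `s`,
#'   `q`, `p`, `singular_values` (full spectrum of `H`) and
#'   `numerical_rank`.
#' @export
era_realize <- function(hankel_pair, r = NULL, rank_tol = 1e-10, r_max = Inf) {
  stopifnot(inherits(hankel_pair, "hankel_pair"))
  H <- hankel_pair$H
  sv <- svd(H)
  # deterministic sign convention
  for (j in seq_along(sv$d)) {
    piv <- which.max(abs(sv$u[, j]))
    if (sv$u[piv, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  num_rank <- sum(sv$d > rank_tol * sv$d[[1]])
  if (num_rank < 1) abort("Hankel matrix is numerically zero; nothing to realize")
  if (is.null(r)) {
    r <- min(num_rank, r_max)
  } else {
    r <- check_count(r, "r")
    if (r > num_rank) {
      abort(sprintf("requested rank %d exceeds the numerical rank %d of H", r, num_rank))
    }
  }
  Ur <- sv$u[, seq_len(r), drop = FALSE]
  Vr <- sv$v[, seq_len(r), drop = FALSE]
  sr <- sv$d[seq_len(r)]
  s_inv_half <- 1 / sqrt(sr)
  s_half <- sqrt(sr)
  A <- (s_inv_half * (crossprod(Ur, hankel_pair$H_shift) %*% Vr)) *
    rep(s_inv_half, each = r)
  # A above: diag(s^-1/2) %*% M %*% diag(s^-1/2); row scaling then col scaling
  B <- (s_half * t(Vr))[, seq_len(hankel_pair$p), drop = FALSE]
  C <- (Ur %*% diag(s_half, r))[seq_len(hankel_pair$q), , drop = FALSE]
  structure(
    list(A = A, B = B, C = C, r = r, s = hankel_pair$s,
         q = hankel_pair$q, p = hankel_pair$p,
         singular_values = sv$d, numerical_rank = num_rank),
    class = "era_realization"
  )
}

#' @export
print.era_realization <- function(x, ...) {
  cat(sprintf("<era_realization> rank %d (numerical rank %d), %d stacks, q = %d, p = %d\n",
              x$r, x$numerical_rank, x$s, x$q, x$p))
  invisible(x)
}

#' Reconstruct a measurement sequence from a realization
#'
#' Generates the impulse response of the identified system: the first
#' output sample (`k = 0`) is the zero vector and sample `k >= 1` is
#' `C_r A_r^(k-1) B_r`, collapsed to `q` channels (summed over inputs when
#' `p > 1`). States are propagated iteratively — no explicit matrix powers
#' — and if the state norm exceeds `norm_ceiling` the reconstruction
#' aborts with an instability diagnostic instead of returning non-finite
#' values.
#'
#' @param realization An [era_realize()] result.
#' @param m Total number of output samples (including the `k = 0` zero).
#' @param norm_ceiling State-norm guard for unstable realizations.
#' @return A `q x m` numeric matrix.
#' @export
reconstruct <- function(realization, m, norm_ceiling = NULL) {
  stopifnot(inherits(realization, "era_realization"))
  m <- check_count(m, "m")
  fitted <- era_fitted(realization, m - 1L, norm_ceiling = norm_ceiling)
  out <- cbind(matrix(0, realization$q, 1), fitted)
  rownames(out) <- paste0("ch", seq_len(realization$q))
  out
}

# Fitted Markov sequence y_1..y_n (no leading zero), q x n.
era_fitted <- function(realization, n_steps, norm_ceiling = NULL) {
  q <- realization$q
  if (n_steps == 0) return(matrix(0, q, 0))
  if (is.null(norm_ceiling)) {
    norm_ceiling <- 1e12 * max(1, sqrt(sum(realization$B^2)))
  }
  ones <- rep(1, realization$p)
  x <- realization$B %*% ones
  A <- realization$A; C <- realization$C
  out <- matrix(0, q, n_steps)
  for (k in seq_len(n_steps)) {
    out[, k] <- C %*% x
    x <- A %*% x
    if (k < n_steps && sqrt(sum(x^2)) > norm_ceiling) {
      abort(
        sprintf("unstable realization: state norm exceeded %.3g at step %d",
                norm_ceiling, k),
        class = "eralfp_instability"
      )
    }
  }
  out
}
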