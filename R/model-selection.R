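#' Akaike Information Criterion for a reconstruction
#'
#' Gaussian-likelihood AIC of a reconstructed series:
#' `N * log(RSS / N + eps) + 2 * n_params`, where `N` is the total number
#' of scalar observations, `RSS` the sum of squared residuals, and
#' `eps = 1e-300` keeps perfect reconstructions finite.
#'
#' @param observed,reconstructed Same-shape series (matrix or long tibble).
#' @param n_params Number of free model parameters.
#' @return A single AIC value (lower is better).
#' @export
compute_aic <- function(observed, reconstructed, n_params) {
  obs <- as_series_matrix(observed)
  rec <- as_series_matrix(reconstructed)
  if (!all(dim(obs) == dim(rec))) abort("observed and reconstructed shapes differ")
  n <- length(obs)
  if (n == 0) abort("empty series")
  rss <- sum((obs - rec)^2)
  n * log(rss / n + 1e-300) + 2 * n_params
}

#' Coarse power-of-two grid of Number-of-Stacks candidates
#'
#' Candidates `2^k` for `k` in `k_min..k_max`, intersected with the
#' validity interval `[1, m - 2]` of a length-`m` series.
#'
#' @param m Series length (samples).
#' @param k_min,k_max Exponent range (defaults 1 and 13).
#' @return Integer vector of candidate stack counts.
#' @export
ns_coarse_grid <- function(m, k_min = 1, k_max = 13) {
  m <- check_count(m, "m", min = 4)
  k_min <- check_count(k_min, "k_min"); k_max <- check_count(k_max, "k_max")
  cand <- 2^(k_min:k_max)
  cand <- cand[cand >= 1 & cand <= m - 2]
  if (length(cand) == 0) abort("no valid stack-count candidates for this series length")
  as.integer(cand)
}

#' Select the Number of Stacks for one phase
#'
#' Chooses the Hankel block-row count (Number of Stacks, NS) used to
#' realize a series, via three nested strategies:
#'
#' 1. `min_aic` — AIC is evaluated on the coarse `2^k` grid
#'    ([ns_coarse_grid()]), then refined around the minimiser by
#'    step-halving down to unit steps; the AIC-minimising NS is accepted
#'    if its relative reconstruction error is at most `rel_err_accept`.
#' 2. `neighboring` — otherwise NS* +/- 10 (clipped to validity) are
#'    evaluated and the lower-RelErr one is accepted under the same gate.
#' 3. `distant` — otherwise candidates expand outward from NS* in steps
#'    of 10 until the evaluation budget is exhausted, and the NS with the
#'    smallest relative error among all evaluated candidates is returned.
#'
#' Reconstructions that blow up (unstable identified dynamics) score
#' infinite AIC/RelErr and are skipped. AIC ties go to the smallest NS.
#'
#' @param data Series for one phase: long tibble or `q x m` matrix.
#' @param k_min,k_max Coarse-grid exponent range.
#' @param rel_err_accept Relative-error acceptance gate for stages 1-2
#'   (stand-in for visual inspection of the reconstruction).
#' @param rank_tol,r_max Rank policy passed to [era_realize()].
#' @param distant_budget Maximum number of stage-3 evaluations.
#' @param refine Refine around the coarse-grid minimiser (default TRUE).
#' @return An `ns_selection` with fields `ns_selected`, `strategy`,
#'   `aic_curve` (tibble: ns, aic, rel_err, rank), `rel_err`, `rank_used`,
#'   `aic`, and the selected `realization`.
#' @export
select_ns <- function(data, k_min = 1, k_max = 13, rel_err_accept = 0.25,
                      rank_tol = 1e-10, r_max = 20, distant_budget = 50,
                      refine = TRUE) {
  Y <- as_series_matrix(data)
  q <- nrow(Y); m <- ncol(Y)
  grid <- ns_coarse_grid(m, k_min, k_max)

  cache <- new.env(parent = emptyenv())
  eval_ns <- function(s) {
    key <- as.character(s)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- tryCatch({
      hp <- build_hankel_pair(Y, s)
      rl <- era_realize(hp, rank_tol = rank_tol, r_max = r_max)
      fit <- era_fitted(rl, m)
      n_params <- rl$r^2 + rl$r * rl$p + q * rl$r
      # reconstructions exact to machine precision are indistinguishable:
      # score them all at the RSS = 0 floor so AIC ties break by parsimony
      # instead of by log of numerical noise
      rss <- sum((Y - fit)^2)
      aic <- if (rss <= 1e-24 * sum(Y^2)) {
        compute_aic(Y, Y, n_params)
      } else {
        compute_aic(Y, fit, n_params)
      }
      list(ns = s,
           aic = aic,
           rel_err = relative_error(Y, fit),
           rank = rl$r, realization = rl)
    }, error = function(e) {
      list(ns = s, aic = Inf, rel_err = Inf, rank = NA_integer_,
           realization = NULL)
    })
    cache[[key]] <- res
    res
  }
  evaluated <- function() {
    keys <- sort(as.integer(ls(cache)))
    purrr::map(as.character(keys), function(k) cache[[k]])
  }
  best_aic <- function() {
    evs <- evaluated()
    aics <- vapply(evs, function(z) z$aic, numeric(1))
    nss <- vapply(evs, function(z) z$ns, numeric(1))
    ok <- is.finite(aics)
    if (!any(ok)) {
      abort("no stack-count candidate produced a finite AIC; series may be degenerate")
    }
    nss <- nss[ok]; aics <- aics[ok]
    nss[which.min(aics)]        # evaluated() is ns-ascending: ties -> smallest
  }

  for (s in grid) eval_ns(s)

  # step-halving refinement inside the bracket around the coarse minimiser
  if (refine) {
    ns_star <- best_aic()
    i <- match(ns_star, grid)
    lo <- if (!is.na(i) && i > 1) grid[i - 1] else max(1, ns_star %/% 2)
    hi <- if (!is.na(i) && i < length(grid)) grid[i + 1] else min(m - 2, ns_star * 2)
    step <- max(1L, as.integer((hi - lo) %/% 4))
    current <- ns_star
    while (step >= 1) {
      for (cand in c(current - step, current + step)) {
        if (cand >= max(1, lo) && cand <= min(hi, m - 2)) eval_ns(as.integer(cand))
      }
      current <- best_aic()
      if (step == 1) break
      step <- step %/% 2L
    }
  }

  ns_star <- best_aic()
  res_star <- eval_ns(ns_star)

  finish <- function(choice, strategy) {
    evs <- evaluated()
    curve <- tibble(
      ns = vapply(evs, function(z) as.integer(z$ns), integer(1)),
      aic = vapply(evs, function(z) z$aic, numeric(1)),
      rel_err = vapply(evs, function(z) z$rel_err, numeric(1)),
      rank = vapply(evs, function(z) as.integer(z$rank), integer(1))
    )
    structure(
      list(ns_selected = as.integer(choice$ns), strategy = strategy,
           aic_curve = curve, rel_err = choice$rel_err, aic = choice$aic,
           rank_used = choice$rank, realization = choice$realization,
           ns_star = as.integer(ns_star), rel_err_accept = rel_err_accept),
      class = "ns_selection"
    )
  }

  if (res_star$rel_err <= rel_err_accept) {
    return(finish(res_star, "min_aic"))
  }

  neigh <- unique(pmax(1L, pmin(as.integer(m - 2), c(ns_star - 10L, ns_star + 10L))))
  neigh <- setdiff(neigh, ns_star)
  neigh_res <- purrr::map(neigh, eval_ns)
  if (length(neigh_res) > 0) {
    rels <- vapply(neigh_res, function(z) z$rel_err, numeric(1))
    best_n <- neigh_res[[which.min(rels)]]
    if (best_n$rel_err <= rel_err_accept) {
      return(finish(best_n, "neighboring"))
    }
  }

  offsets <- 10L * seq(2L, 1L + max(1L, distant_budget %/% 2))
  n_done <- 0L
  for (off in offsets) {
    for (cand in c(ns_star - off, ns_star + off)) {
      if (cand >= 1 && cand <= m - 2) {
        eval_ns(as.integer(cand))
        n_done <- n_done + 1L
      }
    }
    if (n_done >= distant_budget) break
  }
  evs <- evaluated()
  rels <- vapply(evs, function(z) z$rel_err, numeric(1))
  if (!any(is.finite(rels))) {
    abort("no stack-count candidate produced a finite reconstruction")
  }
  finish(evs[[which.min(rels)]], "distant")
}

#' @export
print.ns_selection <- function(x, ...) {
  cat(sprintf("<ns_selection> NS = %d (strategy %s), rank %s, RelErr %.4g, %d candidates evaluated\n",
              x$ns_selected, x$strategy, as.character(x$rank_used),
              x$rel_err, nrow(x$aic_curve)))
  invisible(x)
}
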