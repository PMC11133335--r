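#' Tidy a Number-of-Stacks selection
#'
#' Returns the audit trail: every evaluated candidate with its AIC,
#' relative error and rank, flagged with the selected row.
#'
#' @param x An [select_ns()] result.
#' @param ... Unused.
#' @return A tibble with columns `ns`, `aic`, `rel_err`, `rank`,
#'   `selected`.
#' @method tidy ns_selection
#' @export
tidy.ns_selection <- function(x, ...) {
  mutate(x$aic_curve, selected = .data$ns == x$ns_selected)
}

#' @rdname tidy.ns_selection
#' @method glance ns_selection
#' @export
glance.ns_selection <- function(x, ...) {
  tibble(ns = x$ns_selected, strategy = x$strategy, rank = x$rank_used,
         rel_err = x$rel_err, aic = x$aic, ns_star = x$ns_star,
         n_evaluated = nrow(x$aic_curve))
}

#' Tidy an ERA realization
#'
#' One row per identified mode: the eigenvalues of the reduced state
#' matrix with magnitude (decay per step) and the corresponding Hankel
#' singular value.
#'
#' @param x An [era_realize()] result.
#' @param ... Unused.
#' @return A tibble with columns `mode`, `re`, `im`, `magnitude`,
#'   `singular_value`.
#' @method tidy era_realization
#' @export
tidy.era_realization <- function(x, ...) {
  ev <- eigen(x$A, only.values = TRUE)$values
  ev <- ev[order(-Mod(ev))]
  tibble(mode = seq_along(ev), re = Re(ev), im = Im(ev),
         magnitude = Mod(ev),
         singular_value = x$singular_values[seq_along(ev)])
}

#' @rdname tidy.era_realization
#' @method glance era_realization
#' @export
glance.era_realization <- function(x, ...) {
  tibble(rank = x$r, ns = x$s, n_outputs = x$q, n_inputs = x$p,
         numerical_rank = x$numerical_rank,
         spectral_radius = max(Mod(eigen(x$A, only.values = TRUE)$values)))
}

#' @method autoplot ns_selection
#' @export
autoplot.ns_selection <- function(object, ...) {
  d <- tidy(object)
  d <- d[is.finite(d$aic), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ns, y = .data$aic)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red"), guide = "none") +
    ggplot2::labs(x = "Number of stacks (log scale)", y = "AIC",
                  title = sprintf("NS selection: NS = %d (%s)",
                                  object$ns_selected, object$strategy))
}

#' @method autoplot lfp_spectrogram
#' @export
autoplot.lfp_spectrogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$freq,
                               fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_viridis_c(name = "Power (dB)") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)")
}

#' Plot a reconstruction against the observed series
#'
#' Observed samples in black, the realization's impulse-response
#' reconstruction in red, one facet per channel.
#'
#' @param observed Long tibble or `q x m` matrix for one phase.
#' @param realization An [era_realize()] result fitted to that series.
#' @return A ggplot object.
#' @export
plot_reconstruction <- function(observed, realization) {
  obs <- as_series_matrix(observed)
  fit <- era_fitted(realization, ncol(obs))
  rownames(fit) <- rownames(obs)
  d <- bind_rows(
    mutate(series_to_tibble(obs, rate = 1), kind = "observed"),
    mutate(series_to_tibble(fit, rate = 1), kind = "reconstruction")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = .data$kind)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(observed = "black",
                                            reconstruction = "red")) +
    ggplot2::labs(x = "Sample", y = "Value", colour = NULL)
}
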