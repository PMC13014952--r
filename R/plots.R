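#' Plot a synthetic-control fit
#'
#' Two-panel style display: observed and synthetic trajectories, with the
#' treatment month marked. Use [plot_gap()] for the gap alone.
#'
#' @param object An `scm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scm_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$series[, c("month", "observed", "synthetic")],
    c("observed", "synthetic"),
    names_to = "series", values_to = "rate"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$month, .data$rate, linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$treatment_month, linetype = "dotted") +
    ggplot2::labs(
      x = NULL, y = "Incidents per 1,000,000 residents / month",
      title = paste0(object$treated, " vs synthetic control"),
      linetype = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Gap plot for a fitted synthetic control
#'
#' @param fit An `scm_fit`.
#' @return A ggplot object: observed minus synthetic rate by month.
#' @export
plot_gap <- function(fit) {
  ggplot2::ggplot(fit$series, ggplot2::aes(.data$month, .data$gap)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = fit$treatment_month, linetype = "dotted") +
    ggplot2::labs(
      x = NULL, y = "Gap (observed - synthetic, per 1M / month)",
      title = paste0("Gap: ", fit$treated)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a placebo ensemble
#'
#' The classic in-space placebo display: every placebo unit's gap series in
#' grey, the treated unit's in black.
#'
#' @param object A `placebo_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.placebo_ensemble <- function(object, ...) {
  fits <- c(setNames(list(object$treated_fit), object$treated),
            object$placebo_fits)
  df <- dplyr::bind_rows(purrr::imap(fits, function(f, u) {
    tibble::tibble(month = f$series$month, gap = f$series$gap, unit = u,
                   is_treated = u == object$treated)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$month, .data$gap, group = .data$unit)) +
    ggplot2::geom_line(data = df[!df$is_treated, ], colour = "grey75") +
    ggplot2::geom_line(data = df[df$is_treated, ], colour = "black", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50", linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$treatment_month, linetype = "dotted") +
    ggplot2::labs(
      x = NULL, y = "Gap (per 1M / month)",
      title = paste0("In-space placebos: ", object$treated)
    ) +
    ggplot2::theme_minimal()
}

#' Plot yearly effects with intervals
#'
#' @param effects A tibble from [yearly_effects()] (optionally several
#'   states/categories row-bound with `state`/`category` columns).
#' @return A ggplot object.
#' @export
plot_yearly_effects <- function(effects) {
  p <- ggplot2::ggplot(effects, ggplot2::aes(factor(.data$year), .data$effect)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)
    ) +
    ggplot2::labs(
      x = "Implementation year",
      y = "Effect (incidents per 1M residents / year)"
    ) +
    ggplot2::theme_minimal()
  if ("state" %in% names(effects) && dplyr::n_distinct(effects$state) > 1) {
    p <- p + ggplot2::facet_wrap(~state)
  }
  p
}
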