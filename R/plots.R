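# ggplot2 visualizations of per-node profiles and unfolding fits.

#' Plot an SDRI profile along the sequence
#'
#' Normalized SDRI per node (points and line). With
#' `type = "disorder"` the complementary `1 - SDRI` profile is drawn, which
#' highlights flexible, weakly connected (disorder-prone) segments instead
#' of rigid, well-connected ones.
#'
#' @param object An `sdri_profile` from [sdri_score()] or [run_score()].
#' @param type `"sdri"` or `"disorder"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sdri_profile
#' @export
autoplot.sdri_profile <- function(object, type = c("sdri", "disorder"), ...) {
  type <- match.arg(type)
  ycol <- if (type == "sdri") "sdri_norm" else "disorder"
  ylab <- if (type == "sdri") "normalized SDRI" else "1 - SDRI (disorder profile)"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$node, y = .data[[ycol]])) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "node (continuous numbering)", y = ylab) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a fitted melting curve
#'
#' Observed signal against temperature with the fitted two-state model
#' overlaid and the fitted melting temperature marked.
#'
#' @param object A `two_state_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot two_state_fit
#' @export
autoplot.two_state_fit <- function(object, ...) {
  grid <- tibble::tibble(
    T = seq(min(object$curve$T), max(object$curve$T), length.out = 300)
  )
  grid$F <- predict(object, grid)
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$T, y = .data$F)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = grid, color = "firebrick") +
    ggplot2::geom_vline(xintercept = object$par[["Tm"]], linetype = 2,
                        color = "grey40") +
    ggplot2::labs(x = "temperature (K)", y = "signal",
                  subtitle = sprintf("Tm = %.2f K, dHm = %.1f kcal/mol",
                                     object$par[["Tm"]], object$par[["dHm"]])) +
    ggplot2::theme_minimal()
}

#' Plot SDRI against experimental values
#'
#' Scatter of the validation pairs with the Pearson correlation in the
#' subtitle.
#'
#' @param object An `sdri_validation` from [correlate_with_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sdri_validation
#' @export
autoplot.sdri_validation <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$sdri, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "firebrick", linewidth = 0.5) +
    ggplot2::labs(x = "SDRI (raw)", y = "experimental value",
                  subtitle = sprintf("Pearson r = %.2f, R² = %.2f (n = %d)",
                                     object$pearson_r, object$r_squared,
                                     object$n)) +
    ggplot2::theme_minimal()
}
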