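#' Plot microcanonical entropy and its derivatives
#'
#' Faceted display of S(E), beta = dS/dE, gamma and delta, the panels used
#' to read off inflection-point transition signals. Detected transitions can
#' be overlaid as vertical lines.
#'
#' @param object an `entropy_curves` tibble from [smooth_derivatives()].
#' @param transitions optional [detect_transitions()] result to overlay.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot entropy_curves
#' @export
autoplot.entropy_curves <- function(object, transitions = NULL, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "E", "S", "beta", "gamma",
                  "delta"),
    -"E", names_to = "curve", values_to = "value")
  long$curve <- factor(long$curve, levels = c("S", "beta", "gamma", "delta"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$E, .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~curve, scales = "free_y", ncol = 1,
                        strip.position = "left") +
    ggplot2::labs(x = "E", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(transitions) && nrow(transitions) > 0) {
    p <- p + ggplot2::geom_vline(
      data = tibble::tibble(energy = transitions$energy),
      ggplot2::aes(xintercept = .data$energy),
      linetype = "dashed", colour = "steelblue")
  }
  p
}

#' Plot a structural prevalence field
#'
#' Heat map of p(E, q) with logarithmic colour scaling; cells where no
#' structure was ever observed are left white.
#'
#' @param object a [prevalence_field()] tibble.
#' @param floor smallest prevalence shown on the log scale.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot prevalence_field
#' @export
autoplot.prevalence_field <- function(object, floor = 1e-8, ...) {
  d <- tibble::as_tibble(object)
  d$p_clip <- pmax(d$p, floor)
  ggplot2::ggplot(d, ggplot2::aes(.data$E, .data$q, fill = .data$p_clip)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10", na.value = "white",
                                  name = "p(E, q)") +
    ggplot2::labs(x = "E", y = "q") +
    ggplot2::theme_minimal()
}

#' Canonical specific-heat curve
#'
#' @param canonical a [canonical_observables()] tibble.
#' @param against plot against temperature (default) or the canonical mean
#'   energy, as is common when comparing with microcanonical signals.
#' @return A ggplot object.
#' @export
plot_specific_heat <- function(canonical, against = c("temperature",
                                                      "e_mean")) {
  against <- match.arg(against)
  ggplot2::ggplot(canonical,
                  ggplot2::aes(.data[[against]], .data$cv_fluct)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (against == "temperature") "T" else
                    expression(bar(E)),
                  y = expression(C[V])) +
    ggplot2::theme_minimal()
}
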