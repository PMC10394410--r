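#' Plot a density field
#'
#' One curve per output time, density against position.
#'
#' @param object a `density_field` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot density_field
#' @export
autoplot.density_field <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x, y = .data$rho,
                               colour = factor(.data$time))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (lattice units)", y = "density",
                  colour = "time") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the inferred rate profile of a fit
#'
#' Posterior median rate with its 99% credible ribbon; optionally overlay
#' a known true profile.
#'
#' @param object a `polrate_fit`.
#' @param truth optional data frame with columns `x` and `p_tilde`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot polrate_fit
#' @export
autoplot.polrate_fit <- function(object, truth = NULL, ...) {
  rt <- tidy(object, "rate")
  p <- ggplot2::ggplot(rt, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::labs(x = "position (lattice units)",
                  y = "progression rate",
                  title = "Posterior rate profile (median, 99% CI)") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(
      data = truth, ggplot2::aes(y = .data$p_tilde),
      linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot posterior-predictive density bands against observations
#'
#' @param object a `polrate_predictive`.
#' @param obs optional [observation_set()] to overlay (on the density
#'   scale, using the posterior-median kappa is up to the caller; raw
#'   `y` values are drawn as points).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot polrate_predictive
#' @export
autoplot.polrate_predictive <- function(object, obs = NULL, ...) {
  p <- ggplot2::ggplot(object$density, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::facet_wrap(~time, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "position (lattice units)", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(obs)) {
    p <- p + ggplot2::geom_point(
      data = as_tibble(obs), ggplot2::aes(y = .data$y),
      size = 0.5, colour = "grey30")
  }
  p
}

#' Plot a metagene rate curve
#'
#' The three segments (native TSS window, stretched gene body, native TES
#' window) are shown side by side with the across-gene interquartile
#' ribbon.
#'
#' @param metagene output of [metagene_average()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(metagene) {
  metagene$segment <- factor(metagene$segment, c("tss", "body", "tes"))
  ggplot2::ggplot(metagene, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rate_q25,
                                      ymax = .data$rate_q75),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$rate)) +
    ggplot2::facet_wrap(~segment, scales = "free_x") +
    ggplot2::labs(x = "position (nt offset / relative)",
                  y = "mean rate") +
    ggplot2::theme_minimal()
}
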