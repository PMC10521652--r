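# ggplot2 autoplot methods for the package's result types.

#' Plot a two-state unfolding fit
#'
#' Data points with the fitted transition overlaid.
#'
#' @param object a `two_state_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.two_state_fit <- function(object, ...) {
  xg <- seq(min(object$data$denaturant), max(object$data$denaturant),
            length.out = 200)
  pred <- tibble::tibble(
    denaturant = xg,
    signal = two_state_signal(xg, object$dG, object$m_value, object$a_f,
                              object$b_f, object$a_u, object$b_u, object$RT))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$denaturant, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$Cm, linetype = "dashed") +
    ggplot2::labs(
      x = "denaturant (M)", y = "signal",
      title = sprintf("dG = %.2f kcal/mol, m = %.2f, Cm = %.2f M",
                      object$dG, object$m_value, object$Cm)) +
    ggplot2::theme_minimal()
}

#' Plot a barrel cross-section fit
#'
#' Strand centres on the fitted ellipse, coloured by face label.
#'
#' @param object a `barrel_shape_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.barrel_shape_fit <- function(object, ...) {
  th <- seq(0, 2 * pi, length.out = 200)
  ell <- tibble::tibble(x = object$center2d[1] + object$semi_major_a * cos(th),
                        y = object$center2d[2] + object$semi_minor_b * sin(th))
  pts <- object$strands |>
    dplyr::mutate(
      x = object$center2d[1] + object$semi_major_a * cos(.data$angle),
      y = object$center2d[2] + object$semi_minor_b * sin(.data$angle))
  ggplot2::ggplot(ell, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point(data = pts, ggplot2::aes(colour = .data$face), size = 3) +
    ggplot2::geom_text(data = pts,
                       ggplot2::aes(label = .data$strand), vjust = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (A)", y = "y (A)",
                  title = sprintf("a = %.1f A, b = %.1f A, e = %.2f",
                                  object$semi_major_a, object$semi_minor_b,
                                  object$eccentricity)) +
    ggplot2::theme_minimal()
}

#' Plot a design profile
#'
#' Position-by-residue frequency heatmap.
#'
#' @param object a `design_profile`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.design_profile <- function(object, ...) {
  pr <- object$profile
  pr$position <- factor(pr$position, levels = unique(pr$position))
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$position, y = .data$aa,
                                   fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "position", y = "residue", fill = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot a denaturation curve
#' @param object a `denaturation_curve`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.denaturation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$denaturant,
                                       y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "denaturant (M)", y = "signal") +
    ggplot2::theme_minimal()
}
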