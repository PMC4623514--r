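#' Plot a spin lattice snapshot
#'
#' Raster plot of active (`+1`) and inactive (`-1`) spins.
#'
#' @param spins A spin matrix.
#' @return A ggplot object.
#' @export
plot_lattice <- function(spins) {
  check_lattice(spins)
  df <- tidyr::expand_grid(row = seq_len(nrow(spins)),
                           col = seq_len(ncol(spins)))
  df$spin <- factor(spins[cbind(df$row, df$col)], levels = c(-1, 1),
                    labels = c("inactive (-1)", "active (+1)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$spin)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c("white", "black")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.correlation_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$C)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "r (lattice units)", y = "C(r, t)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.structure_profile <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$k > 0 & df$S > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$S)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "k", y = "S(k, t)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.growth_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$L)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = tibble(
        t = d$t,
        L = object$prefactor * d$t^object$phi
      ),
      linetype = 2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "t (MCS)", y = "L(t)",
      title = sprintf("L(t) ~ t^phi, phi = %.3f +/- %.3f",
                      object$phi, object$stderr)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.collapse_report <- function(object, ...) {
  df <- object$curves
  df$profile <- factor(df$profile)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value,
                                        colour = .data$profile)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal()
  if (object$type == "correlation") {
    ref <- tibble(x = object$grid, value = ojk_correlation(object$grid))
    p <- p +
      ggplot2::geom_line(data = ref, colour = "black", linewidth = 0.9,
                         inherit.aes = FALSE,
                         ggplot2::aes(x = .data$x, y = .data$value)) +
      ggplot2::labs(x = "r / L(t)", y = "C", colour = "profile")
  } else {
    p <- p +
      ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "k L(t)", y = expression(S %.% L^-2),
                    colour = "profile")
  }
  p
}

#' @export
autoplot.magnetization_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temp, y = .data$m_abs)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "T_c"), linetype = 2) +
    ggplot2::labs(x = "T (J / k_B)", y = "<|m|>") +
    ggplot2::theme_minimal()
}
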