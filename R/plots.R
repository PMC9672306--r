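#' Plot a mean-path-length sweep
#'
#' Ratio of the measured mean path length to the invariance-property
#' prediction `pi * R / 2` versus the inner radius, one colour per source
#' gap `d`, with 3-SE error bars and the IP reference line at 1.
#'
#' @param object an `ip_mpl` tibble.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.ip_mpl <- function(object, ...) {
  df <- as_tibble(object)
  df$d_label <- factor(df$d_mm)
  ggplot2::ggplot(
    df[df$valid, ],
    ggplot2::aes(.data$R_mm, .data$ratio, colour = .data$d_label)
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$ratio - 3 * .data$se_L_mm / .data$ip_mm,
      ymax = .data$ratio + 3 * .data$se_L_mm / .data$ip_mm
    )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "inner radius R (mm)",
      y = expression(group(langle, L, rangle) / (pi * R / 2)),
      colour = "d (mm)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a radial density profile
#'
#' Normalized trajectory density versus `r / R_e`, with the flat (equilibrium)
#' reference at the profile's qualifying-region mean.
#'
#' @param object an `ip_density` tibble.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.ip_density <- function(object, ...) {
  R_outer <- attr(object, "R_outer")
  df <- as_tibble(object)
  df$r_rel <- df$r_mid_mm / R_outer
  ggplot2::ggplot(df, ggplot2::aes(.data$r_rel, .data$normalized)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(r / R[e]),
      y = "trajectory density (normalized at r = Re)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an entrance-angle profile
#'
#' Histogram density of the entry angle relative to the inward normal with
#' the Lambertian reference curve `cos(theta) / 2`.
#'
#' @param object an `ip_angles` tibble.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.ip_angles <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$theta_mid, .data$density)) +
    ggplot2::geom_col(width = pi / nrow(df), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lambertian_density),
      colour = "firebrick"
    ) +
    ggplot2::labs(
      x = expression(theta ~ "(rad, relative to inward normal)"),
      y = "density"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
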