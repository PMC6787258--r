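# ggplot2 views of the result objects.

#' Plot an occupancy or analytic-curvature landscape
#'
#' Heatmap over `(s_norm, theta)` of either the placement occupancy or the
#' analytic radius of curvature at the bin centres — the two companion panels
#' of the curvature-sensing analysis.
#'
#' @param object A `curvature_landscape` from [occupancy_map()].
#' @param panel `"occupancy"` (default) or `"curvature"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.curvature_landscape <- function(object, panel = c("occupancy", "curvature"),
                                         ...) {
  panel <- match.arg(panel)
  d <- tidy(object)
  if (panel == "occupancy") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$s_norm, y = .data$theta,
                                    fill = .data$count)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = expression(s[norm]), y = expression(theta ~ "(deg)"),
                    fill = "count",
                    title = "Protein position and orientation on the buckle")
  } else {
    d$R_plot <- pmin(d$R, 200)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$s_norm, y = .data$theta,
                                    fill = .data$R_plot)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(option = "magma", direction = -1) +
      ggplot2::labs(x = expression(s[norm]), y = expression(theta ~ "(deg)"),
                    fill = "R (nm)",
                    title = "Analytic radius of curvature R(s, theta)")
  }
}

#' Plot a free-energy profile along the radius of curvature
#'
#' @param object An `fe_profile` from [free_energy_profile()].
#' @param ... Unused.
#' @return A ggplot object (log-scaled radius axis; unpopulated bins are
#'   gaps, the overflow bin is dropped).
#' @export
autoplot.fe_profile <- function(object, ...) {
  d <- object[is.finite(object$R_mid) & !is.na(object$F), ]
  err <- 1 / sqrt(pmax(d$count, 1))
  d$F_lo <- d$F - err
  d$F_hi <- d$F + err
  ggplot2::ggplot(d, ggplot2::aes(x = .data$R_mid, y = .data$F)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$F_lo, ymax = .data$F_hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "radius of curvature R (nm)",
                  y = expression(F(R) ~ (k[B] * T)),
                  title = "Free energy along the membrane curvature")
}

#' Plot a circle fit over its points
#'
#' @param object A `circle_fit` from [fit_circle()].
#' @param points Optional 2-column matrix of the fitted points to overlay.
#' @param ... Unused.
#' @return A ggplot object with equal coordinate scales.
#' @export
autoplot.circle_fit <- function(object, points = NULL, ...) {
  phi <- seq(0, 2 * pi, length.out = 361)
  circ <- tibble::tibble(x = object$center[1] + object$radius * cos(phi),
                         z = object$center[2] + object$radius * sin(phi))
  p <- ggplot2::ggplot(circ, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_path(colour = "darkgreen") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "z (nm)",
                  title = sprintf("Circle fit: R = %.1f nm", object$radius))
  if (!is.null(points)) {
    pts <- tibble::as_tibble(as.data.frame(as.matrix(points)))
    names(pts) <- c("x", "z")
    p <- p + ggplot2::geom_point(data = pts, size = 0.4, colour = "steelblue")
  }
  p
}

#' Plot the analytic buckle profile
#'
#' Side view (x-z) of one buckle period, optionally coloured by the local
#' curvature.
#'
#' @param profile A [buckle_profile()].
#' @param n Sample points along the arc.
#' @return A ggplot object.
#' @export
plot_buckle <- function(profile, n = 400L) {
  s <- seq(0, profile$L, length.out = n)
  d <- profile_xz(profile, s)
  d$C <- local_curvature(profile, s)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$z, colour = .data$C)) +
    ggplot2::geom_path(linewidth = 1) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "z (nm)", colour = "C (1/nm)",
                  title = sprintf("Buckled membrane profile (gamma = %.3g)",
                                  profile$gamma))
}
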