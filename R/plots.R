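## ggplot2 views of the result objects.

#' @rdname fsc_curve
#' @param object An `fsc_curve`.
#' @param threshold Threshold line to draw.
#' @export
autoplot.fsc_curve <- function(object, threshold = 0.143, ...) {
  res <- resolution_at_threshold(object, threshold)
  ggplot2::ggplot(object$shells, ggplot2::aes(x = .data$freq, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 1 / res$resolution_A, linetype = "dotted") +
    ggplot2::labs(
      x = "spatial frequency (1/Å)", y = "FSC",
      title = sprintf("FSC %.3g at %.1f Å%s", threshold, res$resolution_A,
                      if (res$at_nyquist) " (Nyquist-limited)" else "")
    )
}

#' @rdname rosenthal_henderson_bfactor
#' @param object A `bfactor_fit`.
#' @export
autoplot.bfactor_fit <- function(object, ...) {
  pts <- dplyr::mutate(object$points, x = log(.data$n), y = 1 / .data$d^2)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "ln(particle number)", y = expression(1 / d^2 ~ (ring(A)^-2)),
                  title = sprintf("B-factor %.0f Å²", object$bfactor))
}

#' @rdname fit_rate_through_origin
#' @param object A `rate_fit`.
#' @export
autoplot.rate_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$current, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = 0, colour = "steelblue") +
    ggplot2::labs(x = "beam current (nA)", y = expression(rate ~ (mu * m^3 / s)),
                  title = sprintf("%.3g ± %.2g µm³/nC",
                                  object$slope, object$stderr))
}

#' @rdname thickness_vs_edge_regression
#' @param object An `edge_trend`.
#' @export
autoplot.edge_trend <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$edge_distance, y = .data$thickness)) +
    ggplot2::geom_ribbon(data = object$band,
                         ggplot2::aes(x = .data$edge_distance, y = .data$fit,
                                      ymin = .data$lwr, ymax = .data$upr),
                         fill = "grey80") +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = object$band,
                       ggplot2::aes(x = .data$edge_distance, y = .data$fit),
                       colour = "steelblue") +
    ggplot2::labs(x = "distance to lamella edge (µm)", y = "thickness (nm)")
}

#' Plot a retention-vs-depth profile
#'
#' @param profile Output of [retention_profile()].
#' @return A ggplot.
#' @export
plot_retention_profile <- function(profile) {
  df <- dplyr::mutate(profile, mid = (.data$depth_lo + .data$depth_hi) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$fraction)) +
    ggplot2::geom_col(width = diff(df$depth_hi - df$depth_lo)[1] %||% 5 * 0.9) +
    ggplot2::labs(x = "depth below milling surface (nm)",
                  y = "fraction of picked particles retained")
}

#' Plot the per-shell resolutions of a damage study
#'
#' Shell vs matched-control resolutions side by side, the summary view of a
#' depth-damage experiment.
#'
#' @param report A `damage_report` from [run_damage_study()].
#' @return A ggplot.
#' @export
plot_shell_resolutions <- function(report) {
  ggplot2::ggplot(report$shell_table,
                  ggplot2::aes(x = .data$shell, y = .data$resolution_A,
                               fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "distance shell", y = "FSC 0.143 resolution (Å)",
                  fill = NULL)
}
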