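#' Plot per-tank heat stress accumulation
#'
#' Daily mean temperature and accumulated degree heating weeks per tank.
#'
#' @param stress Per-tank daily DHW tibble from [compute_dhw()].
#' @return A ggplot object.
#' @export
plot_heat_stress <- function(stress) {
  ggplot2::ggplot(stress, ggplot2::aes(date, dhw_c_weeks, colour = tank_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "DHW (°C-weeks)", colour = "Tank") +
    ggplot2::theme_minimal()
}

#' Plot colony BSI trajectories over the DHW grid
#'
#' One line per colony; the dashed reference marks the bleaching and
#' mortality onset threshold (BSI = 0.75).
#'
#' @param trajectories Tibble from [colony_trajectories()].
#' @param onset_bsi Onset threshold to mark (default 0.75).
#' @return A ggplot object.
#' @export
plot_bsi_trajectories <- function(trajectories, onset_bsi = 0.75) {
  ggplot2::ggplot(trajectories, ggplot2::aes(dhw_level, bsi, group = colony_id)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_hline(yintercept = onset_bsi, linetype = 2, colour = "red") +
    ggplot2::labs(x = "DHW (°C-weeks)", y = "BSI") +
    ggplot2::theme_minimal()
}

#' Plot a slope-progression analysis
#'
#' Posterior median of the BSI-trait slope at each DHW level with the
#' 50/75/95% credible ribbons; a slope above zero means colonies with
#' larger trait values hold higher BSI at that stress level (no
#' trade-off).
#'
#' @param progression Slope-posterior tibble from [slope_progression()].
#' @return A ggplot object.
#' @export
plot_slope_progression <- function(progression) {
  ggplot2::ggplot(progression, ggplot2::aes(dhw_level, beta1_median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci95_lower, ymax = ci95_upper), fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci75_lower, ymax = ci75_upper), fill = "grey70") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci50_lower, ymax = ci50_upper), fill = "grey55") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "DHW (°C-weeks)", y = "BSI-trait slope (posterior)") +
    ggplot2::theme_minimal()
}

#' Autoplot method for Bayesian regression fits
#'
#' Shows the marginal posterior density of the slope with the zero line;
#' the shaded area above zero is `p_positive`.
#'
#' @param object A `bayes_lm` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot bayes_lm
#' @export
autoplot.bayes_lm <- function(object, ...) {
  lim <- object$beta1_location + c(-4, 4) * object$beta1_scale
  xs <- seq(lim[1], lim[2], length.out = 400)
  dens <- stats::dt((xs - object$beta1_location) / object$beta1_scale, df = object$df) /
    object$beta1_scale
  d <- tibble::tibble(x = xs, y = dens)
  ggplot2::ggplot(d, ggplot2::aes(x, y)) +
    ggplot2::geom_area(data = d[d$x > 0, ], fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "slope", y = "posterior density",
                  subtitle = sprintf("P(slope > 0) = %.2f", object$p_positive)) +
    ggplot2::theme_minimal()
}

#' Autoplot method for ITS2 profile PCA
#'
#' @param object An `its2_pca` object.
#' @param ... Unused.
#' @return A ggplot object of PC1 vs PC2 scores, coloured by tolerance
#'   category when available.
#' @method autoplot its2_pca
#' @export
autoplot.its2_pca <- function(object, ...) {
  sc <- object$scores
  ve <- object$variance_explained
  p <- ggplot2::ggplot(sc, ggplot2::aes(PC1, PC2))
  p <- if ("tolerance_category" %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = tolerance_category))
  } else {
    p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * ve[1]),
                    y = sprintf("PC2 (%.0f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}
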