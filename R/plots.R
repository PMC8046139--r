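#' Plot an along-tract effective-radius profile
#'
#' @param profile A `tract_profile` tibble from [tract_profile()].
#' @param truth Optional function s -> true radius (normalised arc) drawn
#'   as a reference line.
#' @return A ggplot object: estimated radius per segment along arc length,
#'   resolution-limited segments marked.
#' @export
plot_tract_profile <- function(profile, truth = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$mid_s, y = .data$r)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$flag), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                name = "resolution limit") +
    ggplot2::labs(x = "arc length along tract (mm)",
                  y = expression(hat(r)[eff] ~ (mu * m))) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    s <- profile$mid_s / max(profile$mid_s + profile$mid_s[1])
    ref <- tibble::tibble(mid_s = profile$mid_s, r = truth(s))
    p <- p + ggplot2::geom_line(data = ref, linetype = 2, color = "firebrick")
  }
  p
}

#' Bland-Altman plot
#'
#' @param test,retest Paired estimate vectors.
#' @return A ggplot: percentage difference against pair mean with the mean
#'   difference and +/- 1.96 SD limits of agreement.
#' @export
plot_bland_altman <- function(test, retest) {
  ba <- bland_altman(test, retest)
  df <- tibble::tibble(mean = (test + retest) / 2,
                       diff_pct = ba$differences[[1]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff_pct)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = ba$mean_diff_pct, color = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = 2, color = "steelblue") +
    ggplot2::labs(x = "pair mean", y = "difference (% of pair mean)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a metric correlation matrix
#'
#' @param object A `metric_cor` from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot tile map of Pearson correlations.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.metric_cor <- function(object, ...) {
  df <- tidy.metric_cor(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric1, y = .data$metric2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  high = "firebrick", mid = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(rho)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Cramer-Rao pulse-timing landscape
#'
#' @param landscape Tibble from [protocol_landscape()].
#' @param chosen Optional `c(delta, Delta)` marked with a cross hair.
#' @return A ggplot raster of the radius precision bound over (delta,
#'   Delta); infeasible cells blank.
#' @export
plot_crlb_landscape <- function(landscape, chosen = c(15, 30)) {
  p <- ggplot2::ggplot(dplyr::filter(landscape, .data$valid),
                       ggplot2::aes(x = .data$delta, y = .data$Delta,
                                    fill = .data$sd_r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(sigma[CRLB](hat(r)) ~ (mu * m)),
                                  trans = "log10") +
    ggplot2::labs(x = expression(delta ~ (ms)), y = expression(Delta ~ (ms))) +
    ggplot2::theme_minimal()
  if (!is.null(chosen)) {
    p <- p +
      ggplot2::geom_vline(xintercept = chosen[1], color = "white", linetype = 3) +
      ggplot2::geom_hline(yintercept = chosen[2], color = "white", linetype = 3)
  }
  p
}

#' Mean versus effective radius for iso-effective Gamma laws
#'
#' Visualises the non-identifiability of the count-weighted mean radius
#' given the effective radius alone: along a curve of constant effective
#' radius the mean varies widely with the Gamma shape.
#'
#' @param target_r_eff Effective radius of the curve, um.
#' @param shape_grid Gamma shapes to sweep.
#' @return A ggplot of mean radius against shape at fixed effective radius.
#' @export
plot_iso_effective <- function(target_r_eff = 3,
                               shape_grid = seq(1, 10, by = 0.25)) {
  df <- iso_effective_curve(target_r_eff, shape_grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shape, y = .data$mean_radius)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = target_r_eff, linetype = 2,
                        color = "firebrick") +
    ggplot2::labs(x = expression(alpha ~ "(Gamma shape)"),
                  y = expression("mean radius" ~ (mu * m)),
                  subtitle = sprintf("all curves share r_eff = %g um",
                                     target_r_eff)) +
    ggplot2::theme_minimal()
}
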