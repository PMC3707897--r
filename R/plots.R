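#' Plot a correlation/modulation scatter with the CD prediction
#'
#' One point per subject (pattern correlation vs mean modulation index, with
#' SE error bars) overlaid with the parameter-free CD curve.
#'
#' @param object A `cd_scatter` from [modulation_scatter()] (or any data
#'   frame with `r`, `mean_d` and optionally `se`).
#' @param variance_ratio var(S)/var(C) for the CD curve (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cd_scatter <- function(object, variance_ratio = 1, ...) {
  grid <- tibble::tibble(r = seq(-0.999, 0.999, length.out = 400))
  grid$d <- cd_curve(grid$r, variance_ratio)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$mean_d)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$r, y = .data$d),
                       linewidth = 0.7) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "correlation r(C, S)",
                  y = expression(mean ~ d[M]),
                  title = "Pattern correlation vs measured modulation") +
    ggplot2::theme_minimal()
  if ("se" %in% names(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_d - .data$se,
                   ymax = .data$mean_d + .data$se),
      width = 0.02, linewidth = 0.3
    )
  }
  if ("condition" %in% names(object) &&
      length(unique(object$condition)) > 1) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}

#' Plot an eccentricity profile of BOLD change
#'
#' Ring means with SE error bars against representative eccentricity, with a
#' dashed zero line to read off the sign flip.
#'
#' @param object A `cd_profile` from [eccentricity_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cd_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ecc_deg, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se)
    ) +
    ggplot2::labs(
      x = "eccentricity (deg)", y = "BOLD change (%)",
      title = paste0(object$area[1], ", ", object$condition[1],
                     " (", object$level[1], " level)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot normalised model errors from a model comparison
#'
#' Bar chart of the group-normalised mean error per candidate model (the
#' largest per-point error on the scatter maps to 1).
#'
#' @param object A [compare_models()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cd_model_comparison <- function(object, ...) {
  res <- object$results
  res$model <- factor(res$model, levels = res$model[order(res$rank)])
  ggplot2::ggplot(res, ggplot2::aes(x = .data$model,
                                    y = .data$normalized_mean_error)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "normalised mean error",
                  title = "Model comparison (lower is better)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
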