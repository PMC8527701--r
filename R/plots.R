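#' Plot a DMFS curve
#'
#' @param object a `dmfs_curve` tibble from [dmfs_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dmfs_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time since diagnosis (months)",
                  y = "Distant-metastasis-free survival") +
    ggplot2::theme_minimal()
}

#' Plot a personalized prediction
#'
#' Personalized DMFS curve with the predicted TTR (median replicate) and
#' the 5-year metastasis-free probability annotated.
#'
#' @param object a `prediction_result` from [personalized_prediction()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.prediction_result <- function(object, ...) {
  p <- autoplot(object$dmfs) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(subtitle = sprintf(
      "predicted TTR %.1f months; P(met at diagnosis) %.2f; P(met-free 5y) %.2f",
      object$predicted_ttr, object$p_met_at_diagnosis, object$p_met_free_5y))
  if (is.finite(object$predicted_ttr))
    p <- p + ggplot2::geom_vline(xintercept = object$predicted_ttr,
                                 linetype = "dashed")
  p
}

#' Plot a DMFS fit: Kaplan-Meier strata vs model curves
#'
#' @param object a `dmfs_fit` from [fit_dmfs()].
#' @param ... unused.
#' @return a ggplot faceted by dichotomization threshold.
#' @export
autoplot.dmfs_fit <- function(object, ...) {
  d <- object$residuals
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, colour = .data$arm)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$surv)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), linetype = "dashed") +
    ggplot2::facet_wrap(~threshold, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time since diagnosis (months)", y = "DMFS",
                  colour = paste(object$covariate, "arm"),
                  subtitle = "solid: Kaplan-Meier; dashed: model") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result
#'
#' Enriched terms by directional z-score, sized by DE gene count.
#'
#' @param object an `enrichment_result` from [hypergeometric_enrichment()].
#' @param top show at most this many terms (by adjusted p). Default 20.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  d <- dplyr::slice_min(dplyr::filter(object, .data$count > 0),
                        .data$adj_p, n = top, with_ties = FALSE)
  d$term <- stats::reorder(d$term, -d$adj_p)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$zscore, y = .data$term,
                                  size = .data$count,
                                  colour = .data$adj_p <= 0.05)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Directional z-score  (up - down) / sqrt(count)",
                  y = NULL, size = "DE genes", colour = "adj p <= 0.05") +
    ggplot2::theme_minimal()
}
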