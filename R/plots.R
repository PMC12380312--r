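#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Odds-ratio distribution plot for a cross-validation ensemble
#'
#' Boxplot of the per-SD odds ratios of every feature across the 60
#' fold-models, with whiskers at the distribution extremes and a reference
#' line at OR = 1 (a feature zeroed by the Lasso sits exactly on it).
#'
#' @param object A `cv_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_ensemble <- function(object, ...) {
  d <- or_distribution(object) |>
    dplyr::mutate(feature = stats::reorder(.data$feature, .data$or_median)) |>
    tidyr::unnest_longer("ors", values_to = "or")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$feature)) +
    ggplot2::geom_boxplot(coef = Inf, outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "odds ratio per standard deviation",
      y = NULL,
      title = "Per-fold odds ratios across the cross-validation ensemble"
    ) +
    ggplot2::theme_minimal()
}

#' Expected versus observed band prevalence plot
#'
#' @param object A `band_evaluation` from [evaluate_bands()].
#' @param ... Unused.
#' @return A ggplot object comparing the risk-definition (expected) and
#'   risk-evaluation (observed) positive fractions per band.
#' @export
autoplot.band_evaluation <- function(object, ...) {
  d <- object$comparison |>
    dplyr::select("band", "expected", "observed") |>
    tidyr::pivot_longer(c("expected", "observed"),
      names_to = "set", values_to = "prevalence"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$band, y = .data$prevalence, fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = "risk band", y = "MSKP prevalence", fill = NULL,
      title = "Risk-band prevalence: definition vs evaluation set"
    ) +
    ggplot2::theme_minimal()
}

#' Model-score distributions by outcome
#'
#' Density plot of the ensemble score for negative and positive cases, with
#' optional risk-band cutpoints.
#'
#' @param scores Numeric ensemble scores.
#' @param outcomes Binary outcomes.
#' @param bands Optional `risk_bands` whose cuts are drawn as vertical lines.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, outcomes, bands = NULL) {
  d <- tibble::tibble(
    score = scores,
    outcome = factor(ifelse(as.integer(outcomes) == 1, "positive", "negative"))
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$outcome)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(
      x = "ensemble model score", y = "density", fill = NULL,
      title = "Model-score distribution by MSKP status"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(bands)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(bands$lower_cut, bands$upper_cut), linetype = "dashed"
    )
  }
  p
}
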