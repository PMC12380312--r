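#' Odds ratio per standard deviation
#'
#' A standardized logistic coefficient is the natural log of the odds ratio
#' associated with a one-SD increase of the predictor; exponentiating
#' recovers the OR.
#'
#' @param beta_std Standardized coefficient(s).
#' @return `exp(beta_std)`.
#' @examples
#' or_per_sd(0.039) # ~1.04: 4% higher odds per SD
#' @export
or_per_sd <- function(beta_std) {
  stopifnot(all(is.finite(beta_std)))
  exp(beta_std)
}

#' Maximum odds ratio over a variable's range
#'
#' The odds ratio between a respondent at the maximum versus the minimum
#' observed value of a predictor: `exp(beta_std * range_width / sd)`, where
#' `beta_std` is the per-SD (standardized) coefficient.
#'
#' @param beta_std Standardized coefficient.
#' @param sd Observed standard deviation of the raw variable (> 0).
#' @param range_width Observed max minus min of the raw variable (> 0).
#' @return Positive scalar.
#' @examples
#' max_odds_ratio(0.039, sd = 1.04, range_width = 4) # ~1.16
#' @export
max_odds_ratio <- function(beta_std, sd, range_width) {
  .assert_scalar_number(beta_std, "beta_std")
  if (!is.finite(sd) || sd <= 0) {
    stop("`sd` must be positive: a constant feature has no odds ratio", call. = FALSE)
  }
  if (!is.finite(range_width) || range_width <= 0) {
    stop("`range_width` must be positive", call. = FALSE)
  }
  exp(beta_std * range_width / sd)
}

#' Bonferroni-corrected confidence interval from per-fold odds ratios
#'
#' Builds a family-level confidence interval for a feature's maximum odds
#' ratio from its per-fold values across the cross-validation ensemble. The
#' per-feature coverage is raised to `1 - (1 - family_level) / k_features`
#' (Bonferroni). The default interval is a normal approximation on the
#' log-OR scale using the across-fold mean and standard deviation; an
#' empirical-quantile variant is available via `method`.
#'
#' @param values Per-fold maximum odds ratios (length >= 2, all > 0).
#' @param family_level Family-wise coverage, default 0.90.
#' @param k_features Number of simultaneous intervals (>= 1).
#' @param method `"normal"` (default) or `"quantile"`.
#' @return Named numeric vector `c(low, high)`; a zero-variance fold
#'   distribution yields a degenerate interval flagged with attribute
#'   `degenerate = TRUE`.
#' @export
bonferroni_ci <- function(values, family_level = 0.90, k_features = 1,
                          method = c("normal", "quantile")) {
  method <- match.arg(method)
  stopifnot(length(values) >= 2, all(values > 0), k_features >= 1,
            family_level > 0, family_level < 1)
  alpha <- (1 - family_level) / k_features
  lv <- log(values)
  if (stats::sd(lv) == 0) {
    out <- c(low = values[1], high = values[1])
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- if (method == "normal") {
    z <- stats::qnorm(1 - alpha / 2)
    exp(mean(lv) + c(-1, 1) * z * stats::sd(lv))
  } else {
    unname(stats::quantile(values, c(alpha / 2, 1 - alpha / 2), type = 7))
  }
  stats::setNames(out, c("low", "high"))
}

#' Prevalence with a Wilson score interval
#'
#' Point prevalence `positives / n` with the Wilson score confidence
#' interval (the score-test inversion, via `prop.test` without continuity
#' correction), which stays inside \[0, 1\] and behaves well near the
#' boundaries.
#'
#' @param positives Number of positive cases.
#' @param n Sample size (> 0).
#' @param level Confidence level, default 0.95.
#' @return Tibble with columns `point`, `low`, `high` (proportions).
#' @examples
#' prevalence_ci(154, 680) # 22.6% [19.7%, 25.9%]
#' @export
prevalence_ci <- function(positives, n, level = 0.95) {
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  stopifnot(positives >= 0, positives <= n)
  ci <- stats::prop.test(positives, n, conf.level = level, correct = FALSE)$conf.int
  tibble::tibble(point = positives / n, low = ci[1], high = ci[2])
}

#' Signed percent change implied by an odds ratio
#'
#' Expresses an odds ratio as the percent a respondent is more (OR > 1) or
#' less (OR < 1) likely to be a positive case: `(OR - 1) * 100`.
#'
#' @param or_value Positive odds ratio(s).
#' @return Signed percent(s).
#' @examples
#' percent_change(1.117) # +11.7% more likely
#' percent_change(0.943) # -5.7% (5.7% less likely)
#' @export
percent_change <- function(or_value) {
  stopifnot(all(or_value > 0))
  (or_value - 1) * 100
}

#' Effect-size table for a cross-validation ensemble
#'
#' Summarises every selected feature the way the published model table does:
#' the observed range on the raw scale, the maximum odds ratio
#' (`exp(mean standardized coefficient * range / SD)`), and its
#' Bonferroni-corrected confidence interval across the fold-models.
#'
#' @param ensemble A `cv_ensemble` fitted on standardized features.
#' @param meta Per-column metadata tibble with raw-scale `name`, `min`,
#'   `max`, `sd` (take `fm$meta` from the *unstandardized* feature matrix).
#' @param features Features to report; defaults to the median-selected set.
#' @param family_level Family-wise CI coverage, default 0.90.
#' @param method CI construction passed to [bonferroni_ci()].
#' @return Tibble: `parameter`, `range`, `or_per_sd`, `max_or`, `ci_low`,
#'   `ci_high`, ordered by decreasing `max_or`.
#' @export
effect_summary <- function(ensemble, meta, features = select_by_median(ensemble),
                           family_level = 0.90, method = c("normal", "quantile")) {
  method <- match.arg(method)
  stopifnot(inherits(ensemble, "cv_ensemble"))
  k <- length(features)
  if (k == 0) stop("no features to summarise", call. = FALSE)
  rows <- purrr::map(features, function(f) {
    j <- match(f, ensemble$features)
    mrow <- meta[meta$name == f, ]
    if (nrow(mrow) != 1) stop("no raw-scale metadata for feature ", f, call. = FALSE)
    if (mrow$sd == 0) stop("feature ", f, " is constant; no odds ratio is defined", call. = FALSE)
    betas <- ensemble$coefs[, j]
    ratio <- (mrow$max - mrow$min) / mrow$sd
    ci <- bonferroni_ci(exp(betas * ratio), family_level = family_level,
                        k_features = k, method = method)
    tibble::tibble(
      parameter = f,
      range = sprintf("%g-%g", round(mrow$min, 2), round(mrow$max, 2)),
      or_per_sd = or_per_sd(mean(betas)),
      max_or = max_odds_ratio(mean(betas), sd = 1, range_width = ratio),
      ci_low = ci[["low"]],
      ci_high = ci[["high"]]
    )
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(dplyr::desc(.data$max_or))
}
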