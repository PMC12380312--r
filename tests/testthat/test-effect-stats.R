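test_that("per-SD odds ratios are the exponential of the coefficient", {
  expect_equal(or_per_sd(0), 1)
  # a coefficient of 0.039 reads as ~4% higher odds per SD increment
  expect_equal(or_per_sd(0.039), 1.0398, tolerance = 1e-4)
  expect_equal(or_per_sd(0.1), 1.1052, tolerance = 1e-4)
})

test_that("maximum odds ratios scale the coefficient over the variable's range", {
  # tiredness/difficulty-waking sleep factor: coefficient 0.039, SD 1.04, range 0-4
  expect_lt(abs(max_odds_ratio(0.039, sd = 1.04, range_width = 4) - 1.163), 0.002)
  expect_equal(max_odds_ratio(0, sd = 2, range_width = 10), 1)
  # exponential homomorphism: doubling the coefficient squares the OR
  expect_equal(
    max_odds_ratio(0.2, 1.5, 3),
    max_odds_ratio(0.1, 1.5, 3)^2
  )
  # a range of one SD recovers the per-SD OR
  expect_equal(max_odds_ratio(0.3, 1.7, 1.7), or_per_sd(0.3))
  expect_error(max_odds_ratio(0.1, sd = 0, range_width = 1), "constant feature")
})

test_that("Bonferroni intervals widen with the feature count and match k = 1 closed form", {
  withr::with_seed(33, values <- exp(stats::rnorm(60, 0.2, 0.1)))
  lv <- log(values)
  plain <- bonferroni_ci(values, family_level = 0.90, k_features = 1)
  z <- stats::qnorm(0.95)
  expect_equal(unname(plain), exp(mean(lv) + c(-1, 1) * z * stats::sd(lv)))

  widths <- vapply(
    c(1, 5, 13),
    function(k) diff(log(bonferroni_ci(values, k_features = k))),
    numeric(1)
  )
  expect_true(all(diff(widths) > 0))

  # the interval always contains the point estimate
  expect_true(exp(mean(lv)) > plain[["low"]] && exp(mean(lv)) < plain[["high"]])

  # empirical-quantile variant stays inside the observed values
  q <- bonferroni_ci(values, k_features = 2, method = "quantile")
  expect_gte(q[["low"]], min(values))
  expect_lte(q[["high"]], max(values))

  deg <- bonferroni_ci(rep(1.2, 60), k_features = 3)
  expect_equal(as.numeric(deg), c(1.2, 1.2))
  expect_true(attr(deg, "degenerate"))
})

test_that("the Wilson interval reproduces closed-form arithmetic", {
  # oracle: Wilson closed form (p + z^2/2n +/- z sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)
  wilson <- function(k, n, level = 0.95) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- k / n
    centre <- p + z^2 / (2 * n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    c(centre - half, centre + half) / (1 + z^2 / n)
  }
  got <- prevalence_ci(50, 100)
  expect_equal(c(got$low, got$high), wilson(50, 100), tolerance = 1e-9)
  expect_equal(round(100 * c(got$low, got$high), 1), c(40.4, 59.6))

  edge <- prevalence_ci(0, 50)
  expect_equal(edge$point, 0)
  expect_equal(edge$low, 0)
  expect_gt(edge$high, 0)

  mid <- prevalence_ci(154, 680)
  expect_true(mid$low < mid$point && mid$point < mid$high)
  expect_true(mid$low >= 0 && mid$high <= 1)
  expect_error(prevalence_ci(1, 0), "positive")
})

test_that("odds ratios translate to signed percent-change readings", {
  expect_equal(percent_change(1.117), 11.7, tolerance = 1e-9)
  expect_equal(percent_change(0.943), -5.7, tolerance = 1e-9)
  expect_equal(percent_change(1), 0)
})

test_that("the effect table mirrors the ensemble and raw-scale metadata", {
  fx <- default_model()
  fm <- default_fm()
  eff <- effect_summary(fx$model$ensemble, fm$meta, features = fx$selected)
  expect_setequal(eff$parameter, fx$selected)
  # sorted by decreasing maximum OR, interval containing the point estimate
  expect_true(all(diff(eff$max_or) <= 0))
  expect_true(all(eff$ci_low <= eff$max_or * (1 + 1e-9)))
  expect_true(all(eff$ci_high >= eff$max_or * (1 - 1e-9)))
  expect_true(all(eff$max_or > 0))

  # invariant: max OR equals exp(mean coefficient * range / SD) from metadata
  j <- eff$parameter[1]
  mrow <- fm$meta[fm$meta$name == j, ]
  betas <- fx$model$ensemble$coefs[, j]
  expect_equal(
    eff$max_or[1],
    exp(mean(betas) * (mrow$max - mrow$min) / mrow$sd)
  )
})
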