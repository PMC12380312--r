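test_that("an overwhelming penalty shrinks every slope to zero", {
  d <- simulate_sparse_logistic(n = 500, p_noise = 4, beta = 1, seed = 3)
  fit <- fit_lasso_logistic(d$x, d$y, lambda = 1e6)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, stats::qlogis(mean(d$y)), tolerance = 1e-4)
})

test_that("at lambda zero the fit matches the unpenalized maximum likelihood", {
  d <- simulate_sparse_logistic(n = 2000, p_noise = 4, beta = 0.8, seed = 5)
  fit <- fit_lasso_logistic(d$x, d$y, lambda = 0)
  oracle <- nr_logistic(d$x, d$y)
  expect_lt(max(abs(fit$beta - oracle$beta)), 1e-4)
  expect_lt(abs(fit$intercept - oracle$intercept), 1e-4)
  # and agrees with glm as a second, independent route
  gfit <- stats::glm(d$y ~ d$x, family = stats::binomial())
  expect_lt(max(abs(oracle$beta - unname(stats::coef(gfit)[-1]))), 1e-8)
})

test_that("a moderate penalty keeps the real predictor and silences noise", {
  keep_signal <- logical(50)
  noise_zero <- numeric(50)
  for (r in 1:50) {
    d <- simulate_sparse_logistic(n = 2000, p_noise = 8, beta = 1, seed = 100 + r)
    fit <- fit_lasso_logistic(d$x, d$y, lambda = 20)
    keep_signal[r] <- abs(fit$beta["signal"]) > 1e-8
    noise_zero[r] <- mean(abs(fit$beta[-1]) <= 1e-8)
  }
  expect_true(all(keep_signal))
  expect_gt(mean(noise_zero), 0.5)
})

test_that("degenerate fits are refused", {
  d <- simulate_sparse_logistic(n = 100, p_noise = 2, seed = 8)
  expect_error(fit_lasso_logistic(d$x, rep(1L, 100), lambda = 1), "single class")
  expect_error(fit_lasso_logistic(d$x, d$y, lambda = -1), "non-negative")
})

test_that("the rank AUC equals brute-force pair counting, ties at one half", {
  withr::with_seed(12, {
    for (r in 1:20) {
      n <- sample(20:200, 1)
      scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE) # many ties
      labels <- stats::rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      expect_equal(auc_rank(scores, labels), auc_pairs(scores, labels))
    }
  })
  expect_error(auc_rank(1:5, rep(1, 5)), "single class")
})

test_that("stratified folds preserve prevalence to one respondent per class", {
  y <- rep(c(0L, 1L), c(526, 154))
  withr::with_seed(9, {
    fold <- stratified_folds(y, 3)
    tab <- table(fold, y)
    expect_true(all(abs(tab[, "1"] - 154 / 3) < 1))
    expect_true(all(abs(tab[, "0"] - 526 / 3) < 1))
  })
  # reproducible under the same seed
  f1 <- withr::with_seed(10, stratified_folds(y, 3))
  f2 <- withr::with_seed(10, stratified_folds(y, 3))
  expect_identical(f1, f2)
})

test_that("cross-validation refuses plans the sample cannot stratify", {
  d <- simulate_sparse_logistic(n = 40, p_noise = 2, seed = 13)
  y_rare <- c(rep(1L, 2), rep(0L, 38))
  expect_error(
    cross_validate(d$x, y_rare, plan = cv_plan(1, 3, seed = 1)),
    "rarer than the number of folds"
  )
})

test_that("a one-point grid is honoured and yields the full ensemble", {
  d <- simulate_sparse_logistic(n = 300, p_noise = 4, beta = 1, seed = 17)
  ens <- cross_validate(d$x, d$y, plan = cv_plan(20, 3, seed = 2), lambda_grid = 5)
  expect_equal(ens$best_lambda, 5)
  expect_identical(nrow(ens$coefs), 60L)
  expect_identical(nrow(ens$member_info), 60L)
  # determinism: same plan, same ensemble
  ens2 <- cross_validate(d$x, d$y, plan = cv_plan(20, 3, seed = 2), lambda_grid = 5)
  expect_equal(ens$coefs, ens2$coefs)
  expect_identical(ens$fold_assignments, ens2$fold_assignments)
})

test_that("pure-noise predictors score at chance level", {
  withr::with_seed(19, {
    x <- matrix(stats::rnorm(300 * 10), 300, 10,
      dimnames = list(NULL, paste0("n", 1:10))
    )
    y <- stats::rbinom(300, 1, 0.3)
  })
  ens <- cross_validate(x, y, plan = cv_plan(5, 3, seed = 3), lambda_grid = c(1, 10))
  expect_lt(abs(mean(ens$member_info$test_auc) - 0.5), 0.05)
})

test_that("stronger penalties never increase the active set (per fold)", {
  d <- simulate_sparse_logistic(n = 400, p_noise = 8, beta = 1, seed = 23)
  ens <- cross_validate(d$x, d$y,
    plan = cv_plan(3, 3, seed = 4),
    lambda_grid = default_lambda_grid()
  )
  # the stored grid is decreasing in lambda, so counts must be non-decreasing
  expect_true(all(apply(ens$nonzero_by_lambda, 1, function(r) all(diff(r) >= 0))))
})

test_that("the median rule keeps exactly the features with nonzero median", {
  fake <- structure(
    list(
      features = c("mostly_zero", "always_on", "half_half"),
      coefs = cbind(
        mostly_zero = c(rep(0, 31), rep(0.4, 29)),
        always_on = rep(0.2, 60),
        half_half = c(rep(0, 30), rep(0.3, 30))
      )
    ),
    class = "cv_ensemble"
  )
  d <- or_distribution(fake)
  expect_setequal(select_by_median(fake), c("always_on", "half_half"))
  # a feature zeroed in 31+ folds has median OR exactly 1
  expect_equal(d$or_median[d$feature == "mostly_zero"], 1)
  # zero coefficients map to unit odds ratios
  expect_true(all(unlist(d$ors[d$feature == "mostly_zero"])[1:31] == 1))
})
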