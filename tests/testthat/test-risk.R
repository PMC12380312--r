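test_that("the workflow split reproduces the 60/20/20 stratified arithmetic", {
  y <- rep(c(1L, 0L), c(154, 526))
  sp <- split_workflow(y, seed = 5)
  expect_identical(length(sp$train), 408L)
  expect_identical(length(sp$definition), 136L)
  expect_identical(length(sp$evaluation), 136L)
  expect_identical(sum(y[sp$train]), 92L)
  expect_identical(sum(y[sp$definition]), 31L)
  expect_identical(sum(y[sp$evaluation]), 31L)

  # disjoint and exhaustive
  all_idx <- c(sp$train, sp$definition, sp$evaluation)
  expect_identical(sort(all_idx), seq_along(y))
  expect_identical(anyDuplicated(all_idx), 0L)

  # deterministic
  sp2 <- split_workflow(y, seed = 5)
  expect_identical(sp$train, sp2$train)
  expect_identical(sp$evaluation, sp2$evaluation)

  expect_error(split_workflow(rep(0L, 10), seed = 1), "at least 30")
  expect_error(split_workflow(rep(0L, 100), seed = 1), "single class")
})

test_that("ensemble scores are the mean member probability", {
  x <- matrix(c(0.5, -1, 2, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
  identical_members <- structure(
    list(
      features = c("a", "b"),
      coefs = rbind(c(1, -0.5), c(1, -0.5), c(1, -0.5)),
      intercepts = c(0.2, 0.2, 0.2)
    ),
    class = "cv_ensemble"
  )
  colnames(identical_members$coefs) <- c("a", "b")
  one <- stats::plogis(0.2 + x %*% c(1, -0.5))
  expect_equal(ensemble_score(identical_members, x), as.numeric(one))

  # all-zero coefficients: every score is the inverse-logit intercept
  null_ens <- identical_members
  null_ens$coefs[] <- 0
  null_ens$intercepts[] <- stats::qlogis(0.226)
  expect_equal(ensemble_score(null_ens, x), rep(0.226, 2))

  bad <- matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "c")))
  expect_error(ensemble_score(identical_members, bad), "lack ensemble feature.*b")
})

test_that("tertile bands on a separable toy give 3/3/3 with 0/0/1 prevalence", {
  scores <- 1:9
  outcomes <- c(rep(0, 6), rep(1, 3))
  bands <- define_bands(scores, outcomes)
  expect_equal(bands$bands$n, c(3L, 3L, 3L))
  expect_equal(bands$bands$prevalence, c(0, 0, 1))
  expect_equal(bands$lower_cut, 4)
  expect_equal(bands$upper_cut, 7)

  expect_error(define_bands(rep(1, 10), rep(0:1, 5)), "degenerate score distribution")
})

test_that("band evaluation is self-consistent and flags empty bands as undefined", {
  scores <- 1:9
  outcomes <- c(rep(0, 6), rep(1, 3))
  bands <- define_bands(scores, outcomes)
  ev <- evaluate_bands(bands, scores, outcomes)
  expect_equal(ev$comparison$observed, ev$comparison$expected)
  expect_equal(ev$auc, 1) # perfectly separating scores

  # all held-out scores land in the high band: the others are NA, not 0
  ev2 <- evaluate_bands(bands, c(8, 9, 9), c(0, 1, 1))
  expect_true(is.na(ev2$comparison$observed[1]))
  expect_true(is.na(ev2$comparison$observed[2]))
  expect_equal(ev2$comparison$observed[3], 2 / 3)
})

test_that("the AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(29, {
    scores <- stats::rnorm(150)
    labels <- stats::rbinom(150, 1, 0.3)
  })
  base <- auc_rank(scores, labels)
  expect_equal(auc_rank(stats::plogis(scores), labels), base)
  expect_equal(auc_rank(exp(2 * scores + 1), labels), base)
})

test_that("the definitive workflow is leakage-free and balanced on tertiles", {
  fx <- default_model()
  model <- fx$model
  fm <- fm_subset(default_fm(), fx$selected)

  # standardization statistics come from the training rows alone
  manual_center <- colMeans(fm$values[model$split$train, ])
  expect_equal(model$stats$center, unname(manual_center[model$stats$name]))

  # the three subsets never overlap
  expect_identical(
    anyDuplicated(c(model$split$train, model$split$definition, model$split$evaluation)),
    0L
  )

  # tertile balance on the risk-definition set
  def_bands <- table(model$scores$band[model$scores$subset == "definition"])
  expect_true(all(abs(def_bands - length(model$split$definition) / 3) <= 1))

  # positives score stochastically higher than negatives on the definition set
  def <- model$scores[model$scores$subset == "definition", ]
  w <- stats::wilcox.test(
    def$score[def$outcome == 1], def$score[def$outcome == 0],
    alternative = "greater", exact = FALSE
  )
  expect_lt(w$p.value, 0.05)

  # determinism of the whole workflow
  model2 <- risk_workflow(fm_subset(default_fm(), fx$selected), seed = 13)
  expect_equal(model$scores$score, model2$scores$score)
  expect_equal(model$bands$lower_cut, model2$bands$lower_cut)
})

test_that("cross-validated discrimination on the default cohort is in the working range", {
  fx <- default_model()
  expect_gt(mean(fx$selection$member_info$test_auc), 0.70)
  expect_lt(mean(fx$selection$member_info$test_auc), 0.90)
  expect_identical(nrow(fx$selection$coefs), 60L)
})
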