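test_that("encoding expands categoricals into grouped indicators", {
  toy <- tibble::tibble(
    sex = c(0, 1, 0, 1, 1),
    age_group = c("10_12", "13_15", "16_18", "13_15", "10_12"),
    score = c(1, 2, 3, 4, 5),
    outcome = c(0, 1, 0, 1, 1)
  )
  fm <- encode(toy, outcome = "outcome", exclude = character())
  expect_setequal(
    colnames(fm$values),
    c("sex", "score", "age_group_10_12", "age_group_13_15", "age_group_16_18")
  )
  # binary numeric column passes through unexpanded
  expect_true(is.na(fm$meta$group[fm$meta$name == "sex"]))
  expect_identical(unique(stats::na.omit(fm$meta$group)), "age_group")
  expect_identical(fm$outcome, c(0L, 1L, 0L, 1L, 1L))
  expect_equal(rowSums(fm$values[, grep("age_group", colnames(fm$values))]), rep(1, 5))
})

test_that("encoding templates reproduce the design and reject unseen levels", {
  toy <- tibble::tibble(
    age_group = c("10_12", "13_15", "16_18", "13_15"),
    score = 1:4
  )
  fm <- encode(toy, outcome = NULL, exclude = character())
  new <- tibble::tibble(age_group = c("13_15", "13_15"), score = 5:6)
  fm2 <- encode(new, outcome = NULL, exclude = character(), template = fm)
  # sibling levels absent from the new data appear as constant-zero columns, flagged
  expect_identical(colnames(fm2$values), colnames(fm$values))
  expect_true(all(fm2$values[, "age_group_10_12"] == 0))
  expect_true(fm2$meta$constant[fm2$meta$name == "age_group_10_12"])

  odd <- tibble::tibble(age_group = "19_21", score = 1)
  expect_error(
    encode(odd, outcome = NULL, exclude = character(), template = fm),
    "unseen level.*19_21"
  )
})

test_that("standardization yields exact z-scores and is reusable on held-out rows", {
  toy <- tibble::tibble(a = c(1, 2, 3), b = c(5, 5, 5), outcome = c(0, 1, 0))
  fm <- standardize(encode(toy, outcome = "outcome", exclude = character()))
  expect_equal(fm$values[, "a"], c(-1, 0, 1))
  # constant column: left at zero, flagged, never divided by zero
  expect_equal(fm$values[, "b"], c(0, 0, 0))
  expect_true(fm$meta$constant[fm$meta$name == "b"])

  big <- standardize(default_fm())
  nonconst <- !big$meta$constant
  expect_true(all(abs(colMeans(big$values[, nonconst])) < 1e-9))
  expect_true(all(abs(apply(big$values[, nonconst], 2, stats::sd) - 1) < 1e-9))

  # applying the stored statistics to the training rows is idempotent
  again <- standardize(default_fm(), stats = big$stats)
  expect_equal(again$values, big$values)
})

test_that("rank correlations are invariant under monotone maps and match hand ranks", {
  x <- c(0.3, 1.1, 2.5, 3.7, 5.0)
  m <- cbind(x = x, x3 = x^3, negx = -x)
  rho <- spearman_matrix(m)
  expect_equal(rho["x", "x3"], 1)
  expect_equal(rho["x", "negx"], -1)
  expect_equal(rho, t(rho))
  expect_equal(diag(rho), c(x = 1, x3 = 1, negx = 1))

  # tied case frozen from average-rank arithmetic done by hand:
  # ranks of (1,2,2,4) are (1, 2.5, 2.5, 4); of (1,3,2,4) are (1,3,2,4);
  # Pearson on those ranks is 1.5 / sqrt(1.5 * 5/3) = 0.9486833
  tied <- cbind(x = c(1, 2, 2, 4), y = c(1, 3, 2, 4))
  expect_equal(spearman_matrix(tied)["x", "y"], 0.9486833, tolerance = 1e-6)

  const <- cbind(a = c(1, 2, 3), b = c(7, 7, 7))
  rho <- spearman_matrix(const)
  expect_equal(rho["a", "b"], 0)
  expect_identical(attr(rho, "constant"), "b")
  expect_error(spearman_matrix(cbind(a = 1:2)), "at least 3")
})

test_that("screening collapses duplicated signal and keeps weakly related features", {
  withr::with_seed(77, {
    base <- tibble::tibble(
      a = stats::rnorm(100),
      b = stats::rnorm(100),
      outcome = stats::rbinom(100, 1, 0.3)
    )
    dup <- dplyr::mutate(base, a_copy = a)
    fm <- encode(dup, outcome = "outcome", exclude = character())
    res <- painrisk::screen(fm, threshold = 0.5)
    expect_length(intersect(res$kept, c("a", "a_copy")), 1)
    expect_true("b" %in% res$kept)

    # all pairwise |rho| below the threshold: identity screen
    fm2 <- encode(base, outcome = "outcome", exclude = character())
    res2 <- painrisk::screen(fm2, threshold = 0.5)
    expect_setequal(res2$kept, c("a", "b"))
  })
  expect_error(painrisk::screen(default_fm_std(), threshold = 1.2), "threshold")
})

test_that("screening the default cohort is deterministic and keeps a mid-sized set", {
  res <- default_screen()
  p <- ncol(default_fm()$values)
  expect_gt(length(res$kept), 13)
  expect_lt(length(res$kept), p)
  # regression constant for the default synthetic cohort
  expect_identical(length(res$kept), 25L)

  res2 <- painrisk::screen(default_fm_std(), threshold = 0.5)
  expect_identical(res$kept, res2$kept)

  # bookkeeping: every feature is either kept or dropped with a named reason
  expect_setequal(c(res$kept, res$dropped$name), colnames(default_fm()$values))
  collapsed <- res$dropped[res$dropped$reason != "one-hot reference level", ]
  expect_true(all(!is.na(collapsed$representative)))
  expect_true(all(collapsed$representative %in% res$kept))

  # no near-duplicate survives
  rho <- res$correlation[res$kept, res$kept]
  expect_true(all(abs(rho[upper.tri(rho)]) < 1))
})

test_that("raising the screening threshold never shrinks the kept set", {
  fm <- default_fm_std()
  kept_n <- vapply(
    c(0.3, 0.5, 0.7, 0.9),
    function(th) length(painrisk::screen(fm, threshold = th)$kept),
    numeric(1)
  )
  expect_true(all(diff(kept_n) >= 0))
})
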