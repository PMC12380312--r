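#' Repeated stratified cross-validation plan
#'
#' The default plan is a 20-times repeated stratified 3-fold, yielding 60
#' train/test splits that each preserve the outcome prevalence of the full
#' sample (to within one respondent per fold).
#'
#' @param n_repeats Number of repetitions.
#' @param n_folds Folds per repetition.
#' @param seed Integer seed governing every fold assignment.
#' @return Object of class `cv_plan`.
#' @export
cv_plan <- function(n_repeats = 20, n_folds = 3, seed = 1L) {
  stopifnot(n_repeats >= 1, n_folds >= 2)
  structure(
    list(n_repeats = as.integer(n_repeats), n_folds = as.integer(n_folds),
         stratified = TRUE, seed = as.integer(seed)),
    class = "cv_plan"
  )
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(
    "<cv_plan>", x$n_repeats, "x stratified", paste0(x$n_folds, "-fold"),
    "=", x$n_repeats * x$n_folds, "fold-models | seed", x$seed, "\n"
  )
  invisible(x)
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `n_folds` folds so that every fold's
#' outcome prevalence matches the full sample within one respondent per
#' class. Consumes the current RNG stream (wrap in a seed for determinism).
#'
#' @param y Binary outcome vector.
#' @param n_folds Number of folds.
#' @return Integer vector of fold ids in `1:n_folds`.
#' @export
stratified_folds <- function(y, n_folds) {
  y <- as.integer(y)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated Lasso-logistic ensemble with penalty search
#'
#' Runs the cross-validation plan over a grid of Lasso penalties, scoring
#' each fold-model by the AUC of the ROC curve on its held-out fold, and
#' selects the penalty with the best mean AUC over all folds (ties go to the
#' stronger penalty). The returned ensemble contains every fold-model refit
#' at the winning penalty together with the per-feature distribution of
#' odds ratios per standard deviation across folds.
#'
#' @param x Standardized predictor matrix or `feature_matrix`.
#' @param y Binary outcome (taken from `x$outcome` when `NULL`).
#' @param plan A [cv_plan()].
#' @param lambda_grid Penalties to search (total-log-likelihood scale).
#' @param rule Penalty-selection rule. `"auc"` takes the penalty with the
#'   best mean AUC outright. `"auc_1se"` (default) takes the strongest
#'   penalty whose mean AUC is within one standard error of the best: at
#'   survey-sized samples the AUC-penalty profile is nearly flat, and the
#'   one-SE rule yields the sparse, stable ensembles the median-nonzero
#'   retention step expects.
#' @return Object of class `cv_ensemble`; see [tidy.cv_ensemble()] and
#'   [glance.cv_ensemble()] for summaries.
#' @export
cross_validate <- function(x, y = NULL, plan = cv_plan(),
                           lambda_grid = default_lambda_grid(),
                           rule = c("auc_1se", "auc")) {
  rule <- match.arg(rule)
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$outcome
    x <- x$values
  }
  y <- as.integer(y)
  stopifnot(length(lambda_grid) >= 1, all(lambda_grid >= 0))
  grid <- sort(unique(lambda_grid), decreasing = TRUE)
  n <- length(y)
  if (min(table(y)) < plan$n_folds) {
    stop("a class is rarer than the number of folds; stratified test folds would be single-class", call. = FALSE)
  }

  p <- ncol(x)
  n_members <- plan$n_repeats * plan$n_folds
  coefs <- array(0, dim = c(n_members, p, length(grid)))
  intercepts <- matrix(0, n_members, length(grid))
  aucs <- matrix(NA_real_, n_members, length(grid))
  member_info <- vector("list", n_members)
  fold_assignments <- vector("list", plan$n_repeats)

  withr::with_seed(plan$seed, {
    m <- 0L
    for (r in seq_len(plan$n_repeats)) {
      fold <- stratified_folds(y, plan$n_folds)
      fold_assignments[[r]] <- fold
      for (f in seq_len(plan$n_folds)) {
        m <- m + 1L
        test <- fold == f
        if (length(unique(y[test])) < 2) {
          stop("fold with a single-class test set; the sample is too small for this plan", call. = FALSE)
        }
        xtr <- x[!test, , drop = FALSE]
        ytr <- y[!test]
        ntr <- nrow(xtr)
        path_g <- grid / ntr
        lam_max <- max(abs(crossprod(xtr, ytr - mean(ytr))) / ntr, path_g, 1e-3) * 1.05
        path <- sort(unique(c(lam_max, path_g)), decreasing = TRUE)
        fit <- glmnet::glmnet(
          xtr, ytr,
          family = "binomial", lambda = path,
          standardize = FALSE, thresh = 1e-9, maxit = 1e6
        )
        for (g in seq_along(grid)) {
          k <- which.min(abs(fit$lambda - path_g[g]))
          beta <- as.numeric(fit$beta[, k])
          a0 <- as.numeric(fit$a0[k])
          coefs[m, , g] <- beta
          intercepts[m, g] <- a0
          eta <- a0 + as.numeric(x[test, , drop = FALSE] %*% beta)
          aucs[m, g] <- auc_rank(eta, y[test])
        }
        member_info[[m]] <- tibble::tibble(repetition = r, fold = f, n_train = ntr)
      }
    }
  })

  mean_auc <- colMeans(aucs)
  best_g <- which(mean_auc == max(mean_auc))[1] # grid is decreasing: first max is the strongest penalty
  if (rule == "auc_1se") {
    se_best <- stats::sd(aucs[, best_g]) / sqrt(n_members)
    best_g <- which(mean_auc >= max(mean_auc) - se_best)[1]
  }
  best_lambda <- grid[best_g]

  member_info <- dplyr::bind_rows(member_info)
  member_info$test_auc <- aucs[, best_g]

  beta_best <- coefs[, , best_g, drop = FALSE]
  dim(beta_best) <- c(n_members, p)
  colnames(beta_best) <- colnames(x)

  structure(
    list(
      features = colnames(x),
      coefs = beta_best,
      intercepts = intercepts[, best_g],
      member_info = member_info,
      fold_assignments = fold_assignments,
      best_lambda = best_lambda,
      lambda_grid = grid,
      auc_by_lambda = tibble::tibble(lambda = grid, mean_auc = mean_auc,
                                     sd_auc = apply(aucs, 2, stats::sd)),
      nonzero_by_lambda = apply(abs(coefs) > 1e-8, c(1, 3), sum),
      plan = plan
    ),
    class = "cv_ensemble"
  )
}

#' Default Lasso penalty grid
#'
#' Log-spaced over \[0.01, 100\] (total-log-likelihood scale) and containing
#' the published working penalty of 10.
#'
#' @return Numeric vector of 9 penalties.
#' @export
default_lambda_grid <- function() 10^seq(-2, 2, length.out = 9)

#' @export
print.cv_ensemble <- function(x, ...) {
  cat(
    "<cv_ensemble>", nrow(x$coefs), "fold-models at lambda =",
    format(x$best_lambda), "| mean test AUC",
    round(mean(x$member_info$test_auc), 3), "|",
    length(select_by_median(x)), "of", length(x$features),
    "features with nonzero median coefficient\n"
  )
  invisible(x)
}

#' Per-feature odds-ratio distribution across the ensemble
#'
#' For every feature, the 60 per-SD odds ratios (exponential of the
#' standardized coefficient of each fold-model) with their median, minimum
#' and maximum. A feature zeroed by the Lasso in every fold has all ORs
#' equal to 1.
#'
#' @param ensemble A `cv_ensemble`.
#' @return Tibble: `feature`, `ors` (list column of per-fold ORs),
#'   `or_median`, `or_min`, `or_max`, `coef_median`, `coef_mean`.
#' @export
or_distribution <- function(ensemble) {
  stopifnot(inherits(ensemble, "cv_ensemble"))
  or_mat <- exp(ensemble$coefs)
  tibble::tibble(
    feature = ensemble$features,
    ors = lapply(seq_along(ensemble$features), function(j) unname(or_mat[, j])),
    or_median = unname(apply(or_mat, 2, stats::median)),
    or_min = unname(apply(or_mat, 2, min)),
    or_max = unname(apply(or_mat, 2, max)),
    coef_median = unname(apply(ensemble$coefs, 2, stats::median)),
    coef_mean = unname(colMeans(ensemble$coefs))
  )
}

#' Median-nonzero feature retention rule
#'
#' Second feature-selection step: keep only features whose coefficient
#' distribution over the 60 fold-models has a nonzero median (equivalently,
#' a per-SD odds-ratio median different from 1). A feature zeroed by the
#' Lasso in more than half of the folds is discarded.
#'
#' @param x A `cv_ensemble` or the tibble from [or_distribution()].
#' @param tol Numerical zero for the median coefficient.
#' @return Character vector of retained feature names.
#' @export
select_by_median <- function(x, tol = 1e-8) {
  d <- if (inherits(x, "cv_ensemble")) or_distribution(x) else x
  d$feature[abs(d$coef_median) > tol]
}

#' @rdname or_distribution
#' @param x A `cv_ensemble`.
#' @param ... Unused.
#' @export
tidy.cv_ensemble <- function(x, ...) {
  or_distribution(x) |>
    dplyr::select(-"ors") |>
    dplyr::mutate(selected = abs(.data$coef_median) > 1e-8)
}

#' One-row performance summary of a cross-validation ensemble
#'
#' @param x A `cv_ensemble`.
#' @param ... Unused.
#' @return Tibble with the winning penalty, mean/sd test AUC, member count
#'   and number of median-selected features.
#' @export
glance.cv_ensemble <- function(x, ...) {
  tibble::tibble(
    best_lambda = x$best_lambda,
    mean_auc = mean(x$member_info$test_auc),
    sd_auc = stats::sd(x$member_info$test_auc),
    n_members = nrow(x$coefs),
    n_features = length(x$features),
    n_selected = length(select_by_median(x))
  )
}

#' Serialize an ensemble to JSON
#'
#' Writes per-member intercepts, coefficient vectors, fold ids and the
#' winning penalty.
#'
#' @param ensemble A `cv_ensemble`.
#' @param path Output path.
#' @export
write_ensemble <- function(ensemble, path) {
  members <- lapply(seq_len(nrow(ensemble$coefs)), function(m) {
    list(
      repetition = ensemble$member_info$repetition[m],
      fold = ensemble$member_info$fold[m],
      intercept = ensemble$intercepts[m],
      coefficients = as.list(stats::setNames(ensemble$coefs[m, ], ensemble$features)),
      test_auc = ensemble$member_info$test_auc[m]
    )
  })
  jsonlite::write_json(
    list(lambda = ensemble$best_lambda, features = ensemble$features, members = members),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
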