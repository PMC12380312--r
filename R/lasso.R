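#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Lasso-regularized logistic regression
#'
#' Maximizes the penalized log-likelihood `l(beta) - lambda * sum(|beta_j|)`
#' with an unpenalized intercept. `lambda` penalizes the total (not
#' per-observation) log-likelihood, so the fit is delegated to glmnet with
#' its per-observation penalty set to `lambda / n`; a short warm-start path
#' down to the target penalty keeps the coordinate-descent solution tight
#' (convergence threshold 1e-10).
#'
#' @param x Numeric predictor matrix (standardize first: the penalty treats
#'   all coefficients on a common scale) or a `feature_matrix`.
#' @param y Binary outcome vector (0/1).
#' @param lambda Penalty >= 0 on the total log-likelihood scale.
#' @return Object of class `lasso_fit`: `intercept`, `beta` (named vector),
#'   `lambda`, `n`.
#' @examples
#' \donttest{
#' x <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- rbinom(200, 1, plogis(x[, 1]))
#' fit_lasso_logistic(x, y, lambda = 5)$beta
#' }
#' @export
fit_lasso_logistic <- function(x, y, lambda) {
  if (inherits(x, "feature_matrix")) x <- x$values
  .assert_scalar_number(lambda, "lambda")
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  y <- as.integer(y)
  if (nrow(x) == 0) stop("empty design matrix", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; the logistic likelihood is degenerate", call. = FALSE)
  }
  n <- nrow(x)
  target <- lambda / n
  # decreasing warm-start path ending exactly at the target penalty
  lam_max <- max(abs(crossprod(x, y - mean(y))) / n, target * 2, 1e-3)
  path <- unique(c(exp(seq(log(lam_max), log(max(target, lam_max * 1e-4)), length.out = 15)), target))
  path <- sort(path, decreasing = TRUE)
  fit <- glmnet::glmnet(
    x, y,
    family = "binomial", lambda = path,
    standardize = FALSE, thresh = 1e-10, maxit = 1e6
  )
  if (!all(fit$jerr == 0)) {
    stop("glmnet did not converge (jerr = ", fit$jerr, ")", call. = FALSE)
  }
  k <- length(fit$lambda) # path is fitted in the given order; take the last
  beta <- as.numeric(fit$beta[, k])
  names(beta) <- rownames(fit$beta)
  structure(
    list(
      intercept = as.numeric(fit$a0[k]),
      beta = beta,
      lambda = lambda,
      n = n
    ),
    class = "lasso_fit"
  )
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(
    "<lasso_fit> lambda =", x$lambda, "| n =", x$n, "|",
    sum(abs(x$beta) > 1e-8), "of", length(x$beta), "nonzero coefficients\n"
  )
  invisible(x)
}

#' @export
predict.lasso_fit <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  missing <- setdiff(names(object$beta), colnames(newdata))
  if (length(missing) > 0) {
    stop("newdata lacks feature column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  eta <- object$intercept + as.numeric(newdata[, names(object$beta), drop = FALSE] %*% object$beta)
  if (type == "link") eta else stats::plogis(eta)
}
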