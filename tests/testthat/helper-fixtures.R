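# Shared fixtures are generated once per test run and cached here.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_cohort <- function() {
  fixture("cohort", function() generate_cohort(cohort_spec(seed = 7)))
}

default_scored <- function() {
  fixture("scored", function() score_cohort(default_cohort()))
}

default_fm <- function() {
  fixture("fm", function() encode(default_scored()))
}

default_fm_std <- function() {
  fixture("fm_std", function() standardize(default_fm()))
}

default_screen <- function() {
  fixture("screen", function() painrisk::screen(default_fm_std(), threshold = 0.5))
}

default_model <- function() {
  fixture("model", function() {
    ens <- cross_validate(
      fm_subset(default_fm_std(), default_screen()$kept),
      plan = cv_plan(seed = 11)
    )
    selected <- select_by_median(ens)
    list(
      selection = ens,
      selected = selected,
      model = risk_workflow(fm_subset(default_fm(), selected), seed = 13)
    )
  })
}

# Independent Newton-Raphson fit of an unpenalized logistic regression,
# used as the maximum-likelihood oracle for the Lasso at lambda = 0.
nr_logistic <- function(x, y, tol = 1e-12, maxit = 200) {
  x1 <- cbind(1, x)
  beta <- numeric(ncol(x1))
  for (i in seq_len(maxit)) {
    p <- stats::plogis(as.numeric(x1 %*% beta))
    w <- pmax(p * (1 - p), 1e-12)
    step <- solve(crossprod(x1 * w, x1), crossprod(x1, y - p))
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  list(intercept = beta[1], beta = beta[-1])
}

# Brute-force AUC by pair counting (ties count one half).
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (s in pos) total <- total + sum(s > neg) + 0.5 * sum(s == neg)
  total / (length(pos) * length(neg))
}

# Logistic outcomes from a single standardized predictor plus noise columns.
simulate_sparse_logistic <- function(n, p_noise, beta = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * (p_noise + 1)), n, p_noise + 1)
    colnames(x) <- c("signal", paste0("noise_", seq_len(p_noise)))
    y <- stats::rbinom(n, 1, stats::plogis(beta * x[, 1]))
    list(x = x, y = y)
  })
}
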