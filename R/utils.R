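#' @importFrom rlang %||% .data
#' @keywords internal
NULL

#' Area under the ROC curve by the rank statistic
#'
#' Computes the probability that a randomly chosen positive case receives a
#' higher score than a randomly chosen negative case, with ties counting 1/2
#' (the Mann-Whitney formulation). Equivalent to brute-force pair counting.
#'
#' @param scores Numeric vector of model scores (any monotone scale).
#' @param labels Binary outcome vector (0/1 or logical), same length.
#' @return A single number in \[0, 1\].
#' @examples
#' auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: outcome vector contains a single class", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deterministic key for caching calibrated intercepts
.spec_key <- function(spec) {
  paste(
    spec$target_prevalence,
    paste(deparse(spec$effect_table), collapse = ""),
    paste(deparse(spec$block_correlations), collapse = ""),
    collapse = "|"
  )
}

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
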