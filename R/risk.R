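#' Stratified train / risk-definition / risk-evaluation split
#'
#' Partitions the cohort into the definitive-model workflow subsets: 60% for
#' training the cross-validation ensemble, 20% for defining the risk bands,
#' and 20% held out to evaluate them. Each part preserves the full-sample
#' outcome prevalence within rounding, and the partition is deterministic
#' given the seed.
#'
#' @param y Binary outcome vector for the full cohort.
#' @param seed Integer seed.
#' @param fractions Named numeric vector summing to 1 with elements `train`,
#'   `definition`, `evaluation`.
#' @return Object of class `workflow_split` with integer index vectors
#'   `train`, `definition`, `evaluation`.
#' @export
split_workflow <- function(y, seed = 1L,
                           fractions = c(train = 0.6, definition = 0.2, evaluation = 0.2)) {
  y <- as.integer(y)
  n <- length(y)
  stopifnot(abs(sum(fractions) - 1) < 1e-8,
            all(c("train", "definition", "evaluation") %in% names(fractions)))
  if (n < 30) stop("need at least 30 respondents to split the workflow", call. = FALSE)
  if (length(unique(y)) < 2) stop("outcome has a single class; cannot stratify", call. = FALSE)

  parts <- list(train = integer(), definition = integer(), evaluation = integer())
  withr::with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      n_c <- length(idx)
      n_eval <- round(fractions[["evaluation"]] * n_c)
      n_def <- round(fractions[["definition"]] * n_c)
      parts$evaluation <- c(parts$evaluation, idx[seq_len(n_eval)])
      parts$definition <- c(parts$definition, idx[n_eval + seq_len(n_def)])
      parts$train <- c(parts$train, idx[-seq_len(n_eval + n_def)])
    }
  })
  parts <- lapply(parts, sort)
  for (p in names(parts)) {
    if (length(unique(y[parts[[p]]])) < 2) {
      stop("subset '", p, "' ended up single-class; the outcome is too rare to stratify", call. = FALSE)
    }
  }
  structure(c(parts, list(seed = as.integer(seed), n = n, fractions = fractions)),
            class = "workflow_split")
}

#' @export
print.workflow_split <- function(x, ...) {
  cat(
    "<workflow_split> train", length(x$train), "| definition", length(x$definition),
    "| evaluation", length(x$evaluation), "(seed", paste0(x$seed, ")"), "\n"
  )
  invisible(x)
}

#' Ensemble model score
#'
#' The definitive model score of a respondent is the arithmetic mean of the
#' predicted probabilities of all fold-models in the cross-validation
#' ensemble. Rows must be standardized with the training statistics.
#'
#' @param ensemble A `cv_ensemble`.
#' @param rows A `feature_matrix` or numeric matrix with the ensemble's
#'   feature columns.
#' @return Numeric vector of scores in \[0, 1\], one per row.
#' @export
ensemble_score <- function(ensemble, rows) {
  stopifnot(inherits(ensemble, "cv_ensemble"))
  if (inherits(rows, "feature_matrix")) rows <- rows$values
  missing <- setdiff(ensemble$features, colnames(rows))
  if (length(missing) > 0) {
    stop("rows lack ensemble feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- rows[, ensemble$features, drop = FALSE]
  eta <- x %*% t(ensemble$coefs) # n x members
  eta <- sweep(eta, 2, ensemble$intercepts, "+")
  rowMeans(stats::plogis(eta))
}

#' Define tertile risk bands on the risk-definition set
#'
#' Cuts the model-score line at the empirical 1/3 and 2/3 quantiles and
#' assigns each band the positive-case fraction observed within it. Band
#' membership uses left-closed, right-open intervals: low = score < lower
#' cut, medium = lower cut <= score < upper cut, high = score >= upper cut.
#' The cuts are the right-continuous empirical quantiles (order statistic
#' `floor(n p) + 1`), which makes the three bands balanced to within one
#' respondent up to ties under the right-open membership convention.
#'
#' @param scores Ensemble scores on the risk-definition set.
#' @param outcomes Binary outcomes for the same respondents.
#' @return Object of class `risk_bands`: `lower_cut`, `upper_cut`, and a
#'   `bands` tibble (band, n, positives, prevalence).
#' @export
define_bands <- function(scores, outcomes) {
  outcomes <- as.integer(outcomes)
  stopifnot(length(scores) == length(outcomes))
  if (length(unique(scores)) < 3) {
    stop("degenerate score distribution: fewer than 3 distinct scores", call. = FALSE)
  }
  ss <- sort(scores)
  n <- length(ss)
  cuts <- c(ss[floor(n / 3) + 1], ss[floor(2 * n / 3) + 1])
  band <- band_assign(cuts[1], cuts[2], scores)
  bands <- tibble::tibble(band = factor(c("low", "medium", "high"), levels = levels(band))) |>
    dplyr::left_join(
      tibble::tibble(band = band, outcome = outcomes) |>
        dplyr::group_by(.data$band) |>
        dplyr::summarise(n = dplyr::n(), positives = sum(.data$outcome), .groups = "drop"),
      by = "band"
    ) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      positives = dplyr::coalesce(.data$positives, 0L),
      prevalence = ifelse(.data$n > 0, .data$positives / .data$n, NA_real_)
    )
  structure(
    list(lower_cut = cuts[1], upper_cut = cuts[2], bands = bands),
    class = "risk_bands"
  )
}

band_assign <- function(lower_cut, upper_cut, scores) {
  factor(
    ifelse(scores < lower_cut, "low", ifelse(scores < upper_cut, "medium", "high")),
    levels = c("low", "medium", "high")
  )
}

#' @export
print.risk_bands <- function(x, ...) {
  cat(
    "<risk_bands> cuts at", format(x$lower_cut, digits = 4), "and",
    format(x$upper_cut, digits = 4), "| expected prevalence",
    paste(sprintf("%s %.1f%%", x$bands$band, 100 * x$bands$prevalence), collapse = ", "), "\n"
  )
  invisible(x)
}

#' @rdname define_bands
#' @param x A `risk_bands`.
#' @param ... Unused.
#' @export
tidy.risk_bands <- function(x, ...) {
  x$bands |>
    dplyr::mutate(
      lower = c(-Inf, x$lower_cut, x$upper_cut),
      upper = c(x$lower_cut, x$upper_cut, Inf)
    )
}

#' Evaluate risk bands on held-out data
#'
#' Assigns each held-out respondent to a band, reports the observed positive
#' fraction per band next to the band's expected prevalence, and the overall
#' AUC of the ensemble scores. An empty band has undefined (`NA`), not zero,
#' observed prevalence.
#'
#' @param bands A `risk_bands` from [define_bands()].
#' @param scores Ensemble scores on the risk-evaluation set.
#' @param outcomes Binary outcomes for the same respondents.
#' @return Object of class `band_evaluation`: `comparison` tibble (band, n,
#'   positives, expected, observed) and `auc`.
#' @export
evaluate_bands <- function(bands, scores, outcomes) {
  stopifnot(inherits(bands, "risk_bands"), length(scores) == length(outcomes))
  outcomes <- as.integer(outcomes)
  band <- band_assign(bands$lower_cut, bands$upper_cut, scores)
  obs <- tibble::tibble(band = factor(c("low", "medium", "high"), levels = levels(band))) |>
    dplyr::left_join(
      tibble::tibble(band = band, outcome = outcomes) |>
        dplyr::group_by(.data$band) |>
        dplyr::summarise(n = dplyr::n(), positives = sum(.data$outcome), .groups = "drop"),
      by = "band"
    ) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      positives = dplyr::coalesce(.data$positives, 0L),
      expected = bands$bands$prevalence,
      observed = ifelse(.data$n > 0, .data$positives / .data$n, NA_real_)
    )
  structure(
    list(comparison = obs, auc = auc_rank(scores, outcomes)),
    class = "band_evaluation"
  )
}

#' @export
print.band_evaluation <- function(x, ...) {
  cat("<band_evaluation> AUC", round(x$auc, 3), "\n")
  print(x$comparison)
  invisible(x)
}

#' Definitive risk-model workflow
#'
#' Runs the full definitive-model construction on an encoded cohort: a
#' stratified 60/20/20 split, standardization and cross-validated ensemble
#' training on the training subset only, tertile risk-band definition on the
#' risk-definition subset, and band evaluation on the held-out
#' risk-evaluation subset. Held-out rows never influence training,
#' standardization statistics, penalty choice or cut placement; the returned
#' object records the index sets so this can be asserted structurally.
#'
#' @param fm A raw (unstandardized) `feature_matrix` carrying the outcome.
#' @param seed Seed for the workflow split.
#' @param plan A [cv_plan()] for the training ensemble.
#' @param lambda_grid Penalty grid searched on the training subset.
#' @param rule Penalty-selection rule passed to [cross_validate()]; the
#'   definitive model defaults to the plain best-mean-AUC criterion (features
#'   are already selected, so sparsity is no longer at stake).
#' @return Object of class `risk_model`: `split`, `stats` (training
#'   standardization), `ensemble`, `bands`, `evaluation`, and a per-subject
#'   `scores` tibble (row, subset, score, band, outcome).
#' @export
risk_workflow <- function(fm, seed = 1L, plan = cv_plan(seed = seed),
                          lambda_grid = default_lambda_grid(),
                          rule = c("auc", "auc_1se")) {
  rule <- match.arg(rule)
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$outcome))
  split <- split_workflow(fm$outcome, seed = seed)

  train_fm <- standardize(fm_rows(fm, split$train))
  ensemble <- cross_validate(train_fm, plan = plan, lambda_grid = lambda_grid, rule = rule)

  score_part <- function(rows) {
    part <- standardize(fm_rows(fm, rows), stats = train_fm$stats)
    ensemble_score(ensemble, part)
  }
  def_scores <- score_part(split$definition)
  eval_scores <- score_part(split$evaluation)
  train_scores <- score_part(split$train)

  bands <- define_bands(def_scores, fm$outcome[split$definition])
  evaluation <- evaluate_bands(bands, eval_scores, fm$outcome[split$evaluation])

  scores <- tibble::tibble(
    row = c(split$train, split$definition, split$evaluation),
    subset = rep(c("train", "definition", "evaluation"),
      c(length(split$train), length(split$definition), length(split$evaluation))
    ),
    score = c(train_scores, def_scores, eval_scores),
    outcome = fm$outcome[c(split$train, split$definition, split$evaluation)]
  ) |>
    dplyr::mutate(band = band_assign(bands$lower_cut, bands$upper_cut, .data$score)) |>
    dplyr::arrange(.data$row)

  structure(
    list(
      split = split, stats = train_fm$stats, ensemble = ensemble,
      bands = bands, evaluation = evaluation, scores = scores
    ),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model>\n")
  print(x$split)
  print(x$ensemble)
  print(x$bands)
  print(x$evaluation)
  invisible(x)
}

#' @rdname risk_workflow
#' @param x A `risk_model`.
#' @param ... Unused.
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    n = x$split$n,
    n_train = length(x$split$train),
    best_lambda = x$ensemble$best_lambda,
    train_cv_auc = mean(x$ensemble$member_info$test_auc),
    evaluation_auc = x$evaluation$auc,
    lower_cut = x$bands$lower_cut,
    upper_cut = x$bands$upper_cut
  )
}

#' Serialize risk bands to JSON
#'
#' @param bands A `risk_bands`.
#' @param path Output path.
#' @export
write_bands <- function(bands, path) {
  jsonlite::write_json(
    list(
      lower_cut = bands$lower_cut,
      upper_cut = bands$upper_cut,
      expected_prevalence = as.list(stats::setNames(
        bands$bands$prevalence, as.character(bands$bands$band)
      ))
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
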