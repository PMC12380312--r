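#' Default end-to-end pipeline configuration
#'
#' Every stage parameter of [run_pipeline()] with every seed explicit:
#' cohort generation, instrument scoring, screening threshold, penalty grid,
#' cross-validation plan, and the workflow split. Round-trips unchanged
#' through YAML.
#'
#' @return Nested list of stage parameters.
#' @export
default_config <- function() {
  list(
    cohort = list(
      n_respondents = 680,
      seed = 1L,
      target_prevalence = 0.226,
      effect_scale = 16,
      block_correlations = list(sleep = 0.45, activity = 0.40, chores = 0.30),
      n_incomplete = 0L
    ),
    screen = list(threshold = 0.5),
    lasso = list(
      lambda_grid = as.numeric(default_lambda_grid()),
      rule = "auc_1se", # selection stage: sparse, stable ensembles
      final_rule = "auc" # definitive stage: best mean AUC outright
    ),
    cv = list(n_repeats = 20L, n_folds = 3L, seed = 2L),
    split = list(seed = 3L)
  )
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML file with the structure of [default_config()].
#' @return Validated config list.
#' @export
read_config <- function(path) {
  config <- yaml::read_yaml(path)
  validate_config(config)
}

#' @rdname read_config
#' @param config A config list.
#' @export
validate_config <- function(config) {
  needed_seeds <- list(c("cohort", "seed"), c("cv", "seed"), c("split", "seed"))
  for (key in needed_seeds) {
    val <- config[[key[1]]][[key[2]]]
    if (is.null(val) || !is.numeric(val)) {
      stop("config must set an explicit integer seed at ", paste(key, collapse = "$"),
        call. = FALSE
      )
    }
  }
  defaults <- default_config()
  for (stage in names(defaults)) {
    config[[stage]] <- utils::modifyList(defaults[[stage]], config[[stage]] %||% list())
  }
  config
}

#' Run the full risk-model construction pipeline
#'
#' Executes simulate -> score -> encode/standardize -> screen -> CV-Lasso
#' selection -> definitive-model workflow (split / train / risk bands) ->
#' evaluation, writing every artifact (CSV/JSON) plus a Markdown report to
#' `outdir`. Deterministic: the same config yields an identical run
#' directory.
#'
#' @param config Config list (see [default_config()]); validated before use.
#' @param outdir Output directory, created if absent.
#' @return Invisibly, a list with the in-memory stage objects and `outdir`.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outdir, f)
  stage <- function(name) message("[painrisk] stage: ", name)

  yaml::write_yaml(config, pth("config.yaml"))
  jsonlite::write_json(
    list(config_hash = rlang::hash(config), seeds = list(
      cohort = config$cohort$seed, cv = config$cv$seed, split = config$split$seed
    )),
    pth("provenance.json"),
    auto_unbox = TRUE, digits = NA
  )

  stage("simulate")
  spec <- cohort_spec(
    n_respondents = config$cohort$n_respondents,
    seed = config$cohort$seed,
    target_prevalence = config$cohort$target_prevalence,
    effect_scale = config$cohort$effect_scale,
    block_correlations = config$cohort$block_correlations,
    n_incomplete = config$cohort$n_incomplete
  )
  cohort <- generate_cohort(spec)
  write_cohort(cohort, pth("cohort.csv"))

  stage("score")
  scored <- score_cohort(cohort)
  utils::write.csv(
    dplyr::mutate(scored, ipaq_category = as.character(.data$ipaq_category)),
    pth("scores.csv"),
    row.names = FALSE
  )
  excl <- exclusion_report(scored)
  jsonlite::write_json(
    purrr::map2(excl$id, excl$missing_fields, ~ list(id = .x, missing_fields = .y)),
    pth("exclusions.json"),
    auto_unbox = TRUE
  )

  stage("encode + screen")
  fm <- encode(scored)
  fm_std <- standardize(fm)
  scr <- screen(fm_std, threshold = config$screen$threshold)
  write_screen_result(scr, pth("screen.json"))

  stage("lasso selection")
  sel_plan <- cv_plan(config$cv$n_repeats, config$cv$n_folds, seed = config$cv$seed)
  sel_ens <- cross_validate(fm_subset(fm_std, scr$kept),
    plan = sel_plan,
    lambda_grid = config$lasso$lambda_grid,
    rule = config$lasso$rule
  )
  selected <- select_by_median(sel_ens)
  if (length(selected) == 0) {
    stop("stage 'lasso selection': no feature has a nonzero median coefficient", call. = FALSE)
  }
  or_tab <- or_distribution(sel_ens)
  utils::write.csv(
    dplyr::select(or_tab, -"ors"),
    pth("or_distribution.csv"),
    row.names = FALSE
  )
  write_ensemble(sel_ens, pth("cv_selection.json"))

  stage("definitive model workflow")
  model <- risk_workflow(
    fm_subset(fm, selected),
    seed = config$split$seed,
    plan = cv_plan(config$cv$n_repeats, config$cv$n_folds, seed = config$cv$seed),
    lambda_grid = config$lasso$lambda_grid,
    rule = config$lasso$final_rule
  )
  write_bands(model$bands, pth("risk_bands.json"))
  subject_scores <- model$scores |>
    dplyr::mutate(id = scored$id[.data$row], .before = 1) |>
    dplyr::select(-"row")
  utils::write.csv(subject_scores, pth("subject_scores.csv"), row.names = FALSE)

  stage("effect statistics")
  effects <- effect_summary(model$ensemble, fm$meta, features = selected)
  utils::write.csv(effects, pth("effect_table.csv"), row.names = FALSE)

  prev <- prevalence_ci(sum(scored$mskp_positive), nrow(scored))
  metrics <- list(
    n_surveyed = nrow(cohort),
    n_excluded = nrow(excl),
    n_scored = nrow(scored),
    positives = sum(scored$mskp_positive),
    prevalence = prev$point,
    prevalence_ci = c(prev$low, prev$high),
    n_features_encoded = ncol(fm$values),
    n_features_screened = length(scr$kept),
    n_features_selected = length(selected),
    selection_lambda = sel_ens$best_lambda,
    selection_mean_auc = mean(sel_ens$member_info$test_auc),
    workflow = list(
      n_train = length(model$split$train),
      n_definition = length(model$split$definition),
      n_evaluation = length(model$split$evaluation),
      lambda = model$ensemble$best_lambda,
      train_cv_auc = mean(model$ensemble$member_info$test_auc),
      evaluation_auc = model$evaluation$auc,
      lower_cut = model$bands$lower_cut,
      upper_cut = model$bands$upper_cut,
      expected_prevalence = model$bands$bands$prevalence,
      observed_prevalence = model$evaluation$comparison$observed,
      band_n_evaluation = model$evaluation$comparison$n
    )
  )
  jsonlite::write_json(metrics, pth("metrics.json"), auto_unbox = TRUE, digits = NA)

  stage("report")
  render_report(outdir)

  invisible(list(
    outdir = outdir, config = config, cohort = cohort, scored = scored,
    screen = scr, selection = sel_ens, selected = selected,
    model = model, effects = effects, metrics = metrics
  ))
}
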