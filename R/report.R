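#' Render the run report from serialized artifacts
#'
#' Regenerates `report.md` inside a completed run directory. Every number in
#' the report is read back from the run's serialized artifacts
#' (`metrics.json`, `effect_table.csv`, `screen.json`); nothing is
#' recomputed at render time, so regenerating the report is byte-identical.
#'
#' @param outdir A directory produced by [run_pipeline()].
#' @return The report path, invisibly.
#' @export
render_report <- function(outdir) {
  needed <- c("metrics.json", "effect_table.csv", "screen.json")
  missing <- needed[!file.exists(file.path(outdir, needed))]
  if (length(missing) > 0) {
    stop("incomplete run: missing artifact(s) ", paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- jsonlite::read_json(file.path(outdir, "metrics.json"), simplifyVector = TRUE)
  effects <- utils::read.csv(file.path(outdir, "effect_table.csv"))

  pc <- function(x) sprintf("%.1f%%", 100 * x)
  fmt_prev <- function(x) ifelse(is.na(x), "undefined", pc(x))

  lines <- c(
    "# MSKP risk-model run report",
    "",
    "## Cohort",
    "",
    sprintf(
      "- %d respondents surveyed; %d excluded as incomplete; %d scored.",
      m$n_surveyed, m$n_excluded, m$n_scored
    ),
    sprintf(
      "- MSKP prevalence: %s [95%% CI: %s - %s] (%d positive cases).",
      pc(m$prevalence), pc(m$prevalence_ci[1]), pc(m$prevalence_ci[2]), m$positives
    ),
    "",
    "## Feature selection",
    "",
    sprintf(
      "- Correlation screening: %d encoded features reduced to %d.",
      m$n_features_encoded, m$n_features_screened
    ),
    sprintf(
      "- CV-Lasso median rule (lambda = %g, mean fold AUC %.3f): %d features retained.",
      m$selection_lambda, m$selection_mean_auc, m$n_features_selected
    ),
    "",
    "## Effect sizes (maximum odds ratios, Bonferroni-corrected 90% CI)",
    "",
    "| parameter | range | max OR | CI low | CI high |",
    "|---|---|---|---|---|",
    sprintf(
      "| %s | %s | %.3f | %.3f | %.3f |",
      effects$parameter, effects$range, effects$max_or, effects$ci_low, effects$ci_high
    ),
    "",
    "## Risk stratification",
    "",
    sprintf(
      "- Workflow split: %d train / %d risk-definition / %d risk-evaluation.",
      m$workflow$n_train, m$workflow$n_definition, m$workflow$n_evaluation
    ),
    sprintf(
      "- Definitive ensemble: lambda = %g, train CV AUC %.3f, evaluation AUC %.3f.",
      m$workflow$lambda, m$workflow$train_cv_auc, m$workflow$evaluation_auc
    ),
    sprintf(
      "- Score cuts at %.4f and %.4f (tertiles of the risk-definition set).",
      m$workflow$lower_cut, m$workflow$upper_cut
    ),
    "",
    "| band | expected prevalence | observed prevalence | n (evaluation) |",
    "|---|---|---|---|",
    sprintf(
      "| %s | %s | %s | %d |",
      c("low", "medium", "high"),
      fmt_prev(m$workflow$expected_prevalence),
      fmt_prev(m$workflow$observed_prevalence),
      m$workflow$band_n_evaluation
    ),
    ""
  )
  path <- file.path(outdir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
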