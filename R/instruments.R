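#' Band a 0-10 pain intensity into a 0-3 severity rating
#'
#' Visual-analogue-scale pain intensities (0-10) are collapsed into four
#' severity bands: 0 (no pain), 1 (intensity 1-3), 2 (intensity 4-7) and
#' 3 (intensity above 7). These per-region ratings are the building blocks
#' of the MSKP severity index.
#'
#' @param intensity Integer vector of pain intensities in 0-10. `NA` values
#'   propagate (the record is later flagged incomplete by [score_cohort()]).
#' @return Integer vector of ratings in \{0, 1, 2, 3\}.
#' @examples
#' rate_region(c(0, 3, 7, 8))
#' @export
rate_region <- function(intensity) {
  bad <- !is.na(intensity) & (intensity < 0 | intensity > 10 | intensity != round(intensity))
  if (any(bad)) {
    stop(
      "pain intensity out of range 0-10 at position(s): ",
      paste(which(bad), collapse = ", "),
      call. = FALSE
    )
  }
  out <- rep(NA_integer_, length(intensity))
  ok <- !is.na(intensity)
  out[ok] <- as.integer(cut(as.numeric(intensity[ok]), c(-0.5, 0.5, 3.5, 7.5, 10.5))) - 1L
  out
}

#' MSKP severity index for one respondent
#'
#' Sums the banded severity ratings over the four body regions (neck,
#' shoulders, middle back, lower back). The index ranges 0-12; an index of 4
#' or more defines a positive case of intense musculoskeletal pain. Because a
#' single region contributes at most 3 points, positivity requires
#' significant pain in at least two locations.
#'
#' @param intensities Numeric vector of exactly 4 pain intensities (0-10).
#' @return A list of class `mskp_result` with elements `region_ratings`
#'   (4 integers in 0-3), `index` (0-12) and `positive` (logical).
#' @examples
#' mskp_index(c(5, 5, 0, 0))$positive # TRUE: two moderately painful regions
#' mskp_index(c(8, 0, 0, 0))$positive # FALSE: one region caps at 3 points
#' @export
mskp_index <- function(intensities) {
  if (length(intensities) != 4L) {
    stop("`intensities` must contain exactly 4 region intensities", call. = FALSE)
  }
  ratings <- rate_region(intensities)
  idx <- sum(ratings)
  structure(
    list(region_ratings = ratings, index = idx, positive = !is.na(idx) && idx >= 4L),
    class = "mskp_result"
  )
}

#' @export
print.mskp_result <- function(x, ...) {
  cat(
    "MSKP index:", x$index, "(ratings:", paste(x$region_ratings, collapse = ", "),
    ")", if (isTRUE(x$positive)) "- positive case" else "- negative case", "\n"
  )
  invisible(x)
}

#' Mobile Dependency Test total score
#'
#' The short Mobile Dependency Test (TDM) has 22 Likert items scored 0-4;
#' the total ranges 0-88, higher meaning greater dependency.
#'
#' @param items Numeric vector of 22 item responses in 0-4. Any `NA` yields
#'   an `NA` total (the record is incomplete).
#' @return Integer total in 0-88, or `NA`.
#' @export
tdm_total <- function(items) {
  if (length(items) != 22L) {
    stop("the Mobile Dependency Test has exactly 22 items; got ", length(items), call. = FALSE)
  }
  bad <- !is.na(items) & (items < 0 | items > 4)
  if (any(bad)) {
    stop("TDM items must lie in 0-4; offending position(s): ",
      paste(which(bad), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyNA(items)) {
    return(NA_integer_)
  }
  as.integer(sum(items))
}

#' Five-level physical-activity category from weekly MET-minutes
#'
#' Categorizes weekly energy expenditure into the five activity levels used
#' in the survey summary (very low to very high). The survey instrument
#' prints the five labels but no cutpoints, so the thresholds are exposed as
#' an argument; defaults are 0-599 / 600-1499 / 1500-2999 / 3000-4499 /
#' >= 4500 MET-minutes per week.
#'
#' @param met_minutes Numeric vector of weekly MET-minutes (>= 0).
#' @param thresholds Increasing numeric vector of 4 interior cutpoints.
#' @return Ordered factor with levels `very_low < low < moderate < high <
#'   very_high`.
#' @export
ipaq_category <- function(met_minutes, thresholds = c(600, 1500, 3000, 4500)) {
  stopifnot(length(thresholds) == 4L, !is.unsorted(thresholds))
  lv <- c("very_low", "low", "moderate", "high", "very_high")
  cut(met_minutes,
    breaks = c(-Inf, thresholds, Inf), labels = lv,
    right = FALSE, ordered_result = TRUE
  )
}

# column-name conventions shared by the scorer and the cohort generator
.tdm_cols <- function() sprintf("tdm_item_%02d", 1:22)
.sleep_cols <- function() sprintf("sleep_factor_%d", 1:6)
.pain_cols <- function() c("pain_neck", "pain_shoulders", "pain_midback", "pain_lowback")

#' Score a survey cohort
#'
#' Applies every instrument scorer to a cohort of raw survey records:
#' the TDM total (`mobile_dependency`), the six sleep-disturbance factor
#' scores (passed through), the physical-activity category, and the MSKP
#' index with its positivity flag. Records missing any scored item are
#' excluded (complete-case rule) and reported.
#'
#' @param records A data frame with one row per respondent, as produced by
#'   [generate_cohort()] (see [cohort_dictionary()] for the column layout).
#' @return A tibble of scored respondents with columns `mobile_dependency`,
#'   `sleep_factor_1` ... `sleep_factor_6`, `met_minutes`, `ipaq_category`,
#'   `mskp_index`, `mskp_positive` plus all sociodemographic / activity /
#'   chore columns, with attribute `exclusions`: a tibble listing dropped
#'   record ids and their missing fields.
#' @export
score_cohort <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c(.tdm_cols(), .sleep_cols(), .pain_cols())
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort lacks required columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"id" %in% names(records)) {
    records$id <- sprintf("S%04d", seq_len(nrow(records)))
  }

  item_na <- is.na(records[needed])
  incomplete <- rowSums(item_na) > 0
  exclusions <- tibble::tibble(
    id = records$id[incomplete],
    missing_fields = purrr::map(which(incomplete), ~ needed[item_na[.x, ]])
  )
  kept <- records[!incomplete, , drop = FALSE]
  if (nrow(kept) == 0) {
    stop("empty cohort: every record is missing at least one scored item", call. = FALSE)
  }

  tdm <- apply(as.matrix(kept[.tdm_cols()]), 1, tdm_total)
  ratings <- vapply(.pain_cols(), function(cn) rate_region(kept[[cn]]), integer(nrow(kept)))
  ratings <- matrix(ratings, nrow = nrow(kept))
  idx <- as.integer(rowSums(ratings))

  activity_cols <- grep("^activity_", names(kept), value = TRUE)
  met <- if ("met_minutes" %in% names(kept)) {
    kept$met_minutes
  } else {
    200 * rowSums(as.matrix(kept[activity_cols]) - 1)
  }

  scored <- kept |>
    dplyr::select(-dplyr::all_of(c(.tdm_cols(), .pain_cols()))) |>
    dplyr::mutate(
      mobile_dependency = tdm,
      met_minutes = met,
      ipaq_category = ipaq_category(met),
      mskp_index = idx,
      mskp_positive = idx >= 4L,
      .after = dplyr::last_col()
    )
  attr(scored, "exclusions") <- exclusions
  scored
}

#' Exclusion report from a scored cohort
#'
#' @param scored A tibble returned by [score_cohort()].
#' @return Tibble with one row per excluded record (`id`, `missing_fields`).
#' @export
exclusion_report <- function(scored) {
  attr(scored, "exclusions") %||%
    tibble::tibble(id = character(), missing_fields = list())
}
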