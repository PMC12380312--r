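#' Encode a scored cohort into a numeric feature matrix
#'
#' One-hot encodes every categorical variable (each level becomes an
#' indicator column sharing a categorical-group id) and passes numeric items
#' through, yielding a completely numerical design with per-column metadata
#' (observed range, mean, SD, group). Column order is deterministic. The
#' outcome column is held separately from the predictors.
#'
#' @param data Scored cohort tibble from [score_cohort()] (or any data frame
#'   of respondent-level variables).
#' @param outcome Name of the binary outcome column (default
#'   `"mskp_positive"`); set `NULL` if the data carry no outcome.
#' @param exclude Columns never used as predictors.
#' @param template A `feature_matrix` from a previous [encode()] call; its
#'   categorical levels and column set are reused so held-out rows map onto
#'   the same design. An unseen level raises an error naming it.
#' @return An object of class `feature_matrix`: list with `values` (n x p
#'   numeric matrix), `meta` (per-column tibble), `outcome` (0/1 vector or
#'   `NULL`) and `levels` (named list of categorical levels).
#' @export
encode <- function(data, outcome = "mskp_positive",
                   exclude = c("id", "met_minutes", "mskp_index", "age_years", "age_group_16_18"),
                   template = NULL) {
  data <- tibble::as_tibble(data)
  y <- NULL
  if (!is.null(outcome) && outcome %in% names(data)) {
    y <- as.integer(data[[outcome]])
    exclude <- c(exclude, outcome)
  }
  preds <- data[setdiff(names(data), exclude)]

  is_cat <- vapply(preds, function(x) is.character(x) || is.factor(x), logical(1))
  lev <- if (is.null(template)) {
    lapply(preds[is_cat], function(x) sort(unique(as.character(x))))
  } else {
    template$levels
  }

  cols <- list()
  meta <- list()
  for (nm in names(preds)) {
    x <- preds[[nm]]
    if (is_cat[[nm]]) {
      if (!nm %in% names(lev)) {
        stop("column '", nm, "' is categorical but absent from the encoding template", call. = FALSE)
      }
      unseen <- setdiff(unique(as.character(x)), lev[[nm]])
      if (length(unseen) > 0) {
        stop(
          "unseen level(s) in '", nm, "': ", paste(unseen, collapse = ", "),
          call. = FALSE
        )
      }
      for (lv in lev[[nm]]) {
        cn <- gsub("[^A-Za-z0-9_]", "_", paste(nm, lv, sep = "_"))
        cols[[cn]] <- as.numeric(as.character(x) == lv)
        meta[[cn]] <- tibble::tibble(name = cn, group = nm)
      }
    } else {
      cols[[nm]] <- as.numeric(x)
      meta[[nm]] <- tibble::tibble(name = nm, group = NA_character_)
    }
  }
  ord <- order(names(cols))
  values <- do.call(cbind, cols[ord])
  meta <- dplyr::bind_rows(meta[ord])
  meta <- meta |>
    dplyr::mutate(
      min = apply(values, 2, min),
      max = apply(values, 2, max),
      mean = colMeans(values),
      sd = apply(values, 2, stats::sd),
      constant = .data$sd == 0
    )
  structure(
    list(values = values, meta = meta, outcome = y, levels = lev,
         standardized = FALSE, stats = NULL),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(
    "<feature_matrix>", nrow(x$values), "x", ncol(x$values),
    if (isTRUE(x$standardized)) "(standardized)" else "(raw)",
    "|", sum(!is.na(x$meta$group)), "one-hot columns in",
    length(unique(stats::na.omit(x$meta$group))), "groups\n"
  )
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' Keep a subset of feature columns
#'
#' @param fm A `feature_matrix`.
#' @param keep Character vector of column names to retain.
#' @return A `feature_matrix` restricted to `keep` (original order).
#' @export
fm_subset <- function(fm, keep) {
  stopifnot(inherits(fm, "feature_matrix"))
  missing <- setdiff(keep, colnames(fm$values))
  if (length(missing) > 0) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  sel <- colnames(fm$values) %in% keep
  fm$values <- fm$values[, sel, drop = FALSE]
  fm$meta <- fm$meta[sel, , drop = FALSE]
  if (!is.null(fm$stats)) fm$stats <- fm$stats[fm$stats$name %in% keep, , drop = FALSE]
  fm
}

#' Subset rows of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param rows Integer or logical row index.
#' @return A `feature_matrix` with the selected rows (metadata and
#'   standardization statistics untouched).
#' @export
fm_rows <- function(fm, rows) {
  stopifnot(inherits(fm, "feature_matrix"))
  fm$values <- fm$values[rows, , drop = FALSE]
  if (!is.null(fm$outcome)) fm$outcome <- fm$outcome[rows]
  fm
}

#' Standardize a feature matrix to z-scores
#'
#' Centers and scales every column with the supplied (training) statistics,
#' or with statistics computed from the matrix itself. Constant columns are
#' left at zero and flagged, never divided by zero. The fitted statistics are
#' stored so held-out rows can be transformed identically.
#'
#' @param fm A `feature_matrix`.
#' @param stats Optional tibble `(name, center, scale)` from a previous call
#'   (retrieve with `fm$stats`).
#' @return The standardized `feature_matrix` with `$stats` filled in.
#' @export
standardize <- function(fm, stats = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(stats)) {
    stats <- tibble::tibble(
      name = colnames(fm$values),
      center = unname(colMeans(fm$values)),
      scale = unname(apply(fm$values, 2, stats::sd))
    )
  }
  stats <- stats[match(colnames(fm$values), stats$name), , drop = FALSE]
  if (anyNA(stats$name)) {
    stop("standardization statistics missing for some columns", call. = FALSE)
  }
  v <- sweep(fm$values, 2, stats$center, "-")
  sc <- ifelse(stats$scale > 0, stats$scale, 1)
  v <- sweep(v, 2, sc, "/")
  v[, stats$scale == 0] <- 0
  fm$values <- v
  fm$stats <- stats
  fm$standardized <- TRUE
  fm
}

#' Spearman correlation matrix of a feature set
#'
#' Rank correlation with average ranks for ties. A constant column has no
#' ranks to correlate; its correlations are defined as 0 and the column is
#' flagged in the `constant` attribute.
#'
#' @param x A `feature_matrix`, matrix or data frame with at least 3 rows.
#' @return Symmetric p x p matrix with unit diagonal, values in \[-1, 1\].
#' @export
spearman_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 rows for a rank correlation", call. = FALSE)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  const <- apply(x, 2, function(col) length(unique(col)) == 1)
  rho[const, ] <- 0
  rho[, const] <- 0
  diag(rho) <- 1
  attr(rho, "constant") <- colnames(x)[const]
  rho
}

#' Correlation-driven feature screening
#'
#' First feature-selection step. The reference level of every one-hot group
#' is dropped (it is the logistic baseline), then features are clustered by
#' average-linkage on the distance 1 - |Spearman rho| and the tree is cut at
#' height 1 - `threshold`. Within each multi-feature cluster exactly one
#' representative is kept: the feature with the largest absolute Spearman
#' correlation with the outcome (ties broken alphabetically). The published
#' analysis screened manually from the correlation dendrogram; this
#' automatic, deterministic rule replaces that judgement call.
#'
#' @param fm A `feature_matrix` carrying an outcome.
#' @param threshold Absolute-correlation cutoff in (0, 1); features whose
#'   cluster joins below distance `1 - threshold` are collapsed. Default 0.5.
#' @param outcome Optional 0/1 vector overriding `fm$outcome`.
#' @return An object of class `screen_result`: `kept` (character),
#'   `dropped` (tibble: name, cluster, reason, representative),
#'   `correlation` (full Spearman matrix), `tree` (hclust), `threshold`.
#' @export
screen <- function(fm, threshold = 0.5, outcome = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!(threshold > 0 && threshold < 1)) {
    stop("`threshold` must lie strictly inside (0, 1)", call. = FALSE)
  }
  y <- outcome %||% fm$outcome
  if (is.null(y)) stop("screening needs the outcome to pick cluster representatives", call. = FALSE)

  all_names <- colnames(fm$values)
  rho_full <- spearman_matrix(fm)

  # drop one reference level per one-hot group (alphabetically first)
  refs <- fm$meta |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(ref = sort(.data$name)[1], .groups = "drop")
  dropped <- tibble::tibble(
    name = refs$ref,
    cluster = NA_integer_,
    reason = "one-hot reference level",
    representative = NA_character_
  )

  work <- setdiff(all_names, refs$ref)
  rho <- rho_full[work, work, drop = FALSE]
  ocorr <- vapply(
    work,
    function(nm) {
      r <- suppressWarnings(stats::cor(fm$values[, nm], y, method = "spearman"))
      if (is.na(r)) 0 else r
    },
    numeric(1)
  )

  if (length(work) >= 2) {
    hc <- stats::hclust(stats::as.dist(1 - abs(rho)), method = "average")
    cl <- stats::cutree(hc, h = 1 - threshold)
  } else {
    hc <- NULL
    cl <- stats::setNames(rep(1L, length(work)), work)
  }

  kept <- character()
  for (k in sort(unique(cl))) {
    members <- names(cl)[cl == k]
    rep_name <- members[order(-abs(ocorr[members]), members)][1]
    kept <- c(kept, rep_name)
    losers <- setdiff(members, rep_name)
    if (length(losers) > 0) {
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        name = losers,
        cluster = as.integer(k),
        reason = "collapsed into correlated cluster",
        representative = rep_name
      ))
    }
  }
  kept <- all_names[all_names %in% kept] # original column order

  structure(
    list(
      kept = kept, dropped = dropped, correlation = rho_full,
      tree = hc, threshold = threshold
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(
    "<screen_result> kept", length(x$kept), "of",
    length(x$kept) + nrow(x$dropped), "features (|rho| threshold",
    x$threshold, ")\n"
  )
  invisible(x)
}

#' @rdname screen
#' @param x A `screen_result`.
#' @param ... Unused.
#' @export
tidy.screen_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      name = x$kept, cluster = NA_integer_,
      reason = "kept", representative = NA_character_
    ),
    x$dropped
  )
}

#' Serialize a screening result to JSON
#'
#' @param x A `screen_result`.
#' @param path Output path.
#' @export
write_screen_result <- function(x, path) {
  jsonlite::write_json(
    list(
      threshold = x$threshold,
      kept = x$kept,
      dropped = x$dropped
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
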