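#' Read a subject-level cohort from CSV
#'
#' The expected layout is one row per subject with columns `subject_id`,
#' `center`, one column per candidate predictor, and the binary outcome
#' columns `mild_aki`, `severe_aki`, `death_1y`, `death_3y`. Empty cells are
#' missing values. Outcome columns other than `mild_aki` may be absent or
#' missing; missingness is handled per analysis via
#' [complete_case_filter()].
#'
#' @param path path to a CSV file (comma-separated, UTF-8, header row).
#' @param schema predictor schema, as returned by [aki_predictors()].
#' @return A cohort: a data frame of class `"aki_cohort"` with the schema
#'   attached as attribute `"schema"`.
#' @export
read_cohort <- function(path, schema = aki_predictors()) {
  validate_schema(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  check.names = FALSE, fileEncoding = "UTF-8")
  required <- c(cohort_id_cols(), schema$name, "mild_aki", "severe_aki")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  known <- c(cohort_id_cols(), schema$name, cohort_outcome_cols())
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown column(s) not in schema: ", paste(unknown, collapse = ", "))
  }
  for (oc in setdiff(cohort_outcome_cols(), names(raw))) raw[[oc]] <- NA
  raw <- raw[, c(cohort_id_cols(), schema$name, cohort_outcome_cols())]

  raw$subject_id <- as.character(raw$subject_id)
  raw$center <- as.character(raw$center)
  for (v in schema$name) {
    x <- raw[[v]]
    if (!is.numeric(x)) {
      conv <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(conv))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value for predictor '%s' at row %d: '%s'",
                     v, bad[1], x[bad[1]]))
      }
      x <- conv
    }
    raw[[v]] <- x
  }
  for (v in cohort_outcome_cols()) {
    x <- suppressWarnings(as.numeric(raw[[v]]))
    ok <- is.na(x) | x %in% c(0, 1)
    if (!all(ok)) {
      stop(sprintf("outcome '%s' must be binary 0/1; offending row %d",
                   v, which(!ok)[1]))
    }
    raw[[v]] <- as.integer(x)
  }
  as_cohort(raw, schema)
}

as_cohort <- function(df, schema = aki_predictors()) {
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup) > 0) {
    stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  }
  if (any(is.na(df$center))) stop("missing center label")
  rownames(df) <- NULL
  structure(df, schema = schema, class = c("aki_cohort", "data.frame"))
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells, so a
#' read/write round trip preserves both values and the missingness pattern.
#'
#' @param cohort an `aki_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "",
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.aki_cohort <- function(x, ...) {
  schema <- attr(x, "schema")
  cat(sprintf("<aki_cohort> %d subjects, %d centers, %d candidate predictors\n",
              nrow(x), length(unique(x$center)), nrow(schema)))
  cat(sprintf("  mild AKI: %d (%.1f%%), severe AKI: %d (%.1f%%)\n",
              sum(x$mild_aki, na.rm = TRUE),
              100 * mean(x$mild_aki, na.rm = TRUE),
              sum(x$severe_aki, na.rm = TRUE),
              100 * mean(x$severe_aki, na.rm = TRUE)))
  n_miss <- sum(!stats::complete.cases(x[, schema$name, drop = FALSE]))
  cat(sprintf("  subjects missing >=1 predictor: %d (%.1f%%)\n",
              n_miss, 100 * n_miss / nrow(x)))
  invisible(x)
}

#' Complete-case filter on a set of predictors
#'
#' Retains only subjects with no missing value among the named predictors;
#' analyses of different outcomes or combinations use their own
#' complete-case sets. Subject order is preserved and the operation is
#' idempotent.
#'
#' @param cohort an `aki_cohort`.
#' @param predictors predictor names to require (default: full schema).
#' @param outcome optional outcome column also required non-missing.
#' @return The filtered cohort, with attribute `"counts"`: a list with
#'   `removed`, `retained`, and `cases_retained` (for `mild_aki`, or the
#'   given outcome).
#' @export
complete_case_filter <- function(cohort, predictors = NULL, outcome = NULL) {
  schema <- attr(cohort, "schema")
  if (is.null(predictors)) predictors <- schema$name
  bad <- setdiff(predictors, schema$name)
  if (length(bad) > 0) {
    stop("predictors not in schema: ", paste(bad, collapse = ", "))
  }
  keep <- stats::complete.cases(
    as.data.frame(cohort)[, predictors, drop = FALSE])
  if (!is.null(outcome)) keep <- keep & !is.na(cohort[[outcome]])
  if (!any(keep)) stop("complete-case filter removed every subject")
  out <- as_cohort(as.data.frame(cohort)[keep, , drop = FALSE], schema)
  case_col <- if (is.null(outcome)) "mild_aki" else outcome
  attr(out, "counts") <- list(
    removed = sum(!keep), retained = sum(keep),
    cases_retained = sum(out[[case_col]] == 1, na.rm = TRUE))
  out
}

#' Build the analysis matrix for one outcome
#'
#' Applies the schema transforms (natural log for skewed biomarkers,
#' identity for signed or linear terms), encodes center as reference-cell
#' indicators (first label in sorted order is the reference), and attaches
#' the binary outcome. The cohort must already be complete-case filtered
#' for the requested predictors.
#'
#' @param cohort an `aki_cohort` with no missing values among `predictors`.
#' @param predictors predictor names (default: full schema, in schema order).
#' @param outcome outcome column name (default `"mild_aki"`).
#' @return An object of class `"aki_matrix"`: a list with candidate matrix
#'   `x` (transformed, n x p), forced center-indicator matrix `z`
#'   (n x (C-1)), outcome `y`, `center` factor, `subject_id`, and naming
#'   metadata.
#' @export
build_analysis_matrix <- function(cohort, predictors = NULL,
                                  outcome = "mild_aki") {
  schema <- attr(cohort, "schema")
  if (is.null(predictors)) predictors <- schema$name
  spec <- schema[match(predictors, schema$name), , drop = FALSE]
  if (anyNA(spec$name)) {
    stop("predictors not in schema: ",
         paste(setdiff(predictors, schema$name), collapse = ", "))
  }
  if (!outcome %in% names(cohort)) stop("outcome column absent: ", outcome)
  df <- as.data.frame(cohort)
  keep <- !is.na(df[[outcome]])
  df <- df[keep, , drop = FALSE]
  y <- as.integer(df[[outcome]])
  if (any(is.na(df[, spec$name, drop = FALSE]))) {
    stop("missing predictor values; run complete_case_filter() first")
  }

  x <- matrix(NA_real_, nrow(df), nrow(spec),
              dimnames = list(NULL, spec$name))
  for (i in seq_len(nrow(spec))) {
    v <- df[[spec$name[i]]]
    if (spec$transform[i] == "log") {
      if (any(v <= 0)) {
        stop(sprintf(
          "nonpositive value(s) under log transform for '%s' (subjects %s)",
          spec$name[i],
          paste(head(df$subject_id[v <= 0], 5), collapse = ", ")))
      }
      v <- log(v)
    }
    x[, i] <- v
  }

  levels <- sort(unique(df$center))
  center <- factor(df$center, levels = levels)
  if (length(levels) > 1) {
    z <- matrix(0, nrow(df), length(levels) - 1,
                dimnames = list(NULL, paste0("center", levels[-1])))
    for (j in seq_along(levels)[-1]) {
      z[center == levels[j], j - 1] <- 1
    }
  } else {
    z <- matrix(numeric(0), nrow(df), 0)
  }

  structure(list(
    x = x, z = z, y = y, center = center,
    subject_id = df$subject_id,
    predictor_names = spec$name,
    outcome = outcome,
    reference_center = levels[1],
    n = nrow(df)
  ), class = "aki_matrix")
}

#' @export
print.aki_matrix <- function(x, ...) {
  cat(sprintf(
    "<aki_matrix> n=%d, p=%d candidates, %d centers (ref '%s'), outcome '%s' (%d cases)\n",
    x$n, ncol(x$x), nlevels(x$center), x$reference_center, x$outcome,
    sum(x$y)))
  invisible(x)
}

#' Row subset of an analysis matrix
#'
#' Used by the bootstrap and split-sample machinery; duplicate indices are
#' allowed (sampling with replacement).
#'
#' @param matrix an `aki_matrix`.
#' @param idx integer row indices.
#' @return An `aki_matrix` on the selected rows (center levels unchanged).
#' @export
matrix_rows <- function(matrix, idx) {
  out <- matrix
  out$x <- matrix$x[idx, , drop = FALSE]
  out$z <- matrix$z[idx, , drop = FALSE]
  out$y <- matrix$y[idx]
  out$center <- matrix$center[idx]
  out$subject_id <- matrix$subject_id[idx]
  out$n <- length(idx)
  out
}
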