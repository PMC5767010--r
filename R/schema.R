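#' Candidate predictor schema
#'
#' The default candidate set for postoperative AKI combinations: 22
#' biomarkers measured 0-6 h after cardiac surgery plus cardiopulmonary
#' bypass (CPB) time, 23 candidates in all. Skewed biomarker concentrations
#' enter the analysis on the natural-log scale; the signed change in serum
#' creatinine (which is negative for many patients) and CPB time enter
#' linearly. Center indicators are forced into every model and are not part
#' of the candidate set.
#'
#' @return A data frame with one row per candidate predictor and columns
#'   `name`, `transform` (`"log"` or `"identity"`) and `forced` (always
#'   `FALSE` for candidates).
#' @examples
#' aki_predictors()
#' @export
aki_predictors <- function() {
  log_markers <- c(
    # urine
    "ucr", "uil18", "ungal", "ualb", "ukim1", "ulfabp", "ucysc",
    # plasma
    "pbnp", "pngal", "pil10", "pil6", "pntprobnp", "ptni", "ptnths",
    "pckmb", "phfabp", "pmcp1", "pegf", "pvegf",
    # serum creatinine (0-6 h postoperative, and pre/post average)
    "post_cr", "avg_cr"
  )
  identity_vars <- c("delta_cr", "cpb_time")
  data.frame(
    name = c(log_markers, identity_vars),
    transform = c(rep("log", length(log_markers)),
                  rep("identity", length(identity_vars))),
    forced = FALSE,
    stringsAsFactors = FALSE
  )
}

# Columns a cohort CSV must carry besides the predictors.
cohort_id_cols <- function() c("subject_id", "center")
cohort_outcome_cols <- function() c("mild_aki", "severe_aki",
                                    "death_1y", "death_3y")

validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema),
            all(c("name", "transform") %in% names(schema)))
  if (anyDuplicated(schema$name)) {
    stop("duplicate predictor names in schema")
  }
  bad <- !schema$transform %in% c("log", "identity")
  if (any(bad)) {
    stop("unknown transform(s): ",
         paste(unique(schema$transform[bad]), collapse = ", "))
  }
  invisible(schema)
}
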