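# Bitmask helpers for candidate-predictor subsets. A model is an integer
# whose bit j (0-based) flags inclusion of candidate j; forced covariates
# (intercept, center indicators) never appear in the mask.

#' Size of a candidate-subset bitmask
#'
#' @param mask integer bitmask(s) over candidate predictors.
#' @return Integer vector: number of candidates included in each mask.
#' @export
mask_size <- function(mask) {
  vapply(mask, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:30)) != 0L),
         integer(1))
}

#' Candidate indices included in a bitmask
#'
#' @param mask a single integer bitmask.
#' @param p number of candidate predictors.
#' @return Integer vector of 1-based candidate indices.
#' @export
mask_indices <- function(mask, p) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
}

#' Build a bitmask from candidate indices
#'
#' @param idx 1-based candidate indices (possibly empty).
#' @return A single integer bitmask.
#' @export
mask_from_indices <- function(idx) {
  if (length(idx) == 0) return(0L)
  as.integer(sum(bitwShiftL(1L, as.integer(idx) - 1L)))
}

#' Predictor names included in a bitmask
#'
#' @param mask a single integer bitmask.
#' @param names character vector of candidate predictor names, in column
#'   order of the analysis matrix.
#' @return Character vector of included predictor names.
#' @export
mask_names <- function(mask, names) {
  names[mask_indices(mask, length(names))]
}

#' Build a bitmask from predictor names
#'
#' @param which character vector of predictor names to include.
#' @param names candidate predictor names in analysis-matrix column order.
#' @return A single integer bitmask.
#' @export
mask_from_names <- function(which, names) {
  idx <- match(which, names)
  if (anyNA(idx)) {
    stop("unknown predictor name(s): ",
         paste(which[is.na(idx)], collapse = ", "))
  }
  mask_from_indices(idx)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
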