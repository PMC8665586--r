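#' Canonical predictor set
#'
#' The ten predictors used throughout: the three CSF isoforms, their
#' three pairwise ratios, age, education, sex and APOE e4 carrier
#' status, in the fixed order that defines subset bitmask indices.
#'
#' @return Character vector of the ten canonical feature names.
#' @export
canonical_features <- function() {
  c("ab38", "ab40", "ab42", "r4240", "r4238", "r4038",
    "age", "education", "sex", "apoe4")
}

#' Build the predictor matrix and outcome labels from a cohort
#'
#' Computes the three isoform ratios (`r4240 = ab42/ab40`,
#' `r4238 = ab42/ab38`, `r4038 = ab40/ab38`), assembles the ten
#' canonical predictors, and derives both binary outcomes by strict
#' thresholding: T+ if p-tau181 > `ptau_threshold`, N+ if t-tau >
#' `ttau_threshold`.  Subjects with any missing predictor or a
#' non-positive denominator isoform are dropped with a message.
#'
#' @param cohort A `cohort_table` data frame.
#' @param ptau_threshold,ttau_threshold Positivity cut-offs, pg/mL.
#' @return A list of class `"feature_set"`: `features` (data frame with
#'   the ten canonical columns), `id`, `label_T`, `label_N` (integer
#'   0/1 vectors), and `n_dropped`.
#' @examples
#' fs <- build_features(generate_cohort(generator_config(n_subjects = 50)))
#' colnames(fs$features)
#' @export
build_features <- function(cohort, ptau_threshold = 19.2, ttau_threshold = 242) {
  needed <- c("id", "age", "sex", "education", "apoe4",
              "ab38", "ab40", "ab42", "ptau", "ttau")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop_invalid("cohort lacks columns: ", paste(missing_cols, collapse = ", "))

  ok <- complete.cases(cohort[, needed]) &
    cohort$ab38 > 0 & cohort$ab40 > 0 & cohort$ab42 > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("build_features: dropped ", n_dropped,
            " subject(s) with missing or non-positive predictors")
  x <- cohort[ok, , drop = FALSE]

  features <- data.frame(
    ab38 = x$ab38, ab40 = x$ab40, ab42 = x$ab42,
    r4240 = x$ab42 / x$ab40,
    r4238 = x$ab42 / x$ab38,
    r4038 = x$ab40 / x$ab38,
    age = x$age, education = x$education,
    sex = x$sex, apoe4 = x$apoe4
  )
  structure(
    list(features = features,
         id = x$id,
         label_T = as.integer(x$ptau > ptau_threshold),
         label_N = as.integer(x$ttau > ttau_threshold),
         n_dropped = n_dropped),
    class = "feature_set"
  )
}

#' Enumerate every non-empty feature subset
#'
#' Produces all `2^k - 1` non-empty subsets of `feature_names` in
#' ascending-bitmask order; bit `i` of the index corresponds to the
#' `i`-th name in the given (canonical) order, so the index uniquely
#' identifies membership.  For the ten canonical predictors this yields
#' the full catalogue of 1023 candidate predictor sets.
#'
#' @param feature_names Character vector, 1 to 20 names.
#' @return A list of `"feature_subset"` objects, each with `index`
#'   (bitmask) and `features` (names in canonical order).
#' @examples
#' length(enumerate_subsets(canonical_features()))  # 1023
#' @export
enumerate_subsets <- function(feature_names = canonical_features()) {
  k <- length(feature_names)
  if (k < 1L) stop_invalid("feature_names must contain at least one name")
  if (k > 20L) stop_invalid("at most 20 features are supported")
  if (anyDuplicated(feature_names)) stop_invalid("feature names must be unique")
  lapply(seq_len(2^k - 1L), function(ix) {
    bits <- as.logical(bitwAnd(ix, 2^(seq_len(k) - 1L)))
    structure(list(index = ix, features = feature_names[bits]),
              class = "feature_subset")
  })
}

#' @method print feature_subset
#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("subset #%d: {%s}\n", x$index, paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Serialize feature subsets to JSON
#'
#' @param subsets A list from [enumerate_subsets()].
#' @param path Output file.
#' @export
write_subsets <- function(subsets, path) {
  jsonlite::write_json(
    lapply(subsets, function(s) list(index = s$index, features = s$features)),
    path, auto_unbox = TRUE
  )
  invisible(path)
}
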