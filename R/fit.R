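#' Fit the amyloid-beta A/T/N prediction model
#'
#' High-level modelling interface over the subset-search framework.
#' Splits the cohort into a stratified hold-out test set and a search
#' set, enumerates the requested feature subsets, tunes the nine
#' classifier families per subset by nested cross-validation, and
#' evaluates the overall winner on the untouched test set.
#'
#' @param cohort A `cohort_table` (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @param outcome `"T"` (tau pathology) or `"N"` (neurodegeneration).
#' @param feature_names Features to search over (default the canonical
#'   ten; all `2^k - 1` subsets are evaluated, so k drives cost).
#' @param algorithms Classifier roster, see [default_algorithms()].
#' @param config A [cv_config()]; its `seed` governs the hold-out
#'   split, folds and stochastic learners, its `test_fraction` the
#'   hold-out size.
#' @param progress_every Passed to [run_search()].
#' @return An object of class `"atn_fit"` with components `search`
#'   (the ranked `subset_search`), `evaluation` (`final_evaluation`),
#'   `strata` (TP/FP/TN/FN id lists), `outcome`, and the split indices.
#'   Methods: `print`, `summary`, `predict`, `plot`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(generator_config(n_subjects = 200, seed = 7))
#' fit <- fit_atn(coh, "T", feature_names = c("ab38", "r4240"),
#'                algorithms = default_algorithms("reduced"))
#' print(fit)
#' }
#' @export
fit_atn <- function(cohort, outcome = c("T", "N"),
                    feature_names = canonical_features(),
                    algorithms = default_algorithms("reduced"),
                    config = cv_config(), progress_every = 0) {
  outcome <- match.arg(outcome)
  fs <- build_features(cohort)
  labels <- if (outcome == "T") fs$label_T else fs$label_N
  n <- nrow(fs$features)

  # stratified hold-out split, before any search
  set.seed(derive_seed(config$seed, "holdout"))
  test_idx <- unlist(lapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    sample(idx, round(config$test_fraction * length(idx)))
  }))
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)

  subsets <- enumerate_subsets(feature_names)
  search <- run_search(fs$features[train_idx, , drop = FALSE],
                       labels[train_idx], subsets, algorithms, config,
                       ids = fs$id[train_idx],
                       progress_every = progress_every)
  evaluation <- evaluate_winner(search,
                                fs$features[test_idx, , drop = FALSE],
                                labels[test_idx],
                                test_ids = fs$id[test_idx])
  structure(
    list(search = search, evaluation = evaluation,
         strata = stratify_predictions(evaluation),
         outcome = outcome, feature_names = feature_names,
         train_idx = train_idx, test_idx = test_idx,
         feature_set = fs),
    class = "atn_fit"
  )
}

#' @method print atn_fit
#' @export
print.atn_fit <- function(x, ...) {
  cat(sprintf("Amyloid-beta %s%s prediction model (n = %d search + %d test)\n",
              x$outcome, "+", length(x$train_idx), length(x$test_idx)))
  print(x$evaluation)
  invisible(x)
}

#' @method summary atn_fit
#' @export
summary.atn_fit <- function(object, n = 10, ...) {
  cat(sprintf("Outcome %s+; %d subsets searched over features {%s}\n",
              object$outcome, nrow(object$search$results),
              paste(object$feature_names, collapse = ", ")))
  cat("\nTop subsets by AUC - SD:\n")
  print(utils::head(object$search$results[, c("features", "family",
                                              "auc_mean", "auc_sd")], n),
        row.names = FALSE)
  cat("\n")
  print(object$evaluation)
  strata <- object$strata
  cat(sprintf("  prediction strata: TP=%d FP=%d TN=%d FN=%d\n",
              length(strata$tp), length(strata$fp),
              length(strata$tn), length(strata$fn)))
  invisible(object)
}

#' Predict positivity scores for new subjects
#'
#' Refits the winning model on the full search data and scores a new
#' cohort.
#'
#' @param object An `atn_fit`.
#' @param newdata A `cohort_table` or a data frame already holding the
#'   canonical feature columns.
#' @param ... Unused.
#' @return Numeric score vector (probability or decision value,
#'   depending on the winning family).
#' @export
predict.atn_fit <- function(object, newdata, ...) {
  feats <- if (all(object$evaluation$winner$features %in% names(newdata)))
    newdata else build_features(newdata)$features
  search <- object$search
  winner <- object$evaluation$winner
  spec <- search$algorithms[[winner$family]]
  X_train <- as.matrix(search$features[, winner$features, drop = FALSE])
  X_new <- as.matrix(feats[, winner$features, drop = FALSE])
  storage.mode(X_train) <- storage.mode(X_new) <- "double"
  fit_and_score(spec, winner$params, X_train, search$labels, X_new,
                derive_seed(search$config$seed, "final-model"))
}

#' @export
plot.atn_fit <- function(x, ...) {
  plot(x$evaluation, ...)
}
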