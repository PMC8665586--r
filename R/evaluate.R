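#' Evaluate the search winner on an independent test set
#'
#' Refits the top-ranked subset's chosen (family, hyperparameters) on
#' all search data and scores it on the held-out test set: empirical
#' AUC, the full ROC step curve, and confusion counts at the
#' classification threshold (0.5 for probability scores, 0 for raw
#' decision values).  Test subjects must be disjoint from the search
#' data; any id overlap raises a leakage error.
#'
#' @param search A `subset_search` from [run_search()].
#' @param test_features Data frame with the feature columns.
#' @param test_labels Binary 0/1 outcome for the test subjects.
#' @param test_ids Optional subject ids (checked against the search ids).
#' @param threshold Classification threshold; `NULL` picks the family
#'   default.
#' @return An object of class `"final_evaluation"`: `winner` (the
#'   winning `subset_result`), `test_auc`, `roc`, `confusion`,
#'   `scores`, `labels`, `ids`, `threshold`.
#' @export
evaluate_winner <- function(search, test_features, test_labels,
                            test_ids = NULL, threshold = NULL) {
  stopifnot(inherits(search, "subset_search"))
  if (!is.null(test_ids) && !is.null(search$ids) &&
      length(intersect(test_ids, search$ids)))
    stop("leakage: test subjects overlap the search data (",
         length(intersect(test_ids, search$ids)), " shared ids)")
  winner <- search$details[[1L]]
  spec <- search$algorithms[[winner$family]]
  y <- as.integer(test_labels)

  X_train <- as.matrix(search$features[, winner$features, drop = FALSE])
  X_test <- as.matrix(test_features[, winner$features, drop = FALSE])
  storage.mode(X_train) <- storage.mode(X_test) <- "double"
  scores <- fit_and_score(spec, winner$params, X_train, search$labels,
                          X_test, derive_seed(search$config$seed, "final-model"))
  if (is.null(threshold))
    threshold <- if (spec$score_type == "prob") 0.5 else 0
  structure(
    list(winner = winner,
         test_auc = empirical_auc(scores, y),
         roc = roc_points(scores, y),
         confusion = confusion_counts(scores, y, threshold),
         scores = scores, labels = y, ids = test_ids,
         threshold = threshold),
    class = "final_evaluation"
  )
}

#' @method print final_evaluation
#' @export
print.final_evaluation <- function(x, ...) {
  cat("Independent test-set evaluation\n")
  cat(sprintf("  winner: subset {%s}, %s (%s)\n",
              paste(x$winner$features, collapse = ", "), x$winner$family,
              params_string(x$winner$params)))
  cat(sprintf("  validation AUC %.3f +/- %.3f; test AUC %.3f\n",
              x$winner$auc_mean, x$winner$auc_sd, x$test_auc))
  cat(sprintf("  confusion at threshold %g: TP=%d FP=%d TN=%d FN=%d\n",
              x$threshold, x$confusion["tp"], x$confusion["fp"],
              x$confusion["tn"], x$confusion["fn"]))
  invisible(x)
}

#' @export
plot.final_evaluation <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "s",
                 xlab = "false-positive rate", ylab = "true-positive rate",
                 main = sprintf("ROC, test AUC = %.3f", x$test_auc))
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Stratify test predictions into TP / FP / TN / FN subject lists
#'
#' Partitions the test subjects of a [evaluate_winner()] result by
#' prediction outcome at the evaluation threshold; the four lists are
#' disjoint and together cover the test set.  These strata define the
#' correct/incorrect-prediction contrasts for the downstream proteomics
#' analysis.
#'
#' @param evaluation A `final_evaluation`.
#' @return Named list of id vectors `tp`, `fp`, `tn`, `fn` (indices if
#'   no ids were recorded).
#' @export
stratify_predictions <- function(evaluation) {
  stopifnot(inherits(evaluation, "final_evaluation"))
  ids <- evaluation$ids
  if (is.null(ids)) ids <- seq_along(evaluation$scores)
  pred <- as.integer(evaluation$scores > evaluation$threshold)
  y <- evaluation$labels
  list(tp = ids[pred == 1L & y == 1L],
       fp = ids[pred == 1L & y == 0L],
       tn = ids[pred == 0L & y == 0L],
       fn = ids[pred == 0L & y == 1L])
}

#' Write ROC coordinates and the evaluation summary
#'
#' @param evaluation A `final_evaluation`.
#' @param roc_path TSV destination for the ROC curve (fpr, tpr,
#'   threshold).
#' @param json_path JSON destination for the evaluation summary.
#' @export
write_evaluation <- function(evaluation, roc_path = NULL, json_path = NULL) {
  if (!is.null(roc_path))
    write.table(evaluation$roc[, c("fpr", "tpr", "threshold")], roc_path,
                sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      features = evaluation$winner$features,
      family = evaluation$winner$family,
      params = evaluation$winner$params,
      validation_auc_mean = evaluation$winner$auc_mean,
      validation_auc_sd = evaluation$winner$auc_sd,
      test_auc = evaluation$test_auc,
      confusion = as.list(evaluation$confusion),
      threshold = evaluation$threshold
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(evaluation)
}
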