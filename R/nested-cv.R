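#' Nested cross-validation configuration
#'
#' @param outer_folds Outer folds for error estimation (default 5).
#' @param inner_folds Inner folds for model/hyperparameter selection
#'   (default 2).
#' @param stratified Stratify folds by label (default TRUE).
#' @param test_fraction Fraction held out for the independent test set
#'   by [fit_atn()] (default 0.25).
#' @param seed Master seed; fold assignment, the hold-out split and all
#'   stochastic learners derive their streams from it.
#' @return An object of class `"cv_config"`.
#' @export
cv_config <- function(outer_folds = 5, inner_folds = 2, stratified = TRUE,
                      test_fraction = 0.25, seed = 1L) {
  check_number(outer_folds, "outer_folds", lower = 2)
  check_number(inner_folds, "inner_folds", lower = 2)
  check_number(test_fraction, "test_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_flag(stratified, "stratified")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 stratified = stratified,
                 test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "cv_config")
}

# fold assignment 1..k, stratified by label when requested
make_stratified_folds <- function(labels, k, seed, stratified = TRUE) {
  n <- length(labels)
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

# standardise columns with training statistics (constant columns pass
# through unscaled)
scale_train_test <- function(X_train, X_test) {
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(train = sweep(sweep(X_train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(X_test, 2, mu), 2, sdv, "/"))
}

# fit one (family, params) candidate on train and score test; returns
# numeric scores or NULL on failure (failures are the caller's to log)
fit_and_score <- function(spec, params, X_train, y_train, X_test, seed) {
  if (spec$scale) {
    sc <- scale_train_test(X_train, X_test)
    X_train <- sc$train; X_test <- sc$test
  }
  model <- spec$fit(X_train, y_train, params, seed)
  spec$predict_score(model, X_test)
}

# mean AUC of a candidate over the inner folds of a training portion
inner_cv_auc <- function(spec, params, X, y, inner_fold, seed) {
  aucs <- vapply(seq_len(max(inner_fold)), function(f) {
    tr <- inner_fold != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
      return(NA_real_)
    sc <- fit_and_score(spec, params, X[tr, , drop = FALSE], y[tr],
                        X[!tr, , drop = FALSE], seed)
    empirical_auc(sc, y[!tr])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

# all (family, grid-row) candidates in tie-breaking order
candidate_table <- function(algorithms) {
  out <- list()
  for (spec in algorithms) {
    for (g in seq_len(nrow(spec$grid))) {
      params <- as.list(spec$grid[g, , drop = FALSE])
      out[[length(out) + 1L]] <- list(spec = spec, params = params)
    }
  }
  out
}

params_string <- function(params) {
  if (length(params) == 0L) return("defaults")
  paste(sprintf("%s=%s", names(params),
                vapply(params, function(v) format(v, trim = TRUE), character(1))),
        collapse = ", ")
}

#' Nested cross-validation model selection for one feature subset
#'
#' Implements the tuning protocol of the subset-search framework.  For
#' each outer fold, every (family, grid point) candidate is scored by
#' inner `inner_folds`-fold cross-validated AUC on the outer-training
#' portion; the inner winner is refit on the whole outer-training
#' portion and scored on the outer-test portion, yielding one outer AUC
#' per fold.  The reported (family, hyperparameters) pair is the inner-CV
#' winner on the full data, used later for the final refit.  Ties are
#' broken deterministically by family order, then grid order.
#' Candidates that fail to fit are skipped with a log entry, never
#' aborting the subset.
#'
#' @param features Data frame or matrix of predictors (the subset's
#'   columns only).
#' @param labels Binary 0/1 outcome.
#' @param algorithms List of [algorithm_spec()] objects (see
#'   [default_algorithms()]).
#' @param config A [cv_config()].
#' @param subset Optional `feature_subset` for bookkeeping.
#' @return An object of class `"subset_result"`: `subset_index`,
#'   `features`, `family`, `params`, `outer_aucs`, `auc_mean`,
#'   `auc_sd`, `rank_key` (`auc_mean - auc_sd`), `failures` (log of
#'   skipped candidates).
#' @export
nested_cv_select <- function(features, labels, algorithms, config,
                             subset = NULL) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.integer(labels)
  if (length(unique(y)) < 2L)
    stop_invalid("both classes must be present")
  if (nrow(X) < 2L * config$outer_folds)
    stop_invalid("too few subjects for the configured outer folds")

  cands <- candidate_table(algorithms)
  failures <- character(0)
  fold_seed <- derive_seed(config$seed, "outer-folds")
  outer_fold <- make_stratified_folds(y, config$outer_folds, fold_seed,
                                      config$stratified)

  select_best <- function(X_part, y_part, inner_seed, fit_seed) {
    inner_fold <- make_stratified_folds(y_part, config$inner_folds,
                                        inner_seed, config$stratified)
    best <- NULL; best_auc <- -Inf
    for (ci in seq_along(cands)) {
      cand <- cands[[ci]]
      auc <- tryCatch(
        inner_cv_auc(cand$spec, cand$params, X_part, y_part, inner_fold,
                     fit_seed),
        error = function(e) {
          failures <<- c(failures, sprintf("%s (%s): %s", cand$spec$name,
                                           params_string(cand$params),
                                           conditionMessage(e)))
          NA_real_
        })
      if (is.finite(auc) && auc > best_auc) { best_auc <- auc; best <- cand }
    }
    if (is.null(best))
      stop("no candidate model could be fitted for this subset")
    best
  }

  outer_aucs <- numeric(config$outer_folds)
  for (f in seq_len(config$outer_folds)) {
    tr <- outer_fold != f
    best <- select_best(X[tr, , drop = FALSE], y[tr],
                        derive_seed(config$seed, paste0("inner", f)),
                        derive_seed(config$seed, paste0("fit", f)))
    sc <- tryCatch(
      fit_and_score(best$spec, best$params, X[tr, , drop = FALSE], y[tr],
                    X[!tr, , drop = FALSE],
                    derive_seed(config$seed, paste0("refit", f))),
      error = function(e) NULL)
    outer_aucs[f] <- if (is.null(sc)) NA_real_ else empirical_auc(sc, y[!tr])
  }

  final <- select_best(X, y, derive_seed(config$seed, "inner-final"),
                       derive_seed(config$seed, "fit-final"))
  aucs <- outer_aucs[is.finite(outer_aucs)]
  structure(
    list(subset_index = if (is.null(subset)) NA_integer_ else subset$index,
         features = colnames(X),
         family = final$spec$name,
         params = final$params,
         outer_aucs = outer_aucs,
         auc_mean = mean(aucs),
         auc_sd = if (length(aucs) > 1L) sd(aucs) else 0,
         rank_key = mean(aucs) - (if (length(aucs) > 1L) sd(aucs) else 0),
         failures = failures),
    class = "subset_result"
  )
}

#' @method print subset_result
#' @export
print.subset_result <- function(x, ...) {
  cat(sprintf("subset #%s {%s}\n",
              x$subset_index, paste(x$features, collapse = ", ")))
  cat(sprintf("  best: %s (%s)\n", x$family, params_string(x$params)))
  cat(sprintf("  outer AUC %.3f +/- %.3f (rank key %.3f)\n",
              x$auc_mean, x$auc_sd, x$rank_key))
  if (length(x$failures))
    cat("  skipped candidates:", length(x$failures), "\n")
  invisible(x)
}
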