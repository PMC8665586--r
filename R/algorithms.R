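# Classifier families for the subset-search framework.
#
# Each family is an `algorithm_spec`: a name, fixed parameters, a
# hyperparameter grid (data frame, one row per candidate), a fit/predict
# pair, whether its features should be standardised with training-fold
# statistics, and whether its score is a probability or a raw decision
# value (the AUC metric is rank-based, so either works; the score type
# only decides the default classification threshold).

#' Define a classifier family
#'
#' @param name Family name (unique within a list of specs).
#' @param grid Data frame of hyperparameter candidates (one row each);
#'   a zero-column, one-row data frame means "defaults only, no tuning".
#' @param fit `function(X, y, params, seed)` returning a fitted model;
#'   `X` a numeric matrix, `y` integer 0/1, `params` a one-row list.
#' @param predict_score `function(model, X)` returning numeric scores.
#' @param scale Standardise features (train-fold mean/SD) for this
#'   family?
#' @param score_type `"prob"` (threshold 0.5) or `"decision"`
#'   (threshold 0).
#' @param fixed Named list of fixed parameters (documentation only).
#' @return An object of class `"algorithm_spec"`.
#' @export
algorithm_spec <- function(name, grid, fit, predict_score,
                           scale = FALSE, score_type = "prob",
                           fixed = list()) {
  stopifnot(is.function(fit), is.function(predict_score),
            is.data.frame(grid), nrow(grid) >= 1L)
  structure(list(name = name, grid = grid, fit = fit,
                 predict_score = predict_score, scale = scale,
                 score_type = score_type, fixed = fixed),
            class = "algorithm_spec")
}

# ---- individual families ----------------------------------------------

spec_logistic <- function(Cs = c(1e-4, 1e-3, 1e-2, 0.1, 1, 10, 100, 1000)) {
  algorithm_spec(
    name = "logistic_regression",
    fixed = list(penalty = "l2", maxit = 250),
    grid = data.frame(C = Cs),
    scale = TRUE,
    fit = function(X, y, params, seed) {
      # ridge-penalised logistic; lambda = 1/(n*C) matches the
      # "1/C * ||w||^2/2 + sum(loss)" parameterisation
      pad <- ncol(X) < 2L
      if (pad) X <- cbind(X, .pad = 0)
      fit <- glmnet::glmnet(X, factor(y, 0:1), family = "binomial",
                            alpha = 0, lambda = 1 / (nrow(X) * params$C),
                            standardize = FALSE, maxit = 250000)
      list(fit = fit, pad = pad)
    },
    predict_score = function(model, X) {
      if (model$pad) X <- cbind(X, .pad = 0)
      as.numeric(predict(model$fit, X, type = "response"))
    }
  )
}

spec_naive_bayes <- function() {
  algorithm_spec(
    name = "naive_bayes",
    grid = data.frame(row.names = 1),  # defaults only
    fit = function(X, y, params, seed)
      e1071::naiveBayes(as.data.frame(X), factor(y, 0:1)),
    predict_score = function(model, X)
      as.numeric(predict(model, as.data.frame(X), type = "raw")[, "1"])
  )
}

# Minkowski k-nearest neighbours with probability votes (fraction of
# positive labels among the k nearest training points).
knn_scores <- function(train_X, train_y, X, k, p) {
  apply(X, 1L, function(row) {
    d <- if (p == 1) colSums(abs(t(train_X) - row))
         else sqrt(colSums((t(train_X) - row)^2))
    mean(train_y[order(d)[seq_len(k)]])
  })
}

spec_knn <- function(ks = 1:9, ps = c(1, 2)) {
  algorithm_spec(
    name = "knn",
    fixed = list(metric = "minkowski"),
    grid = expand.grid(n_neighbors = ks, p = ps),
    scale = TRUE,
    fit = function(X, y, params, seed)
      list(X = X, y = y, k = min(params$n_neighbors, nrow(X)), p = params$p),
    predict_score = function(model, X)
      knn_scores(model$X, model$y, X, model$k, model$p)
  )
}

spec_svc <- function() {
  nonlin <- expand.grid(kernel = c("radial", "polynomial", "sigmoid"),
                        C = 10^(-4:3),
                        gamma = c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1),
                        stringsAsFactors = FALSE)
  lin <- data.frame(kernel = "linear", C = c(1e-4, 1e-3, 1e-2, 0.1, 1, 10, 100, 1000),
                    gamma = NA_real_, stringsAsFactors = FALSE)
  algorithm_spec(
    name = "svc",
    grid = rbind(nonlin, lin),
    scale = TRUE,
    score_type = "decision",
    fit = function(X, y, params, seed) {
      args <- list(x = X, y = factor(y, 0:1), kernel = params$kernel,
                   cost = params$C, scale = FALSE)
      if (!is.na(params$gamma)) args$gamma <- params$gamma
      do.call(e1071::svm, args)
    },
    predict_score = function(model, X) {
      dv <- attr(predict(model, X, decision.values = TRUE), "decision.values")
      # orient so larger = more positive-class
      if (colnames(dv)[1] == "0/1") -as.numeric(dv) else as.numeric(dv)
    }
  )
}

spec_decision_tree <- function(depths = 1:9,
                               criteria = c("gini", "information")) {
  algorithm_spec(
    name = "decision_tree",
    grid = expand.grid(max_depth = depths, criterion = criteria,
                       stringsAsFactors = FALSE),
    fit = function(X, y, params, seed) {
      df <- data.frame(X, .y = factor(y, 0:1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = params$criterion),
                   control = rpart::rpart.control(
                     maxdepth = params$max_depth, cp = 0,
                     minsplit = 10, xval = 0))
    },
    predict_score = function(model, X)
      as.numeric(predict(model, data.frame(X), type = "prob")[, "1"])
  )
}

spec_random_forest <- function(depths = c(3, 4, 5, 8, 10),
                               trees = c(5, 20, 50, 100, 200, 500, 1000)) {
  algorithm_spec(
    name = "random_forest",
    grid = expand.grid(max_depth = depths, n_estimators = trees),
    fit = function(X, y, params, seed) {
      df <- data.frame(X, .y = factor(y, 0:1))
      ranger::ranger(.y ~ ., data = df, probability = TRUE,
                     num.trees = params$n_estimators,
                     max.depth = params$max_depth,
                     seed = seed, num.threads = 1L)
    },
    predict_score = function(model, X)
      predict(model, data.frame(X), num.threads = 1L)$predictions[, "1"]
  )
}

xgb_fit <- function(X, y, nrounds, max_depth, eta, seed) {
  set.seed(seed)
  xgboost::xgboost(x = X, y = factor(y, 0:1), nrounds = nrounds,
                   max_depth = max_depth, learning_rate = eta,
                   nthread = 1L, verbosity = 0)
}

spec_gradient_boosting <- function(depths = c(3, 4, 5, 8, 10),
                                   rates = c(0.01, 0.05, 0.1, 0.2),
                                   trees = c(5, 20, 50, 100, 200, 500, 1000)) {
  algorithm_spec(
    name = "gradient_boosting",
    grid = expand.grid(max_depth = depths, learning_rate = rates,
                       n_estimators = trees),
    fit = function(X, y, params, seed)
      xgb_fit(X, y, params$n_estimators, params$max_depth,
              params$learning_rate, seed),
    predict_score = function(model, X) as.numeric(predict(model, X))
  )
}

spec_xgboost <- function(depths = 6:8,
                         rates = c(0.01, 0.025, 0.05, 0.075, 0.1),
                         trees = c(5, 20, 50, 100, 200, 500, 1000)) {
  algorithm_spec(
    name = "xgboost",
    grid = expand.grid(max_depth = depths, learning_rate = rates,
                       n_estimators = trees),
    fit = function(X, y, params, seed)
      xgb_fit(X, y, params$n_estimators, params$max_depth,
              params$learning_rate, seed),
    predict_score = function(model, X) as.numeric(predict(model, X))
  )
}

# AdaBoost (SAMME) over depth-1 decision stumps.
adaboost_fit <- function(X, y, n_estimators, learning_rate) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  yy <- factor(y, 0:1)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    df <- data.frame(X, .y = yy)
    stump <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = 1, cp = 0, minsplit = 2, xval = 0))
    pred <- as.integer(as.character(predict(stump, df, type = "class")))
    err <- sum(w * (pred != y))
    if (err <= 1e-10) {  # perfect stump: take it with a large vote and stop
      stumps[[length(stumps) + 1L]] <- stump
      alphas <- c(alphas, learning_rate * log(1e10))
      break
    }
    if (err >= 0.5) break
    alpha <- learning_rate * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  if (length(stumps) == 0L) {  # no usable stump: constant score
    stumps <- list(NULL); alphas <- 0
  }
  list(stumps = stumps, alphas = alphas)
}

adaboost_score <- function(model, X) {
  df <- data.frame(X)
  total <- sum(abs(model$alphas))
  if (total == 0) return(rep(0, nrow(df)))
  margin <- rep(0, nrow(df))
  for (i in seq_along(model$stumps)) {
    if (is.null(model$stumps[[i]])) next
    pred <- as.integer(as.character(predict(model$stumps[[i]], df, type = "class")))
    margin <- margin + model$alphas[i] * (2 * pred - 1)
  }
  margin / total
}

spec_adaboost <- function(rates = c(0.25, 0.5, 1.0, 1.25, 1.5),
                          trees = c(20, 50, 100, 150, 200)) {
  algorithm_spec(
    name = "adaboost",
    fixed = list(base = "depth-1 stump"),
    grid = expand.grid(learning_rate = rates, n_estimators = trees),
    score_type = "decision",
    fit = function(X, y, params, seed) {
      set.seed(seed)
      adaboost_fit(X, y, params$n_estimators, params$learning_rate)
    },
    predict_score = adaboost_score
  )
}

#' The nine classifier families with their default hyperparameter grids
#'
#' Returns the full roster — logistic regression (ridge), naive Bayes,
#' k-nearest neighbours, support-vector classifier, decision tree,
#' random forest, gradient boosting, XGBoost and AdaBoost — with either
#' the full published grids (`"full"`) or a one-candidate-per-family
#' reduced grid (`"reduced"`) for fast runs.  Support-vector C values
#' for the non-linear kernels are powers of ten (10^-4 .. 10^3); naive
#' Bayes has no grid and runs with defaults.
#'
#' @param grids `"full"` or `"reduced"`.
#' @return Named list of [algorithm_spec()] objects, in the fixed
#'   tie-breaking order used by model selection.
#' @export
default_algorithms <- function(grids = c("full", "reduced")) {
  grids <- match.arg(grids)
  if (grids == "full") {
    specs <- list(
      spec_logistic(), spec_naive_bayes(), spec_knn(), spec_svc(),
      spec_decision_tree(), spec_random_forest(),
      spec_gradient_boosting(), spec_xgboost(), spec_adaboost()
    )
  } else {
    svc <- spec_svc()
    svc$grid <- data.frame(kernel = "radial", C = 1, gamma = 0.1,
                           stringsAsFactors = FALSE)
    specs <- list(
      spec_logistic(Cs = 1),
      spec_naive_bayes(),
      spec_knn(ks = 5, ps = 2),
      svc,
      spec_decision_tree(depths = 3, criteria = "gini"),
      spec_random_forest(depths = 5, trees = 30),
      spec_gradient_boosting(depths = 3, rates = 0.1, trees = 20),
      spec_xgboost(depths = 6, rates = 0.1, trees = 20),
      spec_adaboost(rates = 1.0, trees = 10)
    )
  }
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}
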