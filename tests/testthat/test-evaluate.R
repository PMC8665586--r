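make_fitted_search <- function(n = 120, seed = 5) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.4)
  X <- data.frame(f = y + rnorm(n, sd = 0.05), g = rnorm(n))
  ids <- sprintf("id%03d", seq_len(n))
  search <- run_search(X, y, enumerate_subsets(c("f", "g")),
                       fast_algorithms(), cv_config(seed = seed),
                       ids = ids)
  list(search = search, X = X, y = y, ids = ids)
}

test_that("a separable pattern evaluates to AUC 1 with a clean confusion", {
  fx <- make_fitted_search()
  set.seed(99)
  y_new <- rbinom(40, 1, 0.5)
  X_new <- data.frame(f = y_new + rnorm(40, sd = 0.05), g = rnorm(40))
  ev <- evaluate_winner(fx$search, X_new, y_new,
                        test_ids = sprintf("new%03d", 1:40))
  expect_equal(ev$test_auc, 1)
  expect_equal(sum(ev$confusion), 40)
  expect_equal(unname(ev$confusion["fp"] + ev$confusion["fn"]), 0)
  expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)
})

test_that("train/test id overlap is a hard leakage failure", {
  fx <- make_fitted_search()
  expect_error(
    evaluate_winner(fx$search, fx$X[1:10, ], fx$y[1:10],
                    test_ids = fx$ids[1:10]),
    "leakage")
})

test_that("prediction strata partition the test set and are reproducible", {
  fx <- make_fitted_search(seed = 8)
  set.seed(123)
  y_new <- rbinom(60, 1, 0.4)
  X_new <- data.frame(f = y_new + rnorm(60, sd = 0.4), g = rnorm(60))
  ids <- sprintf("t%03d", 1:60)
  ev <- evaluate_winner(fx$search, X_new, y_new, test_ids = ids)
  st <- stratify_predictions(ev)
  expect_setequal(unlist(st), ids)
  expect_equal(length(st$tp) + length(st$fp) + length(st$tn) + length(st$fn),
               60)
  expect_equal(length(st$tp), unname(ev$confusion["tp"]))
  ev2 <- evaluate_winner(fx$search, X_new, y_new, test_ids = ids)
  expect_identical(stratify_predictions(ev2), st)
})

test_that("all-positive scores put every negative in the FP stratum", {
  ev <- structure(
    list(scores = rep(1, 10), labels = rep(c(1L, 0L), each = 5),
         ids = letters[1:10], threshold = 0.5),
    class = "final_evaluation")
  st <- stratify_predictions(ev)
  expect_length(st$fp, 5)
  expect_length(st$tn, 0)
  expect_length(st$fn, 0)
})

test_that("evaluation artifacts are written faithfully", {
  fx <- make_fitted_search(seed = 2)
  set.seed(5)
  y_new <- rbinom(30, 1, 0.5)
  X_new <- data.frame(f = y_new + rnorm(30, sd = 0.3), g = rnorm(30))
  ev <- evaluate_winner(fx$search, X_new, y_new)
  roc_path <- withr::local_tempfile(fileext = ".tsv")
  json_path <- withr::local_tempfile(fileext = ".json")
  write_evaluation(ev, roc_path, json_path)
  roc <- read.delim(roc_path)
  expect_equal(roc$fpr, ev$roc$fpr, tolerance = 1e-9)
  js <- jsonlite::read_json(json_path)
  expect_equal(js$test_auc, ev$test_auc, tolerance = 1e-12)
  expect_equal(js$confusion$tp, unname(ev$confusion["tp"]))
})
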