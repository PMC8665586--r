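#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided Mann-Whitney test for `x` versus `y` with midrank ties.
#' The p-value is exact (full enumeration of rank splits) when
#' `length(x) + length(y) <= exact_limit` and the data are tie-free,
#' otherwise it uses the normal approximation with tie and continuity
#' corrections.  The returned `auc`, `U / (n1 * n0)`, is the rank-based
#' AUC of `x` scored against `y` and coincides with [empirical_auc()].
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_limit Combined sample size up to which the exact
#'   distribution is used (default 12).
#' @return A list with `U` (number of (x, y) pairs with x > y, ties
#'   counted one half), `p` (two-sided), `auc`, `n_x`, `n_y`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y, exact_limit = 12) {
  if (length(x) == 0L || length(y) == 0L)
    stop_invalid("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_invalid("samples must not contain NA")
  n1 <- length(x); n0 <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (n1 + n0) <= exact_limit && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE,
                alternative = "two.sided")
  )
  list(U = unname(U), p = wt$p.value, auc = unname(U) / (n1 * n0),
       n_x = n1, n_y = n0)
}

#' Binormal AUC from group summary statistics
#'
#' Closed-form AUC under Gaussian class-conditional score distributions:
#' `pnorm((mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2))`.  The
#' value is signed — below 0.5 when the positive group scores lower —
#' which lets published sub-0.5 single-feature AUCs be reproduced
#' without direction flipping.
#'
#' @param mean_pos,sd_pos Positive-group mean and SD.
#' @param mean_neg,sd_neg Negative-group mean and SD.
#' @return AUC in (0, 1).
#' @examples
#' binormal_auc(2411, 566.95, 1764, 496.1)  # ~0.805 (Abeta1-38, T+)
#' @export
binormal_auc <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  check_number(sd_pos, "sd_pos", lower = 0, strict_lower = TRUE)
  check_number(sd_neg, "sd_neg", lower = 0, strict_lower = TRUE)
  pnorm((mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

#' Cross-validated AUC of a one-feature logistic model
#'
#' Stratified k-fold cross-validation of a univariate logistic
#' regression; out-of-fold predicted probabilities are pooled and scored
#' with [empirical_auc()].  For a monotone single-feature model this
#' equals the feature's empirical AUC up to fold noise.  Folds that
#' happen to lose a class are avoided by refolding with a shifted seed
#' (with a message).
#'
#' @param feature Numeric predictor.
#' @param labels Binary 0/1 outcome.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @return A list with `auc` and `scores` (pooled out-of-fold
#'   probabilities, in input order).
#' @export
single_feature_cv_auc <- function(feature, labels, folds = 5, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop_invalid("both classes must be present")
  n <- length(feature)
  for (attempt in 0:20) {
    fold <- make_stratified_folds(labels, folds, derive_seed(seed, paste0("sfcv", attempt)))
    ok <- all(vapply(seq_len(folds), function(f)
      length(unique(labels[fold != f])) == 2L, logical(1)))
    if (ok) break
    message("single_feature_cv_auc: refolding (a fold lost a class)")
  }
  scores <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- glm(y ~ x, family = binomial(),
               data = data.frame(x = feature[tr], y = labels[tr]))
    scores[!tr] <- predict(fit, newdata = data.frame(x = feature[!tr]),
                           type = "response")
  }
  list(auc = empirical_auc(scores, labels), scores = scores)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p by summing hypergeometric probabilities no larger
#' than the observed table's.  A table with a zero margin carries no
#' information about association; by convention p = 1 (with a message).
#'
#' @param counts 2x2 matrix of non-negative integers.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L) || any(counts < 0) || any(counts != round(counts)))
    stop_invalid("counts must be a 2x2 matrix of non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    message("fisher_exact: zero margin, p = 1 by convention")
    return(1)
  }
  fisher.test(counts)$p.value
}

#' Group comparison report for the six biomarker features
#'
#' For each isoform and ratio, compares biomarker-negative versus
#' -positive subjects: group means and SDs, Mann-Whitney U and
#' two-sided p, the empirical AUC of the feature for the positive
#' label, and which group is higher.
#'
#' @param cohort A `cohort_table`.
#' @param outcome `"T"` or `"N"`.
#' @return Data frame, one row per feature.
#' @export
compare_groups <- function(cohort, outcome = c("T", "N")) {
  outcome <- match.arg(outcome)
  fs <- build_features(cohort)
  lab <- if (outcome == "T") fs$label_T else fs$label_N
  feats <- c("ab38", "ab40", "ab42", "r4240", "r4238", "r4038")
  rows <- lapply(feats, function(f) {
    v <- fs$features[[f]]
    pos <- v[lab == 1L]; neg <- v[lab == 0L]
    mw <- mann_whitney(pos, neg)
    data.frame(feature = f,
               mean_neg = mean(neg), sd_neg = sd(neg),
               mean_pos = mean(pos), sd_pos = sd(pos),
               U = mw$U, p = mw$p,
               auc = empirical_auc(v, lab),
               higher_in = if (mean(pos) > mean(neg)) "positive" else "negative",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sample-characteristics table by biomarker status
#'
#' Descriptive comparison of demographics between the negative and
#' positive groups: Welch t-tests for the numeric characteristics (age,
#' education) and Fisher's exact test for sex and APOE e4 status.
#'
#' @inheritParams compare_groups
#' @return Data frame, one row per characteristic.
#' @export
describe_cohort <- function(cohort, outcome = c("T", "N")) {
  outcome <- match.arg(outcome)
  lab <- cohort[[paste0("label_", outcome)]]
  num_row <- function(name, v) {
    pos <- v[lab == 1L]; neg <- v[lab == 0L]
    data.frame(characteristic = name,
               neg = sprintf("%.2f +/- %.2f", mean(neg), sd(neg)),
               pos = sprintf("%.2f +/- %.2f", mean(pos), sd(pos)),
               test = "Welch t",
               p = t.test(pos, neg)$p.value,
               stringsAsFactors = FALSE)
  }
  bin_row <- function(name, v) {
    tab <- table(factor(v, 0:1), factor(lab, 0:1))
    data.frame(characteristic = name,
               neg = sprintf("%.1f%%", 100 * mean(v[lab == 0L])),
               pos = sprintf("%.1f%%", 100 * mean(v[lab == 1L])),
               test = "Fisher exact",
               p = fisher_exact(tab),
               stringsAsFactors = FALSE)
  }
  rbind(
    data.frame(characteristic = "n",
               neg = as.character(sum(lab == 0L)),
               pos = as.character(sum(lab == 1L)),
               test = "", p = NA_real_, stringsAsFactors = FALSE),
    num_row("age (y)", cohort$age),
    num_row("education (y)", cohort$education),
    bin_row("sex (% female)", cohort$sex),
    bin_row("APOE e4 carriers (%)", cohort$apoe4)
  )
}
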