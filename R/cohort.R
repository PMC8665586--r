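#' Configuration for the synthetic cohort generator
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param prevalence_positive Proportion of biomarker-positive subjects,
#'   strictly between 0 and 1.  Defaults follow the published group
#'   sizes: 0.31 for the tau outcome, 43/110 for neurodegeneration.
#' @param outcome `"T"` (tau pathology, label from p-tau181) or `"N"`
#'   (neurodegeneration, label from t-tau).
#' @param group_params_neg,group_params_pos [group_params()] objects for
#'   the biomarker-negative and -positive groups; default to the
#'   published values for the chosen outcome.
#' @param ptau_threshold p-tau181 positivity cut-off, pg/mL (default 19.2).
#' @param ttau_threshold t-tau positivity cut-off, pg/mL (default 242).
#' @param seed Integer seed; every draw of [generate_cohort()] is a pure
#'   function of the configuration including this seed.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects = 318,
                             outcome = c("T", "N"),
                             prevalence_positive = NULL,
                             group_params_neg = NULL,
                             group_params_pos = NULL,
                             ptau_threshold = 19.2,
                             ttau_threshold = 242,
                             seed = 1L) {
  outcome <- match.arg(outcome)
  if (is.null(prevalence_positive))
    prevalence_positive <- if (outcome == "T") 0.31 else 43 / 110
  if (is.null(group_params_neg))
    group_params_neg <- default_group_params(paste0(outcome, "-"))
  if (is.null(group_params_pos))
    group_params_pos <- default_group_params(paste0(outcome, "+"))
  check_number(n_subjects, "n_subjects", lower = 2)
  check_number(prevalence_positive, "prevalence_positive",
               lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(ptau_threshold, "ptau_threshold", lower = 0, strict_lower = TRUE)
  check_number(ttau_threshold, "ttau_threshold", lower = 0, strict_lower = TRUE)
  if (!inherits(group_params_neg, "group_params") ||
      !inherits(group_params_pos, "group_params"))
    stop_invalid("group_params_neg/pos must be group_params objects")
  structure(
    list(n_subjects = as.integer(n_subjects),
         prevalence_positive = prevalence_positive,
         outcome = outcome,
         group_params_neg = group_params_neg,
         group_params_pos = group_params_pos,
         ptau_threshold = ptau_threshold,
         ttau_threshold = ttau_threshold,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# lognormal draw truncated to one side of a threshold; side = "above"/"below".
# meanlog is offset from log(threshold) so the untruncated mass already
# favours the requested side; truncation then makes it exact.
rlnorm_side <- function(n, threshold, side, sdlog = 0.35, offset = 0.25) {
  meanlog <- log(threshold) + if (side == "above") offset else -offset
  pthr <- plnorm(threshold, meanlog, sdlog)
  u <- if (side == "above") runif(n, pthr, 1) else runif(n, 0, pthr)
  qlnorm(u, meanlog, sdlog)
}

#' Generate a synthetic cognitively-unimpaired cohort
#'
#' Draws a cohort whose group-conditional isoform, ratio and demographic
#' distributions match the configured [group_params()] (via
#' [calibrate_lognormal()]), and whose tau labels are consistent with
#' the positivity thresholds by construction: the configured outcome's
#' tau marker is drawn from a lognormal truncated to the correct side of
#' its threshold, the other marker from an untruncated group-shifted
#' lognormal.  Both `label_T` and `label_N` are always recomputed from
#' the marker values (strict `>`), so `label_T == (ptau > 19.2)` and
#' `label_N == (ttau > 242)` hold exactly for every subject.
#'
#' @param config A [generator_config()].
#' @return A `data.frame` of class `"cohort_table"`: columns `id`, `age`
#'   (years), `sex` (1 = female), `education` (years), `apoe4`
#'   (1 = carrier), `ab38`, `ab40`, `ab42`, `ptau`, `ttau` (pg/mL),
#'   `label_T`, `label_N` (0/1).
#' @examples
#' coh <- generate_cohort(generator_config(n_subjects = 100, seed = 42))
#' table(coh$label_T)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    stop_invalid("config must be a generator_config object")
  set.seed(config$seed)
  n <- config$n_subjects
  pos <- rbinom(n, 1L, config$prevalence_positive)

  model_neg <- calibrate_lognormal(config$group_params_neg)
  model_pos <- calibrate_lognormal(config$group_params_pos)

  X <- matrix(NA_real_, n, 3,
              dimnames = list(NULL, c("ab38", "ab40", "ab42")))
  i_pos <- which(pos == 1L); i_neg <- which(pos == 0L)
  X[i_neg, ] <- sample_isoforms(model_neg, length(i_neg))
  X[i_pos, ] <- sample_isoforms(model_pos, length(i_pos))

  gp <- function(field) {
    ifelse(pos == 1L,
           config$group_params_pos[[field]],
           config$group_params_neg[[field]])
  }
  age <- rnorm(n, gp("mean_age"), gp("sd_age"))
  education <- pmax(rnorm(n, gp("mean_edu"), gp("sd_edu")), 0)
  sex <- rbinom(n, 1L, gp("frac_female"))
  apoe4 <- rbinom(n, 1L, gp("frac_apoe4"))

  target_thr <- if (config$outcome == "T") config$ptau_threshold else config$ttau_threshold
  other_thr <- if (config$outcome == "T") config$ttau_threshold else config$ptau_threshold
  target <- numeric(n)
  target[i_pos] <- rlnorm_side(length(i_pos), target_thr, "above")
  target[i_neg] <- rlnorm_side(length(i_neg), target_thr, "below")
  # the non-target marker tracks the group without truncation
  other <- rlnorm(n, log(other_thr) + ifelse(pos == 1L, 0.2, -0.2), 0.35)

  if (config$outcome == "T") { ptau <- target; ttau <- other }
  else { ttau <- target; ptau <- other }

  out <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    age = age, sex = sex, education = education, apoe4 = apoe4,
    ab38 = X[, "ab38"], ab40 = X[, "ab40"], ab42 = X[, "ab42"],
    ptau = ptau, ttau = ttau,
    label_T = as.integer(ptau > config$ptau_threshold),
    label_N = as.integer(ttau > config$ttau_threshold),
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Read/write the cohort CSV dialect
#'
#' The cohort is stored as plain CSV with the fixed header
#' `id,age,sex,education,apoe4,ab38,ab40,ab42,ptau,ttau,label_T,label_N`.
#'
#' @param cohort A `cohort_table` data frame.
#' @param path File path.
#' @return `read_cohort` returns a `cohort_table`; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "age", "sex", "education", "apoe4",
              "ab38", "ab40", "ab42", "ptau", "ttau", "label_T", "label_N")
  missing <- setdiff(needed, names(x))
  if (length(missing))
    stop_invalid("cohort file lacks columns: ", paste(missing, collapse = ", "))
  class(x) <- c("cohort_table", "data.frame")
  x
}
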