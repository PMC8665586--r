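#' Exhaustive feature-subset model search
#'
#' Runs [nested_cv_select()] for every feature subset and ranks the
#' per-subset winners by `auc_mean - auc_sd` (descending).  Fold
#' assignments derive from the configuration seed alone, so each
#' subset's result is independent of which other subsets are searched,
#' and a rerun with the same seed reproduces the report exactly.
#'
#' @param features Data frame with (at least) all columns named by the
#'   subsets.
#' @param labels Binary 0/1 outcome vector.
#' @param subsets List from [enumerate_subsets()].
#' @param algorithms List of [algorithm_spec()]s.
#' @param config A [cv_config()].
#' @param ids Optional subject ids (used later to guard against
#'   train/test leakage).
#' @param resume A previous `subset_search` over the same data; already
#'   computed subset indices are reused rather than re-run.
#' @param progress_every Log a progress message every this many subsets
#'   (0 = silent).
#' @return An object of class `"subset_search"` with elements `results`
#'   (ranked data frame: subset_index, features, family, params,
#'   auc_mean, auc_sd, rank_key), `details` (list of `subset_result`),
#'   plus the training data, ids, algorithms and config needed for the
#'   final refit.
#' @export
run_search <- function(features, labels, subsets, algorithms, config,
                       ids = NULL, resume = NULL, progress_every = 0) {
  labels <- as.integer(labels)
  have <- list()
  if (!is.null(resume)) {
    stopifnot(inherits(resume, "subset_search"))
    have <- resume$details
    names(have) <- vapply(resume$details, function(d)
      as.character(d$subset_index), character(1))
  }
  details <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    key <- as.character(s$index)
    details[[i]] <- if (!is.null(have[[key]])) have[[key]] else
      nested_cv_select(features[, s$features, drop = FALSE], labels,
                       algorithms, config, subset = s)
    if (progress_every > 0 && i %% progress_every == 0)
      message(sprintf("searched %d / %d subsets", i, length(subsets)))
  }
  res <- data.frame(
    subset_index = vapply(details, `[[`, integer(1), "subset_index"),
    features = vapply(details, function(d) paste(d$features, collapse = "+"),
                      character(1)),
    family = vapply(details, `[[`, character(1), "family"),
    params = vapply(details, function(d) params_string(d$params), character(1)),
    auc_mean = vapply(details, `[[`, numeric(1), "auc_mean"),
    auc_sd = vapply(details, `[[`, numeric(1), "auc_sd"),
    rank_key = vapply(details, `[[`, numeric(1), "rank_key"),
    stringsAsFactors = FALSE
  )
  o <- order(res$rank_key, decreasing = TRUE)
  structure(
    list(results = res[o, ], details = details[o],
         features = features, labels = labels,
         ids = ids, algorithms = algorithms, config = config),
    class = "subset_search"
  )
}

#' @method print subset_search
#' @export
print.subset_search <- function(x, n = 5, ...) {
  cat(sprintf("Feature-subset search: %d subsets, ranked by AUC - SD\n",
              nrow(x$results)))
  top <- utils::head(x$results, n)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %d. {%s} %s: %.3f +/- %.3f\n", i, top$features[i],
                top$family[i], top$auc_mean[i], top$auc_sd[i]))
  invisible(x)
}

#' @method summary subset_search
#' @export
summary.subset_search <- function(object, ...) {
  res <- object$results
  cat(sprintf("%d subsets searched; AUC range %.3f - %.3f\n",
              nrow(res), min(res$auc_mean), max(res$auc_mean)))
  cat("winning family counts:\n")
  print(sort(table(res$family), decreasing = TRUE))
  invisible(res)
}

#' @export
plot.subset_search <- function(x, n = 10, ...) {
  top <- utils::head(x$results, n)
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(top$auc_mean),
                    names.arg = rev(paste0(top$features, " (", top$family, ")")),
                    horiz = TRUE, las = 1, xlim = c(0, 1),
                    xlab = "outer-fold mean AUC",
                    main = sprintf("Top %d feature subsets", nrow(top)))
  invisible(x)
}

#' Write a subset-search report as TSV
#'
#' One row per subset (features, chosen family and hyperparameters,
#' outer-fold AUC mean and SD, rank key), in ranked order.
#'
#' @param search A `subset_search`.
#' @param path Output file.
#' @export
write_search_report <- function(search, path) {
  write.table(search$results, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
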