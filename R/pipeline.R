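#' Default end-to-end run configuration
#'
#' Builds the configuration for [run_all()], optionally overriding the
#' defaults from a YAML file and/or a named list.  With no arguments
#' the configuration reproduces the calibrated synthetic study at
#' reduced hyperparameter grids; `full_grids = TRUE` switches to the
#' full published grids.
#'
#' @param yaml_path Optional YAML file of overrides.
#' @param overrides Optional named list of overrides (applied after the
#'   YAML).
#' @return A list of class `"run_config"` with elements `out_dir`,
#'   `seed`, `n_subjects`, `outcomes`, `feature_names`, `full_grids`,
#'   `test_fraction`, `outer_folds`, `inner_folds`, `n_peptides`,
#'   `n_differential`, `effect_size`, `missing_rate`, `n_low_detect`,
#'   `fdr_threshold`, `min_detect_fraction`, `min_jaccard`.
#' @export
run_config <- function(yaml_path = NULL, overrides = list()) {
  cfg <- list(
    out_dir = "abatn-run",
    seed = 1L,
    n_subjects = 318L,
    outcomes = c("T", "N"),
    feature_names = canonical_features(),
    full_grids = FALSE,
    test_fraction = 0.25,
    outer_folds = 5L,
    inner_folds = 2L,
    n_peptides = 567L,
    n_differential = 30L,
    effect_size = 1.5,
    missing_rate = 0.05,
    n_low_detect = 247L,
    fdr_threshold = 0.05,
    min_detect_fraction = 0.10,
    min_jaccard = 0.1
  )
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    cfg <- modifyList(cfg, y[intersect(names(y), names(cfg))])
  }
  cfg <- modifyList(cfg, overrides[intersect(names(overrides), names(cfg))])
  cfg$outcomes <- match.arg(cfg$outcomes, c("T", "N"), several.ok = TRUE)
  check_number(cfg$fdr_threshold, "fdr_threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(cfg$min_detect_fraction, "min_detect_fraction",
               lower = 0, upper = 1, strict_upper = TRUE)
  structure(cfg, class = c("run_config", "list"))
}

#' Run the whole study end to end
#'
#' Orchestrates simulate -> describe -> search -> evaluate -> stratify
#' -> differential expression -> enrichment with one master seed, and
#' writes every stage's artifact under `config$out_dir`: the cohort
#' CSV, per-outcome description and comparison TSVs, ranked search
#' reports, ROC TSVs and evaluation JSONs, the peptide matrix and GMT,
#' DE and enrichment TSVs for the group and (data permitting) the
#' TP/FP and TN/FN contrasts, and a `summary.json` tying the numbers
#' together.  A stage failure stops with the stage name; artifacts of
#' completed stages persist.  Identical configuration and seed give an
#' identical summary.
#'
#' @param config A [run_config()].
#' @param progress_every Passed to [run_search()].
#' @return The summary list, invisibly; also written as
#'   `summary.json`.
#' @export
run_all <- function(config = run_config(), progress_every = 0) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(config$out_dir, ...)
  stage <- "simulate"
  summary <- list(seed = config$seed, n_subjects = config$n_subjects)
  tryCatch({
    cohort <- generate_cohort(generator_config(
      n_subjects = config$n_subjects, outcome = config$outcomes[1],
      seed = derive_seed(config$seed, "cohort")))
    write_cohort(cohort, pth("cohort.csv"))

    algorithms <- default_algorithms(if (config$full_grids) "full" else "reduced")
    for (outcome in config$outcomes) {
      stage <- paste0("describe-", outcome)
      write.table(describe_cohort(cohort, outcome),
                  pth(sprintf("describe_%s.tsv", outcome)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(compare_groups(cohort, outcome),
                  pth(sprintf("compare_%s.tsv", outcome)),
                  sep = "\t", row.names = FALSE, quote = FALSE)

      stage <- paste0("search-", outcome)
      fit <- fit_atn(cohort, outcome,
                     feature_names = config$feature_names,
                     algorithms = algorithms,
                     config = cv_config(outer_folds = config$outer_folds,
                                        inner_folds = config$inner_folds,
                                        test_fraction = config$test_fraction,
                                        seed = derive_seed(config$seed,
                                                           paste0("cv", outcome))),
                     progress_every = progress_every)
      write_search_report(fit$search, pth(sprintf("search_%s.tsv", outcome)))
      stage <- paste0("evaluate-", outcome)
      write_evaluation(fit$evaluation,
                       roc_path = pth(sprintf("roc_%s.tsv", outcome)),
                       json_path = pth(sprintf("evaluation_%s.json", outcome)))
      strata <- fit$strata
      summary[[paste0("outcome_", outcome)]] <- list(
        n_subsets = nrow(fit$search$results),
        winner_features = fit$evaluation$winner$features,
        winner_family = fit$evaluation$winner$family,
        validation_auc_mean = fit$evaluation$winner$auc_mean,
        validation_auc_sd = fit$evaluation$winner$auc_sd,
        test_auc = fit$evaluation$test_auc,
        confusion = as.list(fit$evaluation$confusion),
        n_test = length(fit$test_idx)
      )
      if (outcome == config$outcomes[1]) first_fit <- fit
    }
    summary$n_models_total <- sum(vapply(config$outcomes, function(o)
      summary[[paste0("outcome_", o)]]$n_subsets, numeric(1)))

    stage <- "proteomics"
    sim <- generate_proteomics(cohort,
                               n_peptides = config$n_peptides,
                               n_differential = config$n_differential,
                               effect_size = config$effect_size,
                               missing_rate = config$missing_rate,
                               n_low_detect = config$n_low_detect,
                               outcome = config$outcomes[1],
                               seed = derive_seed(config$seed, "proteomics"))
    write_proteomics(sim$matrix, pth("proteomics.tsv"))
    write_gmt(sim$gmt, pth("annotation.gmt"))
    filtered <- detectability_filter(sim$matrix, config$min_detect_fraction)
    summary$n_peptides_detectable <- attr(filtered, "n_kept")

    run_contrast <- function(tag, groups) {
      lv <- levels(droplevels(as.factor(groups[!is.na(groups)])))
      if (length(lv) != 2L) return(NULL)
      tab <- table(groups)
      if (any(tab < 3L)) return(NULL)  # too small to compare
      keep <- !is.na(groups)
      de <- moderated_t(filtered[, keep, drop = FALSE], groups[keep],
                        config$fdr_threshold)
      write_de_result(de, pth(sprintf("de_%s.tsv", tag)))
      universe <- rownames(filtered)
      deps <- de$peptide_id[de$dep]
      enr <- if (length(deps)) ora(deps, sim$gmt, universe) else NULL
      if (!is.null(enr) && nrow(enr)) {
        write_enrichment(enr, pth(sprintf("enrich_%s.tsv", tag)))
        net <- term_network(enr, config$min_jaccard)
        write_term_network(net, pth(sprintf("network_%s.tsv", tag)))
      }
      list(n_dep = sum(de$dep),
           top_terms = if (!is.null(enr) && nrow(enr))
             utils::head(enr$term[enr$adj_p < 0.05], 5) else character(0))
    }

    stage <- "de-groups"
    lab <- sim$labels
    grp <- factor(ifelse(lab == 1L, "pos", "neg"), c("neg", "pos"))
    summary$de_group <- run_contrast(paste0(config$outcomes[1], "_groups"), grp)

    stage <- "de-strata"
    strata <- first_fit$strata
    mk <- function(a, b, na, nb) {
      g <- rep(NA_character_, ncol(filtered))
      names(g) <- colnames(filtered)
      g[names(g) %in% a] <- na
      g[names(g) %in% b] <- nb
      factor(g, c(na, nb))
    }
    summary$de_tp_fp <- run_contrast("TP_FP",
                                     mk(strata$fp, strata$tp, "FP", "TP"))
    summary$de_tn_fn <- run_contrast("TN_FN",
                                     mk(strata$fn, strata$tn, "FN", "TN"))

    stage <- "summary"
    jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(summary)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}
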