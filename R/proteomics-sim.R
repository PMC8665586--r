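#' Generate a synthetic peptide-abundance matrix with planted effects
#'
#' Emulates a targeted CSF MRM peptide panel measured on a cohort:
#' log-scale Gaussian abundances, a designated set of truly differential
#' peptides shifted upward in the biomarker-positive subjects, a
#' missing-at-random mask, and a block of near-undetectable peptides
#' that exercise the detectability filter (their observed fraction is
#' forced to at most `detect_fraction`, while every other peptide is
#' guaranteed to clear it).  Alongside the matrix it returns the truth
#' list of differential peptides and a gene-set collection in which one
#' term is exactly the planted set and the rest are random null sets,
#' for enrichment-recovery experiments.
#'
#' @param cohort A `cohort_table` (or any data frame with `id` and the
#'   label column for `outcome`).
#' @param n_peptides Panel size (default 567, the published panel).
#' @param n_differential Number of truly differential peptides.
#' @param effect_size Standardised mean shift (in within-group SD units)
#'   added to differential peptides in labelled positives.
#' @param missing_rate Missing-at-random probability in `[0, 1)` for
#'   detectable peptides.
#' @param n_low_detect Number of peptides given near-total missingness
#'   (default 247, so that 320 of 567 survive the >10% filter).
#' @param outcome `"T"` or `"N"`: which label carries the planted effect.
#' @param n_null_sets Number of random null gene sets in the annotation.
#' @param detect_fraction The detectability cut-off the low-detect block
#'   is constructed to fail (default 0.10).
#' @param seed Integer seed.
#' @return A list of class `"proteomics_sim"`:
#'   `matrix` (peptides x subjects, `NA` = missing), `truth`
#'   (differential peptide ids), `gmt` (a [gene_set_collection()]; the
#'   planted term is named `"PLANTED_SET"`), `low_detect` (ids of the
#'   near-undetectable block), `labels` (named 0/1 vector per subject).
#' @export
generate_proteomics <- function(cohort, n_peptides = 567, n_differential = 30,
                                effect_size = 1.5, missing_rate = 0.05,
                                n_low_detect = 247, outcome = c("T", "N"),
                                n_null_sets = 20, detect_fraction = 0.10,
                                seed = 1L) {
  outcome <- match.arg(outcome)
  check_number(n_peptides, "n_peptides", lower = 1)
  check_number(n_differential, "n_differential", lower = 0, upper = n_peptides)
  check_number(effect_size, "effect_size", lower = 0)
  check_number(missing_rate, "missing_rate", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(n_low_detect, "n_low_detect", lower = 0, upper = n_peptides)
  if (n_differential > n_peptides - n_low_detect)
    stop_invalid("n_differential must fit among the detectable peptides")
  set.seed(as.integer(seed))

  labels <- cohort[[paste0("label_", outcome)]]
  names(labels) <- cohort$id
  n_sub <- length(labels)
  pep_ids <- sprintf("PEP%04d", seq_len(n_peptides))

  # per-peptide baseline level; unit within-group SD on the log scale
  base <- rnorm(n_peptides, mean = 5, sd = 1.5)
  M <- matrix(rnorm(n_peptides * n_sub), n_peptides, n_sub,
              dimnames = list(pep_ids, names(labels))) + base

  detectable <- pep_ids[seq_len(n_peptides - n_low_detect)]
  low_detect <- setdiff(pep_ids, detectable)
  truth <- if (n_differential > 0) sample(detectable, n_differential) else character(0)
  if (length(truth) && any(labels == 1L))
    M[truth, labels == 1L] <- M[truth, labels == 1L] + effect_size

  # MAR mask on detectable peptides, but never below the detectability floor
  floor_obs <- floor(detect_fraction * n_sub) + 1L
  if (missing_rate > 0) {
    mask <- matrix(runif(n_peptides * n_sub) < missing_rate, n_peptides, n_sub)
    mask[low_detect %in% rownames(M), ] <- FALSE  # handled below
    mask[match(low_detect, pep_ids), ] <- FALSE
    for (i in match(detectable, pep_ids)) {
      obs <- which(!mask[i, ])
      if (length(obs) < floor_obs) {
        keep <- sample(which(mask[i, ]), floor_obs - length(obs))
        mask[i, keep] <- FALSE
      }
    }
    M[mask] <- NA_real_
  }
  # low-detect block: observed count drawn in 0..floor(detect_fraction*n)
  for (i in match(low_detect, pep_ids)) {
    k <- sample.int(floor(detect_fraction * n_sub) + 1L, 1L) - 1L
    miss <- rep(TRUE, n_sub)
    if (k > 0) miss[sample.int(n_sub, k)] <- FALSE
    M[i, miss] <- NA_real_
  }

  sets <- list()
  if (length(truth)) sets$PLANTED_SET <- sort(truth)
  for (j in seq_len(n_null_sets)) {
    sz <- min(sample(15:40, 1L), length(detectable))
    sets[[sprintf("NULL_SET_%02d", j)]] <- sort(sample(detectable, sz))
  }
  gmt <- gene_set_collection(sets,
    description = setNames(c(if (length(truth)) "planted differential set",
                             rep("random null set", n_null_sets)),
                           names(sets)))

  structure(
    list(matrix = M, truth = sort(truth), gmt = gmt,
         low_detect = low_detect, labels = labels, outcome = outcome),
    class = "proteomics_sim"
  )
}

#' Read/write a peptide-abundance TSV
#'
#' Peptides as rows, subjects as columns, first column `peptide_id`,
#' empty cells denote missing values.
#'
#' @param matrix A numeric matrix with peptide row names.
#' @param path File path.
#' @export
write_proteomics <- function(matrix, path) {
  df <- data.frame(peptide_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_proteomics
#' @export
read_proteomics <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
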