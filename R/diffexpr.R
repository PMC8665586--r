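#' Peptide detectability filter
#'
#' Keeps peptides observed (non-missing) in strictly more than
#' `min_fraction` of subjects, the standard gate for sparse targeted
#' panels.
#'
#' @param matrix Peptides x subjects numeric matrix, `NA` = missing.
#' @param min_fraction Detectability cut-off in `[0, 1)` (default 0.10).
#' @return The filtered matrix, with attributes `n_kept` and
#'   `n_dropped`.
#' @export
detectability_filter <- function(matrix, min_fraction = 0.10) {
  check_number(min_fraction, "min_fraction", lower = 0, upper = 1,
               strict_upper = TRUE)
  frac <- rowMeans(!is.na(matrix))
  keep <- frac > min_fraction
  if (!any(keep))
    stop("detectability filter removed every peptide (empty panel)")
  out <- matrix[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Newton inversion of the trigamma function (used by the empirical-Bayes
# prior fit); trigamma is convex decreasing on (0, Inf)
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in 1:75) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

# moment-match the scaled inverse-chi-square prior (d0, s0^2) from the
# observed log sample variances: E[log s^2] and Var[log s^2] follow
# log-chi-square theory, so digamma/trigamma inversion recovers d0
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L)
    stop("too few peptides with positive residual variance to fit a prior")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated two-group differential expression
#'
#' Per-peptide two-group comparison with variance moderation.  For each
#' peptide the group means and the pooled residual variance `s^2` (with
#' residual df `d`) are computed from pairwise-complete observations
#' (no imputation).  A scaled inverse-chi-square prior `(d0, s0^2)` is
#' estimated across peptides by moment matching of `log s^2` using
#' digamma/trigamma inversion; the posterior variance
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` then yields the moderated
#' t-statistic `t = (mean2 - mean1) / (s~ sqrt(1/n1 + 1/n2))` on
#' `d0 + d` degrees of freedom.  As `d0 -> 0` this reduces to the
#' ordinary pooled t; as `d0 -> Inf` all peptides share `s0^2`.
#' Peptides with fewer than two observations in either group are
#' skipped (and reported).
#'
#' @param matrix Peptides x subjects matrix (log-scale abundances,
#'   `NA` = missing).
#' @param groups Two-level factor (or coercible) over the columns; the
#'   contrast is second level minus first.
#' @param fdr_threshold Adjusted-p cut-off for the DEP flag
#'   (default 0.05).
#' @return A data frame of class `"de_result"`, one row per analysed
#'   peptide: `peptide_id`, `logFC`, `t_ordinary`, `t` (moderated),
#'   `p`, `adj_p`, `dep`.  Attributes: `prior` (`d0`, `s02`),
#'   `n_skipped`, `contrast`.
#' @export
moderated_t <- function(matrix, groups, fdr_threshold = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop_invalid("groups must have exactly two levels")
  groups <- droplevels(groups)
  if (length(groups) != ncol(matrix))
    stop_invalid("groups length must match the number of subjects")
  g1 <- groups == levels(groups)[1L]
  g2 <- groups == levels(groups)[2L]

  M1 <- matrix[, g1, drop = FALSE]; M2 <- matrix[, g2, drop = FALSE]
  n1 <- rowSums(!is.na(M1)); n2 <- rowSums(!is.na(M2))
  usable <- n1 >= 2L & n2 >= 2L
  n_skipped <- sum(!usable)
  if (!any(usable))
    stop("no peptide has at least two observations per group")

  m1 <- rowMeans(M1, na.rm = TRUE); m2 <- rowMeans(M2, na.rm = TRUE)
  ss1 <- rowSums((M1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((M2 - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df

  idx <- which(usable)
  if (all(s2[idx] == 0))
    stop("all residual variances are zero; the variance prior is degenerate. ",
         "Check that abundances are continuous measurements.")

  prior <- fit_variance_prior(s2[idx], df[idx])
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(idx)) else
    (d0 * s02 + df[idx] * s2[idx]) / (d0 + df[idx])
  se_scale <- sqrt(1 / n1[idx] + 1 / n2[idx])
  delta <- (m2 - m1)[idx]
  t_mod <- delta / (sqrt(s2_post) * se_scale)
  t_ord <- delta / (sqrt(s2[idx]) * se_scale)
  df_total <- if (is.infinite(d0)) Inf else d0 + df[idx]
  p <- 2 * pt(-abs(t_mod), df = df_total)
  adj <- bh_adjust(p)

  out <- data.frame(
    peptide_id = rownames(matrix)[idx],
    logFC = delta,
    t_ordinary = t_ord,
    t = t_mod,
    p = p,
    adj_p = adj,
    dep = adj < fdr_threshold,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "prior") <- prior
  attr(out, "n_skipped") <- n_skipped
  attr(out, "contrast") <- paste(levels(groups)[2L], "-", levels(groups)[1L])
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1), with
#' input validation; a thin, checked interface over the standard BH
#' procedure.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, in input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop_invalid("p must be numeric in [0, 1] with no NA")
  p.adjust(p, method = "BH")
}

#' Optional protein-level roll-up of a peptide DE result
#'
#' Summarises peptide rows to proteins by the peptide with the largest
#' absolute moderated t per protein (an extension; the core analysis is
#' peptide-level).
#'
#' @param de A `de_result`.
#' @param protein_map Named character vector: peptide id -> protein id.
#' @return A `de_result`-shaped data frame with `protein_id` first.
#' @export
summarize_by_protein <- function(de, protein_map) {
  prot <- protein_map[de$peptide_id]
  if (anyNA(prot)) stop_invalid("protein_map lacks some peptide ids")
  keep <- !duplicated(prot[order(-abs(de$t))])[order(order(-abs(de$t)))]
  ix <- order(-abs(de$t))[!duplicated(prot[order(-abs(de$t))])]
  out <- de[ix, , drop = FALSE]
  out <- cbind(protein_id = prot[ix], out)
  out[order(out$p), ]
}

#' Write a DE result TSV
#'
#' Column set mirrors the conventional DEP export: protein/peptide id,
#' p-value, adjusted p-value, t-value and logFC.
#'
#' @param de A `de_result`.
#' @param path Output file.
#' @export
write_de_result <- function(de, path) {
  out <- data.frame(`Protein ID` = de$peptide_id, `p-value` = de$p,
                    `adjusted p-value` = de$adj_p, `t-value` = de$t,
                    logFC = de$logFC, check.names = FALSE)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
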