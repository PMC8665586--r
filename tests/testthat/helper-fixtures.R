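# shared fixtures, built in code

# small cohort with a chosen outcome and seed
tiny_cohort <- function(n = 100, outcome = "T", seed = 1) {
  generate_cohort(generator_config(n_subjects = n, outcome = outcome,
                                   seed = seed))
}

# minimal fast classifier roster for pipeline-level tests
fast_algorithms <- function() {
  default_algorithms("reduced")[c("logistic_regression", "knn",
                                  "decision_tree")]
}

# cohort-shaped label frame for proteomics fixtures (n1 negatives then
# n2 positives, the published contrast sizes by default)
label_frame <- function(n_neg = 55, n_pos = 21) {
  data.frame(id = sprintf("S%03d", seq_len(n_neg + n_pos)),
             label_T = rep(c(0L, 1L), c(n_neg, n_pos)),
             label_N = rep(c(0L, 1L), c(n_neg, n_pos)))
}

# independent rank-based AUC oracle: count positive/negative pairs
pairwise_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# exact Mann-Whitney two-sided p by enumerating all rank splits
enumerated_mw_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  r <- rank(pooled)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact upper-tail overlap probability by enumerating all n-subsets of
# the universe (brute-force hypergeometric oracle, N <= 12)
enumerated_ora_p <- function(set, universe, n_query, k_obs) {
  combs <- utils::combn(length(universe), n_query)
  hits <- apply(combs, 2, function(ix)
    length(intersect(universe[ix], set)) >= k_obs)
  mean(hits)
}
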