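test_that("Mann-Whitney matches full enumeration on small samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1, tolerance = 1e-12)   # 2/20 rank splits as extreme
  expect_equal(mw$p, enumerated_mw_p(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    expect_equal(mann_whitney(x, y)$p, enumerated_mw_p(x, y),
                 tolerance = 1e-10)
  }
})

test_that("Mann-Whitney identities hold", {
  set.seed(8)
  x <- rnorm(9); y <- rnorm(14)
  expect_equal(mann_whitney(x, y)$U + mann_whitney(y, x)$U,
               length(x) * length(y))
  z <- c(1, 2, 2, 5)
  expect_equal(mann_whitney(z, z)$auc, 0.5)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact and approximate Mann-Whitney p agree at n = 6 + 6", {
  set.seed(13)
  for (i in 1:100) {
    x <- rnorm(6); y <- rnorm(6)
    p_exact <- mann_whitney(x, y, exact_limit = 12)$p
    p_approx <- mann_whitney(x, y, exact_limit = 0)$p
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("binormal AUC reproduces the published single-feature values", {
  expect_equal(binormal_auc(10, 2, 10, 3), 0.5)
  # printed T-group statistics for Abeta1-38 give ~0.805 (published 0.811)
  expect_equal(binormal_auc(2411, 566.95, 1764, 496.1), 0.805,
               tolerance = 0.001)
  # N groups, 42/38 ratio: positives lower, direction-corrected ~0.653
  v <- binormal_auc(0.6146, 0.25, 0.7483, 0.23)
  expect_lt(v, 0.5)
  expect_equal(1 - v, 0.653, tolerance = 0.002)
})

test_that("binormal AUC is antisymmetric in the group roles", {
  set.seed(2)
  for (i in 1:25) {
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, 0.5, 2); s2 <- runif(1, 0.5, 2)
    expect_equal(binormal_auc(m1, s1, m2, s2),
                 1 - binormal_auc(m2, s2, m1, s1), tolerance = 1e-12)
  }
})

test_that("single-feature CV AUC tracks the feature's empirical AUC", {
  set.seed(31)
  labels <- rbinom(300, 1, 0.4)
  feature <- labels + rnorm(300, sd = 0.8)
  res <- single_feature_cv_auc(feature, labels, seed = 4)
  expect_equal(res$auc, empirical_auc(feature, labels), tolerance = 0.05)
  # a feature identical to the label is classified perfectly
  expect_equal(single_feature_cv_auc(labels, labels, seed = 1)$auc, 1)
})

test_that("a label-independent feature scores near 0.5", {
  set.seed(77)
  labels <- rbinom(500, 1, 0.5)
  feature <- rnorm(500)
  auc <- single_feature_cv_auc(feature, labels, seed = 2)$auc
  # permutation band: empirical AUC over label shuffles
  perm <- replicate(200, empirical_auc(feature, sample(labels)))
  expect_gt(auc, quantile(perm, 0.005))
  expect_lt(auc, quantile(perm, 0.995))
})

test_that("Fisher's exact test matches the hypergeometric tail sums", {
  # two maximally unbalanced tables out of C(20,10) equally likely splits
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  m <- matrix(c(7, 2, 3, 8), 2)
  expect_equal(fisher_exact(m), fisher_exact(m[2:1, ]), tolerance = 1e-12)
  expect_message(p <- fisher_exact(matrix(c(0, 0, 4, 5), 2)), "zero margin")
  expect_equal(p, 1)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("group comparison and description tables are coherent", {
  coh <- tiny_cohort(n = 250, outcome = "T", seed = 10)
  cmp <- compare_groups(coh, "T")
  expect_equal(nrow(cmp), 6)
  expect_true(all(cmp$p > 0 & cmp$p <= 1))
  expect_true(all(cmp$auc >= 0 & cmp$auc <= 1))
  # ab38 is higher in positives and discriminative by construction
  expect_equal(cmp$higher_in[cmp$feature == "ab38"], "positive")
  expect_gt(cmp$auc[cmp$feature == "ab38"], 0.7)
  # AUC column consistent with the Mann-Whitney U column
  i <- which(cmp$feature == "ab40")
  n1 <- sum(coh$label_T == 1); n0 <- sum(coh$label_T == 0)
  expect_equal(cmp$auc[i], cmp$U[i] / (n1 * n0), tolerance = 1e-12)

  desc <- describe_cohort(coh, "T")
  expect_identical(desc$characteristic[1], "n")
  expect_equal(sum(as.integer(desc[1, c("neg", "pos")])), 250)
  expect_true(all(desc$p[-1] > 0 & desc$p[-1] <= 1))
})
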