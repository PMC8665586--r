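test_that("detectability filter keeps peptides strictly above the cut-off", {
  M <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("P", 1:6), paste0("S", 1:10)))
  M[1, 1:9] <- NA          # 10% observed -> not strictly greater, dropped
  M[2, 1:10] <- NA         # all missing
  M[3, 1:8] <- NA          # 20% observed, kept
  f <- detectability_filter(M, 0.10)
  expect_identical(rownames(f), paste0("P", 3:6))
  expect_equal(attr(f, "n_kept"), 4)
  # min_fraction = 0 drops only all-missing peptides
  f0 <- detectability_filter(M, 0)
  expect_identical(rownames(f0), paste0("P", c(1, 3:6)))
  expect_error(detectability_filter(M, 1), "must be <")
  expect_error(detectability_filter(M[2, , drop = FALSE], 0.1),
               "empty panel")
})

test_that("moderated t matches its own posterior formula and the d0 limits", {
  set.seed(1)
  M <- matrix(rnorm(120 * 16, sd = rep(sqrt(rchisq(120, 4) / 4), 16)), 120)
  rownames(M) <- sprintf("P%03d", 1:120)
  grp <- factor(rep(c("a", "b"), each = 8))
  de <- moderated_t(M, grp)
  prior <- attr(de, "prior")
  # recompute one peptide from first principles
  id <- de$peptide_id[1]
  i <- match(id, rownames(M))
  x <- M[i, grp == "a"]; y <- M[i, grp == "b"]
  s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 14
  s2_post <- (prior$d0 * prior$s02 + 14 * s2) / (prior$d0 + 14)
  t_manual <- (mean(y) - mean(x)) / sqrt(s2_post * (1 / 8 + 1 / 8))
  expect_equal(de$t[1], t_manual, tolerance = 1e-12)
  expect_equal(de$p[1], 2 * pt(-abs(t_manual), prior$d0 + 14),
               tolerance = 1e-12)
  # ordinary t uses the raw pooled variance
  expect_equal(de$t_ordinary[1],
               (mean(y) - mean(x)) / sqrt(s2 * (1 / 4)), tolerance = 1e-12)
  # d0 -> 0: moderated equals ordinary; d0 -> Inf: shared variance
  expect_equal((0 * prior$s02 + 14 * s2) / (0 + 14), s2)
  # shrinkage pulls each variance toward the prior
  expect_true((s2_post - s2) * (prior$s02 - s2) >= 0)
})

test_that("moderated t agrees with limma on complete data", {
  skip_if_not_installed("limma")
  set.seed(9)
  M <- matrix(rnorm(200 * 20, sd = rep(sqrt(rchisq(200, 5) / 5), 20)), 200)
  rownames(M) <- sprintf("P%03d", 1:200)
  M[1:20, 13:20] <- M[1:20, 13:20] + 1.2
  grp <- factor(rep(c("a", "b"), c(12, 8)))
  de <- moderated_t(M, grp)
  fitl <- limma::eBayes(limma::lmFit(M, stats::model.matrix(~grp)))
  tt <- limma::topTable(fitl, coef = 2, number = Inf, sort.by = "none")
  o <- match(de$peptide_id, rownames(tt))
  expect_equal(attr(de, "prior")$d0, fitl$df.prior, tolerance = 1e-9)
  expect_equal(attr(de, "prior")$s02, fitl$s2.prior, tolerance = 1e-9)
  expect_equal(de$t, tt$t[o], tolerance = 1e-9)
  expect_equal(de$p, tt$P.Value[o], tolerance = 1e-9)
  expect_equal(de$logFC, tt$logFC[o], tolerance = 1e-9)
})

test_that("moderated t is monotone in the mean difference at fixed variance", {
  set.seed(4)
  # every peptide shares the same residual pattern, so the pooled
  # variances are identical and only the planted shift varies
  e <- rnorm(12)
  grp <- factor(rep(c("a", "b"), each = 6))
  shifts <- seq(0, 2, length.out = 50)
  M <- matrix(rep(e, each = 50), 50, 12) +
    outer(shifts, as.numeric(grp == "b"))
  rownames(M) <- sprintf("P%02d", 1:50)
  de <- moderated_t(M, grp)
  o <- match(sprintf("P%02d", 1:50), de$peptide_id)
  expect_equal(diff(de$logFC[o]), rep(diff(shifts)[1], 49), tolerance = 1e-9)
  expect_true(all(diff(de$t[o]) > 0))
})

test_that("peptides with too few observations are skipped, not fatal", {
  set.seed(6)
  M <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("P", 1:4), NULL))
  M[1, 1:9] <- NA   # <2 obs in one group
  grp <- factor(rep(c("a", "b"), each = 5))
  de <- moderated_t(M, grp)
  expect_equal(attr(de, "n_skipped"), 1)
  expect_setequal(de$peptide_id, paste0("P", 2:4))
  expect_error(moderated_t(M, rep("a", 10)), "two levels")
})

test_that("BH adjustment matches the hand-worked step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation equivariance
  set.seed(12)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
  # adjusted >= raw, <= 1
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
})

test_that("protein roll-up keeps the strongest peptide per protein", {
  set.seed(2)
  M <- matrix(rnorm(6 * 12), 6, 12, dimnames = list(paste0("P", 1:6), NULL))
  M[1, 7:12] <- M[1, 7:12] + 3
  grp <- factor(rep(c("a", "b"), each = 6))
  de <- moderated_t(M, grp)
  map <- setNames(c("A", "A", "B", "B", "C", "C"), paste0("P", 1:6))
  prot <- summarize_by_protein(de, map)
  expect_equal(nrow(prot), 3)
  expect_setequal(prot$protein_id, c("A", "B", "C"))
  # protein A is represented by its strongest peptide, P1
  expect_identical(prot$peptide_id[prot$protein_id == "A"], "P1")
})
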