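test_that("ratios and strict-threshold labels are computed correctly", {
  coh <- data.frame(
    id = c("a", "b", "c", "d"),
    age = 70, sex = 1L, education = 16, apoe4 = 0L,
    ab38 = c(2000, 2000, 2000, 2000),
    ab40 = c(8000, 8000, 8000, 8000),
    ab42 = c(1400, 1400, 1400, 1400),
    ptau = c(19.2, 19.21, 10, 30),
    ttau = c(242, 242.5, 100, 300)
  )
  fs <- build_features(coh)
  expect_equal(fs$features$r4240, rep(0.175, 4))
  expect_equal(fs$features$r4238, rep(0.7, 4))
  expect_equal(fs$features$r4038, rep(4, 4))
  expect_identical(fs$label_T, c(0L, 1L, 0L, 1L))
  expect_identical(fs$label_N, c(0L, 1L, 0L, 1L))
  expect_identical(colnames(fs$features), canonical_features())
})

test_that("subjects with missing or degenerate predictors are dropped", {
  coh <- tiny_cohort(30, seed = 3)
  coh$ab40[2] <- NA; coh$ab38[5] <- 0
  expect_message(fs <- build_features(coh), "dropped 2")
  expect_equal(fs$n_dropped, 2)
  expect_equal(nrow(fs$features), 28)
  expect_false(any(c(coh$id[2], coh$id[5]) %in% fs$id))
})

test_that("ratio columns are invariant to common rescaling", {
  coh <- tiny_cohort(50, seed = 6)
  fs1 <- build_features(coh)
  coh2 <- coh
  coh2$ab42 <- coh2$ab42 * 3.7
  coh2$ab40 <- coh2$ab40 * 3.7
  fs2 <- build_features(coh2)
  expect_equal(fs2$features$r4240, fs1$features$r4240, tolerance = 1e-12)
})

test_that("subset enumeration is a bijection with nonzero bitmasks", {
  subs10 <- enumerate_subsets(canonical_features())
  expect_length(subs10, 1023)
  subs3 <- enumerate_subsets(c("a", "b", "c"))
  expect_length(subs3, 7)
  expect_length(enumerate_subsets("x"), 1)
  expect_identical(enumerate_subsets("x")[[1]]$features, "x")

  # membership reconstructed from the index must match exactly
  idx <- vapply(subs10, `[[`, integer(1), "index")
  expect_identical(idx, 1:1023)
  feats <- canonical_features()
  for (s in subs10[c(1, 2, 3, 512, 777, 1023)]) {
    bits <- which(as.logical(bitwAnd(s$index, 2^(0:9))))
    expect_identical(s$features, feats[bits])
  }
  # union of singletons recovers the feature set
  singles <- Filter(function(s) length(s$features) == 1L, subs10)
  expect_setequal(unlist(lapply(singles, `[[`, "features")), feats)
  # no duplicate membership patterns
  keys <- vapply(subs10, function(s) paste(s$features, collapse = "|"),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("enumeration rejects invalid inputs", {
  expect_error(enumerate_subsets(character(0)), "at least one")
  expect_error(enumerate_subsets(letters[c(1, 1, 2)]), "unique")
  expect_error(enumerate_subsets(paste0("f", 1:21)), "at most 20")
})
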