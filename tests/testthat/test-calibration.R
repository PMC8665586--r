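test_that("lognormal moment matching reproduces the printed isoform moments", {
  for (g in c("T-", "T+", "N-", "N+")) {
    gp <- default_group_params(g)
    m <- calibrate_lognormal(gp)
    mu <- m$log_mean; s2 <- diag(m$log_cov)
    means <- exp(mu + s2 / 2)
    sds <- means * sqrt(exp(s2) - 1)
    expect_equal(unname(means),
                 c(gp$mean_ab38, gp$mean_ab40, gp$mean_ab42), tolerance = 1e-12)
    expect_equal(unname(sds),
                 c(gp$sd_ab38, gp$sd_ab40, gp$sd_ab42), tolerance = 1e-12)
  }
})

test_that("log-correlation solves the ratio-variance equation by hand", {
  # hand-solved: sigma38^2 = log(1 + (496.1/1764)^2), sigma40^2 likewise,
  # ratio 40/38 log-variance from 4.354 +/- 0.42, then
  # rho = (s38^2 + s40^2 - sr^2) / (2 s38 s40) ~ 0.937
  m <- calibrate_lognormal(default_group_params("T-"))
  rho <- attr(m, "rho")
  expect_equal(unname(rho["r4038"]), 0.937, tolerance = 0.001)
  # consistency: covariance reproduces the ratio log-variance exactly
  S <- m$log_cov
  gp <- default_group_params("T-")
  target <- log(1 + (gp$sd_r4038 / gp$mean_r4038)^2)
  expect_equal(S["ab40", "ab40"] + S["ab38", "ab38"] - 2 * S["ab40", "ab38"],
               target, tolerance = 1e-12)
})

test_that("independence and single-CV formula instances hold", {
  # when the ratio log-variance equals the sum of the isoform
  # log-variances, the implied correlation is zero
  mean_x <- 100; cv_x <- 0.2; mean_y <- 50; cv_y <- 0.3
  s2x <- log(1 + cv_x^2); s2y <- log(1 + cv_y^2)
  rv <- s2x + s2y
  # invert: pick a ratio mean and the SD implying rv
  rmean <- 2; rsd <- rmean * sqrt(exp(rv) - 1)
  gp <- group_params(mean_x, mean_x * cv_x, mean_y, mean_y * cv_y,
                     80, 20,
                     0.8, 0.1, 0.8, 0.1, rmean, rsd,
                     70, 5, 15, 3, 0.5, 0.2)
  # the other two (arbitrary) ratio targets may force a PD repair; only
  # the 40/38 independence relation is under test here
  m <- suppressWarnings(calibrate_lognormal(gp))
  expect_equal(unname(attr(m, "rho")["r4038"]), 0, tolerance = 1e-10)

  # mean m, CV 0.1 -> sigma^2 = log(1.01), mu = log(m) - log(1.01)/2
  gp2 <- group_params(200, 20, 7000, 2000, 1400, 500,
                      0.2, 0.05, 0.7, 0.2, 4.3, 0.4,
                      70, 5, 15, 3, 0.5, 0.2)
  m2 <- suppressWarnings(calibrate_lognormal(gp2))
  expect_equal(unname(diag(m2$log_cov)["ab38"]), log(1.01), tolerance = 1e-12)
  expect_equal(unname(m2$log_mean["ab38"]), log(200) - log(1.01) / 2,
               tolerance = 1e-12)
})

test_that("invalid group parameters are rejected", {
  expect_error(group_params(-1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                            70, 5, 15, 3, 0.5, 0.2), "must be >")
  expect_error(group_params(1, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                            70, 5, 15, 3, 0.5, 0.2), "must be >")
  expect_error(calibrate_lognormal(list(a = 1)), "group_params")
})

test_that("inconsistent ratio variances are clamped with a warning", {
  # ratio SD far too small for the isoform CVs -> |rho| > 1
  gp <- group_params(1764, 496.1, 7617, 2052, 1353, 559.4,
                     0.1749, 0.05, 0.7610, 0.22, 4.354, 0.0001,
                     70, 5, 15, 3, 0.5, 0.2)
  expect_warning(m <- calibrate_lognormal(gp), "clamp")
  ev <- eigen(m$log_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_true(all(abs(attr(m, "rho") <= 1)))
})

test_that("Monte Carlo ratios track the printed ratio statistics", {
  set.seed(123)
  for (g in c("T-", "N+")) {
    gp <- default_group_params(g)
    m <- calibrate_lognormal(gp)
    X <- abatn:::sample_isoforms(m, 1e5)
    r <- cbind(X[, "ab42"] / X[, "ab40"], X[, "ab42"] / X[, "ab38"],
               X[, "ab40"] / X[, "ab38"])
    target_mean <- c(gp$mean_r4240, gp$mean_r4238, gp$mean_r4038)
    target_sd <- c(gp$sd_r4240, gp$sd_r4238, gp$sd_r4038)
    # ratio log-variances are matched exactly; arithmetic ratio means are
    # implied (the printed table is overdetermined), so a few-percent band
    expect_lt(max(abs(colMeans(r) / target_mean - 1)), 0.04)
    expect_lt(max(abs(apply(r, 2, sd) / target_sd - 1)), 0.04)
    logvar_target <- log(1 + (target_sd / target_mean)^2)
    expect_equal(apply(log(r), 2, var), logvar_target, tolerance = 0.02)
  }
})
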