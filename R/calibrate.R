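#' Moment-matched lognormal model of the three amyloid-beta isoforms
#'
#' Converts the printed arithmetic group statistics (isoform means/SDs and
#' ratio means/SDs) into the parameters of a trivariate lognormal
#' distribution on (Abeta1-38, Abeta1-40, Abeta1-42).
#'
#' Per isoform the log-moments follow from exact lognormal moment
#' matching: `sigma^2 = log(1 + CV^2)`, `mu = log(mean) - sigma^2 / 2`.
#' Each pairwise log-correlation is then solved from the corresponding
#' ratio's log-variance via
#' `Var(log X - log Y) = sx^2 + sy^2 - 2 * rho * sx * sy`,
#' the ratio's log-variance being matched from its own mean/SD the same
#' way.  Because the printed table carries more moments than a trivariate
#' lognormal has parameters, ratio *means* are implied rather than
#' matched; they land within a few percent of the printed values (the
#' ratio log-variances are matched exactly).
#'
#' Correlations are clamped to `[-0.999, 0.999]` with a warning if the
#' printed moments are inconsistent with any valid correlation, and the
#' covariance matrix is shrunk toward its diagonal (again with a warning)
#' in the unlikely case it is not positive definite.
#'
#' @param group A [group_params()] object.
#' @return An object of class `"lognormal_group_model"` with elements
#'   `log_mean` (length-3 named vector) and `log_cov` (3x3 matrix), plus
#'   the implied log-correlations as attribute `"rho"`.
#' @examples
#' m <- calibrate_lognormal(default_group_params("T-"))
#' exp(m$log_mean + diag(m$log_cov) / 2)  # recovers the isoform means
#' @export
calibrate_lognormal <- function(group) {
  if (!inherits(group, "group_params"))
    stop_invalid("group must be a group_params object")

  iso <- c("ab38", "ab40", "ab42")
  m <- c(group$mean_ab38, group$mean_ab40, group$mean_ab42)
  s <- c(group$sd_ab38, group$sd_ab40, group$sd_ab42)
  names(m) <- names(s) <- iso
  if (any(m <= 0) || any(s <= 0))
    stop_invalid("isoform means and SDs must be strictly positive")

  sig2 <- log(1 + (s / m)^2)
  mu <- log(m) - sig2 / 2
  sig <- sqrt(sig2)

  ratio_logvar <- function(rm, rs) {
    if (rm <= 0 || rs <= 0) stop_invalid("ratio means and SDs must be strictly positive")
    log(1 + (rs / rm)^2)
  }
  # ratio -> (numerator, denominator)
  pairs <- list(
    r4240 = c("ab42", "ab40"),
    r4238 = c("ab42", "ab38"),
    r4038 = c("ab40", "ab38")
  )
  rv <- c(
    r4240 = ratio_logvar(group$mean_r4240, group$sd_r4240),
    r4238 = ratio_logvar(group$mean_r4238, group$sd_r4238),
    r4038 = ratio_logvar(group$mean_r4038, group$sd_r4038)
  )

  rho <- vapply(names(pairs), function(r) {
    x <- pairs[[r]][1]; y <- pairs[[r]][2]
    (sig2[x] + sig2[y] - rv[r]) / (2 * sig[x] * sig[y])
  }, numeric(1))
  if (any(abs(rho) > 0.999)) {
    warning("printed ratio variances imply |correlation| > 1; clamping to [-0.999, 0.999]",
            call. = FALSE)
    rho <- pmin(pmax(rho, -0.999), 0.999)
  }

  S <- diag(sig2)
  dimnames(S) <- list(iso, iso)
  for (r in names(pairs)) {
    x <- pairs[[r]][1]; y <- pairs[[r]][2]
    S[x, y] <- S[y, x] <- rho[r] * sig[x] * sig[y]
  }
  # pairwise-clamped correlations can in principle break joint PD;
  # shrink off-diagonals until the smallest eigenvalue is positive
  shrink <- 1
  while (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    shrink <- shrink * 0.95
    S2 <- diag(sig2)
    dimnames(S2) <- list(iso, iso)
    for (r in names(pairs)) {
      x <- pairs[[r]][1]; y <- pairs[[r]][2]
      S2[x, y] <- S2[y, x] <- shrink * rho[r] * sig[x] * sig[y]
    }
    S <- S2
    if (shrink < 0.5) break
  }
  if (shrink < 1)
    warning("log-covariance was not positive definite; off-diagonals shrunk by ",
            signif(shrink, 3), call. = FALSE)

  structure(
    list(log_mean = mu, log_cov = S),
    rho = rho,
    class = "lognormal_group_model"
  )
}

#' @method print lognormal_group_model
#' @export
print.lognormal_group_model <- function(x, ...) {
  cat("Trivariate lognormal isoform model\n")
  cat("  log-means:", paste(sprintf("%s=%.4f", names(x$log_mean), x$log_mean),
                            collapse = ", "), "\n")
  cat("  log-correlations:",
      paste(sprintf("%s=%.3f", names(attr(x, "rho")), attr(x, "rho")),
            collapse = ", "), "\n")
  invisible(x)
}

# draw n rows of (ab38, ab40, ab42) from a calibrated model
sample_isoforms <- function(model, n) {
  if (n == 0L)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, names(model$log_mean))))
  L <- chol(model$log_cov)
  Z <- matrix(rnorm(n * 3), n, 3) %*% L
  X <- exp(sweep(Z, 2, model$log_mean, "+"))
  colnames(X) <- names(model$log_mean)
  X
}
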