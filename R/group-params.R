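#' Group-conditional distribution parameters for the cohort generator
#'
#' Bundles the summary statistics that define one biomarker group
#' (e.g. T- or T+): means and SDs of the three CSF amyloid-beta isoforms
#' (pg/mL), of their three pairwise ratios (dimensionless), of age and
#' education (years), and the female and APOE e4 carrier fractions.
#'
#' @param mean_ab38,sd_ab38 Abeta1-38 mean and SD, pg/mL.
#' @param mean_ab40,sd_ab40 Abeta1-40 mean and SD, pg/mL.
#' @param mean_ab42,sd_ab42 Abeta1-42 mean and SD, pg/mL.
#' @param mean_r4240,sd_r4240 Abeta1-42/Abeta1-40 ratio mean and SD.
#' @param mean_r4238,sd_r4238 Abeta1-42/Abeta1-38 ratio mean and SD.
#' @param mean_r4038,sd_r4038 Abeta1-40/Abeta1-38 ratio mean and SD.
#' @param mean_age,sd_age Age mean and SD, years.
#' @param mean_edu,sd_edu Education mean and SD, years.
#' @param frac_female Proportion of females in `[0, 1]`.
#' @param frac_apoe4 Proportion of APOE e4 carriers in `[0, 1]`.
#' @return An object of class `"group_params"` (a named list).
#' @seealso [default_group_params()] for the published cohort values,
#'   [calibrate_lognormal()] for the latent isoform model.
#' @export
group_params <- function(mean_ab38, sd_ab38, mean_ab40, sd_ab40,
                         mean_ab42, sd_ab42,
                         mean_r4240, sd_r4240, mean_r4238, sd_r4238,
                         mean_r4038, sd_r4038,
                         mean_age, sd_age, mean_edu, sd_edu,
                         frac_female, frac_apoe4) {
  gp <- list(
    mean_ab38 = mean_ab38, sd_ab38 = sd_ab38,
    mean_ab40 = mean_ab40, sd_ab40 = sd_ab40,
    mean_ab42 = mean_ab42, sd_ab42 = sd_ab42,
    mean_r4240 = mean_r4240, sd_r4240 = sd_r4240,
    mean_r4238 = mean_r4238, sd_r4238 = sd_r4238,
    mean_r4038 = mean_r4038, sd_r4038 = sd_r4038,
    mean_age = mean_age, sd_age = sd_age,
    mean_edu = mean_edu, sd_edu = sd_edu,
    frac_female = frac_female, frac_apoe4 = frac_apoe4
  )
  means <- gp[grep("^mean_(ab|r)", names(gp))]
  sds <- gp[grep("^sd_", names(gp))]
  for (nm in names(means)) check_number(means[[nm]], nm, lower = 0, strict_lower = TRUE)
  for (nm in names(sds)) check_number(sds[[nm]], nm, lower = 0, strict_lower = TRUE)
  check_number(gp$mean_age, "mean_age", lower = 0, strict_lower = TRUE)
  check_number(gp$mean_edu, "mean_edu", lower = 0, strict_lower = TRUE)
  check_number(gp$frac_female, "frac_female", lower = 0, upper = 1)
  check_number(gp$frac_apoe4, "frac_apoe4", lower = 0, upper = 1)
  structure(gp, class = "group_params")
}

#' Published group summary statistics for the study CU cohort
#'
#' Returns the [group_params()] object for one of the four biomarker
#' groups of the study population (cognitively unimpaired, n = 318):
#' tau-pathology negative/positive (`"T-"`, `"T+"`, split at CSF
#' p-tau181 > 19.2 pg/mL) or neurodegeneration negative/positive
#' (`"N-"`, `"N+"`, split at CSF t-tau > 242 pg/mL).  Values are the
#' published per-group means and SDs of the isoforms, ratios and
#' demographics; these constants are the calibration targets of the
#' synthetic-cohort generator.
#'
#' @param group One of `"T-"`, `"T+"`, `"N-"`, `"N+"`.
#' @return A `"group_params"` object.
#' @export
default_group_params <- function(group = c("T-", "T+", "N-", "N+")) {
  group <- match.arg(group)
  switch(group,
    "T-" = group_params(
      1764, 496.1, 7617, 2052, 1353, 559.4,
      0.1749, 0.05, 0.7610, 0.22, 4.354, 0.42,
      73.87, 4.54, 15.77, 2.77, 0.50, 0.1538),
    "T+" = group_params(
      2411, 566.95, 10424, 2529, 1492, 784,
      0.1381, 0.06, 0.6014, 0.25, 4.329, 0.35,
      77.26, 5.32, 15.69, 2.91, 0.50, 0.3276),
    "N-" = group_params(
      1760, 469.6, 7593, 1945, 1328, 565.1,
      0.1720, 0.05, 0.7483, 0.23, 4.350, 0.41,
      74.46, 4.66, 15.57, 3.10, 0.5075, 0.1940),
    "N+" = group_params(
      2503, 567.2, 10838, 2503, 1575, 778.8,
      0.1411, 0.05, 0.6146, 0.25, 4.336, 0.35,
      77.52, 5.55, 15.98, 2.37, 0.4884, 0.3256)
  )
}

#' @method print group_params
#' @export
print.group_params <- function(x, ...) {
  cat("Biomarker group parameters\n")
  cat(sprintf("  Abeta1-38: %8.1f +/- %-8.1f pg/mL\n", x$mean_ab38, x$sd_ab38))
  cat(sprintf("  Abeta1-40: %8.1f +/- %-8.1f pg/mL\n", x$mean_ab40, x$sd_ab40))
  cat(sprintf("  Abeta1-42: %8.1f +/- %-8.1f pg/mL\n", x$mean_ab42, x$sd_ab42))
  cat(sprintf("  42/40 ratio: %.4f +/- %.4f   42/38: %.4f +/- %.4f   40/38: %.4f +/- %.4f\n",
              x$mean_r4240, x$sd_r4240, x$mean_r4238, x$sd_r4238,
              x$mean_r4038, x$sd_r4038))
  cat(sprintf("  age %.1f +/- %.1f y, education %.1f +/- %.1f y, %.0f%% female, %.0f%% APOE e4\n",
              x$mean_age, x$sd_age, x$mean_edu, x$sd_edu,
              100 * x$frac_female, 100 * x$frac_apoe4))
  invisible(x)
}
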