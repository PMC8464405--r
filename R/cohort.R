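#' Packaged femoral-artery cohort tables
#'
#' Plain-text transcriptions of the published cohort tables for the 14
#' superficial femoral artery (SFA) specimens: `sfa_table1()` returns the
#' subject demographics and risk factors (age, sex, BMI, smoking,
#' hypertension, diabetes, dyslipidemia, coronary artery disease);
#' `sfa_table2()` returns the specimen-level pathology, structural
#' parameters (mean collagen fiber angle `alpha_deg`, in-plane and
#' out-of-plane dispersions `kappa_ip`, `kappa_op`) and the fitted two- and
#' four-fiber-family constitutive parameters with their direction-wise
#' coefficients of determination.
#'
#' @return A data frame, one row per specimen.
#' @examples
#' nrow(sfa_table2())  # 14
#' @export
sfa_table2 <- function() {
  utils::read.csv(system.file("extdata", "sfa_table2.csv",
                              package = "fiberwall"),
                  stringsAsFactors = FALSE)
}

#' @rdname sfa_table2
#' @export
sfa_table1 <- function() {
  utils::read.csv(system.file("extdata", "sfa_table1.csv",
                              package = "fiberwall"),
                  stringsAsFactors = FALSE)
}

#' Pearson correlation of a structural parameter with age
#'
#' Pearson correlation between a cohort field and age, with the two-sided
#' p-value from the t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom (the no-correlation null hypothesis), plus
#' the ordinary-least-squares slope and intercept of the field on age.
#' Incomplete pairs are excluded pairwise.
#'
#' @param records Cohort data frame with an `age` column.
#' @param field Name of the column to correlate with age.
#' @return A list of class `age_correlation` with `r`, `p`, `n`, `slope`
#'   (field units per year), `intercept` and `field`.
#' @examples
#' pearson_with_age(sfa_table2(), "alpha_deg")
#' @export
pearson_with_age <- function(records, field) {
  stopifnot(is.data.frame(records), "age" %in% names(records),
            field %in% names(records))
  ok <- stats::complete.cases(records[c("age", field)])
  x <- records$age[ok]
  y <- records[[field]][ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("constant age: correlation undefined")
  ols <- stats::lm(y ~ x)
  if (stats::sd(y) == 0) {
    # degenerate but regression still defined: zero slope, flagged r
    warning("constant field: correlation undefined (flagged NA)")
    return(structure(list(r = NA_real_, p = NA_real_, n = length(x),
                          slope = unname(stats::coef(ols)[2]),
                          intercept = unname(stats::coef(ols)[1]),
                          field = field),
                     class = "age_correlation"))
  }
  ct <- stats::cor.test(x, y)
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 slope = unname(stats::coef(ols)[2]),
                 intercept = unname(stats::coef(ols)[1]), field = field),
            class = "age_correlation")
}

#' @export
print.age_correlation <- function(x, ...) {
  cat(sprintf("%s vs age (n = %d): r = %.2f, p = %.2f; OLS %s = %.4g x Age + %.4g\n",
              x$field, x$n, x$r, x$p, x$field, x$slope, x$intercept))
  invisible(x)
}

#' Age trend of the out-of-plane dispersion
#'
#' Convenience wrapper for the cohort's headline trend: the OLS regression
#' of `kappa_op` on age (published for this cohort as
#' `kappa_op = 0.0011 x Age + 0.37`).
#'
#' @param records Cohort data frame with `age` and `kappa_op` columns.
#' @return An `age_correlation` object (see [pearson_with_age()]).
#' @export
age_trend_kop <- function(records) pearson_with_age(records, "kappa_op")

#' Cohort summary statistics
#'
#' Mean and sample (n-1) standard deviation of age and of every
#' coefficient-of-determination column present, plus counts by sex.
#'
#' @param records Cohort data frame.
#' @return A list with `age_mean`, `age_sd`, `n`, `sex_counts`, and a data
#'   frame `r2` of mean/SD per R^2 column (columns matching `^r2_`).
#' @export
cohort_summary <- function(records) {
  stopifnot(is.data.frame(records), "age" %in% names(records))
  r2_cols <- grep("^r2_", names(records), value = TRUE)
  r2 <- if (length(r2_cols)) {
    data.frame(column = r2_cols,
               mean = vapply(records[r2_cols], mean, numeric(1),
                             na.rm = TRUE),
               sd = vapply(records[r2_cols], stats::sd, numeric(1),
                           na.rm = TRUE),
               row.names = NULL)
  } else data.frame(column = character(), mean = numeric(), sd = numeric())
  n <- nrow(records)
  list(age_mean = mean(records$age), age_sd = if (n > 1)
    stats::sd(records$age) else NA_real_, n = n,
    sex_counts = if ("sex" %in% names(records)) table(records$sex) else NULL,
    r2 = r2)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Deterministic rounding used when comparing recomputed statistics with
#' printed table values (R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
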