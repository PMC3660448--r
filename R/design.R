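# Study-design stage: covariate adjustment of the agonist phenotypes and
# selection of hyper-/hypo-aggregator extremes within ancestry strata.

.COVARIATES <- c("age", "sex", "diabetes", "hypertension", "bmi", "ldl",
                 "smoking", "fibrinogen")
.PHENOTYPES <- c("pheno_col", "pheno_epi", "pheno_adp")

#' Covariate-adjust one phenotype
#'
#' Ordinary least-squares residuals of a quantitative phenotype on the
#' eight standard covariates (age, sex, diabetes, hypertension, BMI, LDL,
#' smoking, fibrinogen). Rows with any missing value are excluded from the
#' fit (their residual is `NA`) and the exclusion count is reported via
#' `message()`. A rank-deficient design (e.g. a constant covariate) drops
#' the aliased covariate with a warning rather than failing.
#'
#' @param phenotype numeric vector.
#' @param covariates data.frame containing the eight covariate columns,
#'   same row order as `phenotype`.
#' @return numeric residual vector aligned with the input (`NA` where a
#'   row was excluded).
#' @export
adjust_phenotype <- function(phenotype, covariates) {
  miss <- setdiff(.COVARIATES, names(covariates))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  dat <- cbind(.y = phenotype, covariates[.COVARIATES])
  ok <- stats::complete.cases(dat)
  if (sum(!ok) > 0)
    message(sum(!ok), " row(s) excluded from adjustment (missing values)")
  if (sum(ok) <= length(.COVARIATES) + 1)
    stop("too few complete rows to adjust (", sum(ok), ")")
  fit <- stats::lm(.y ~ ., data = dat[ok, , drop = FALSE])
  cf <- stats::coef(fit)
  if (anyNA(cf))
    warning("covariate(s) dropped as aliased: ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  res <- rep(NA_real_, length(phenotype))
  res[ok] <- stats::residuals(fit)
  res
}

#' Covariate-adjust all three agonist phenotypes within strata
#'
#' Fits [adjust_phenotype()] independently per ancestry stratum and per
#' agonist, so adjustment never borrows information across strata.
#'
#' @param cohort cohort data.frame (see [read_cohort()]).
#' @return `cohort` with added residual columns `resid_col`, `resid_epi`,
#'   `resid_adp`.
#' @export
adjust_cohort <- function(cohort) {
  for (ph in .PHENOTYPES)
    cohort[[sub("pheno", "resid", ph)]] <- NA_real_
  for (s in unique(cohort$stratum)) {
    idx <- which(cohort$stratum == s)
    for (ph in .PHENOTYPES) {
      r <- adjust_phenotype(cohort[[ph]][idx],
                            cohort[idx, .COVARIATES, drop = FALSE])
      cohort[[sub("pheno", "resid", ph)]][idx] <- r
    }
  }
  cohort
}

#' Select hyper-/hypo-phenotype extremes within strata
#'
#' A subject is *hyper* when its adjusted residual lies strictly above the
#' stratum's upper quartile for **all three** agonists, *hypo* when
#' strictly below the lower quartile for all three, otherwise
#' *unselected*. Quartiles are empirical quantiles with linear
#' interpolation (`quantile()` type 7); a residual exactly at the quartile
#' is not selected. Strata with fewer than 8 subjects are refused:
#' quartiles are meaningless there.
#'
#' @param cohort adjusted cohort data.frame (from [adjust_cohort()]),
#'   with `resid_col`, `resid_epi`, `resid_adp` columns.
#' @param quartile tail probability, default 0.25.
#' @return `cohort` with a `group` column in
#'   `c("hyper", "hypo", "unselected")` (`NA` residuals are never
#'   selected).
#' @export
select_extremes <- function(cohort, quartile = 0.25) {
  if (quartile <= 0 || quartile >= 0.5)
    stop("'quartile' must lie in (0, 0.5)")
  rc <- sub("pheno", "resid", .PHENOTYPES)
  miss <- setdiff(rc, names(cohort))
  if (length(miss)) stop("cohort not adjusted: missing ",
                         paste(miss, collapse = ", "))
  cohort$group <- "unselected"
  for (s in unique(cohort$stratum)) {
    idx <- which(cohort$stratum == s)
    if (length(idx) < 8)
      stop("stratum '", s, "' has ", length(idx),
           " subjects; at least 8 required for quartile selection")
    hyper <- rep(TRUE, length(idx)); hypo <- rep(TRUE, length(idx))
    for (col in rc) {
      r <- cohort[[col]][idx]
      q <- stats::quantile(r, c(quartile, 1 - quartile), na.rm = TRUE,
                           names = FALSE)
      hyper <- hyper & !is.na(r) & r > q[2]
      hypo  <- hypo  & !is.na(r) & r < q[1]
    }
    cohort$group[idx[hyper]] <- "hyper"
    cohort$group[idx[hypo]] <- "hypo"
  }
  cohort
}
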