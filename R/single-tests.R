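# Per-variant association tests, stratified on MAF: two-sided Fisher
# exact on allele-count 2x2 tables for rare variants, additive logistic
# regression for common ones.

#' Two-sided Fisher exact test on a 2x2 allele-count table
#'
#' Conditional exact test with both margins fixed. The two-sided p-value
#' follows the probability-mass rule: the sum of hypergeometric point
#' probabilities of every table (with the observed margins) whose
#' probability does not exceed that of the observed table (a relative
#' tolerance of 1e-7 guards floating-point ties, as in standard
#' implementations). A table whose minor-allele margin is zero is
#' monomorphic and returns p = 1 by convention.
#'
#' @param minor_hyper,minor_hypo minor-allele counts in the hyper (case)
#'   and hypo (control) groups.
#' @param major_hyper,major_hypo major-allele counts.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(1, 0, 47, 54)   # 48/102
#' @export
fisher_exact_two_sided <- function(minor_hyper, minor_hypo,
                                   major_hyper, major_hypo) {
  cnt <- c(minor_hyper, minor_hypo, major_hyper, major_hypo)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  m <- minor_hyper + minor_hypo            # minor-allele margin
  n_hyper <- minor_hyper + major_hyper     # alleles in hyper group
  n_hypo <- minor_hypo + major_hypo
  if (n_hyper == 0 || n_hypo == 0)
    stop("both groups need a positive allele margin")
  if (m == 0) return(1)
  support <- max(0, m - n_hypo):min(m, n_hyper)
  dens <- stats::dhyper(support, n_hyper, n_hypo, m)
  obs <- stats::dhyper(minor_hyper, n_hyper, n_hypo, m)
  keep <- dens <= obs * (1 + 1e-7)
  if (all(keep)) return(1)           # whole support: exactly 1
  min(sum(dens[keep]), 1)
}

#' Build an allele-count 2x2 table from dosages
#'
#' Complete-case allele counts: missing calls contribute to neither
#' margin.
#'
#' @param dosage minor-allele dosage vector (0/1/2, `NA` missing).
#' @param is_hyper logical vector, `TRUE` for hyper (case) subjects.
#' @return named vector `minor_hyper`, `minor_hypo`, `major_hyper`,
#'   `major_hypo`.
#' @export
allele_table <- function(dosage, is_hyper) {
  stopifnot(length(dosage) == length(is_hyper))
  ok <- !is.na(dosage)
  mh <- sum(dosage[ok & is_hyper]); mo <- sum(dosage[ok & !is_hyper])
  c(minor_hyper = mh, minor_hypo = mo,
    major_hyper = 2 * sum(ok & is_hyper) - mh,
    major_hypo = 2 * sum(ok & !is_hyper) - mo)
}

#' Additive logistic regression for a common variant
#'
#' Maximum-likelihood fit of group (hyper = 1) on minor-allele dosage
#' (0, 1, 2) with intercept; the reported p-value is the Wald test of the
#' dosage coefficient. Complete separation or non-convergence flags the
#' result and leaves the p-value missing rather than fabricating one.
#'
#' @param dosage minor-allele dosage vector (`NA` dropped complete-case).
#' @param is_hyper logical case indicator.
#' @return list with `beta`, `se`, `p_value`, `converged`.
#' @export
logistic_additive <- function(dosage, is_hyper) {
  ok <- !is.na(dosage)
  d <- dosage[ok]; y <- as.integer(is_hyper[ok])
  if (length(unique(d)) < 2) stop("dosage has no variation")
  if (all(y == 1) || all(y == 0)) stop("both groups must be non-empty")
  fit <- withCallingHandlers(
    stats::glm(y ~ d, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  sm <- summary(fit)$coefficients
  beta <- sm["d", "Estimate"]; se <- sm["d", "Std. Error"]
  # separation / non-convergence shows up as an exploding estimate or
  # standard error; never report a Wald p computed from those
  sep <- !fit$converged || abs(beta) > 10 || se > 100
  list(beta = beta, se = se,
       p_value = if (sep) NA_real_ else sm["d", "Pr(>|z|)"],
       converged = !sep)
}

#' Single-variant association scan
#'
#' For every variant, within one ancestry stratum: compute the
#' complete-case MAF among the selected extremes, then dispatch on rarity
#' — Fisher exact on the allele-count table when the variant is rare
#' (MAF < `maf_threshold`), additive logistic regression when common.
#' Variants monomorphic in the stratum are reported with method `"none"`
#' and a missing p-value (no test), matching the convention of printing
#' `NA` rather than p = 1.
#'
#' @param gm a [genotype_matrix].
#' @param cohort data.frame with `subject_id`, `stratum` and `group`
#'   columns; only rows with group `hyper`/`hypo` are used.
#' @param stratum ancestry stratum to analyse.
#' @param maf_threshold rarity boundary, default 0.05.
#' @return data.frame with one row per variant: `variant_id`, `stratum`,
#'   `maf`, `rarity`, `method`, `statistic` (logistic beta), `p_value`,
#'   `direction` (`+` minor allele enriched in hyper, `-` in hypo, `0`
#'   balanced), `n` subjects used.
#' @export
single_variant_scan <- function(gm, cohort, stratum, maf_threshold = 0.05) {
  sel <- cohort[cohort$stratum == stratum &
                  cohort$group %in% c("hyper", "hypo"), ]
  if (nrow(sel) == 0) stop("no selected subjects in stratum '", stratum, "'")
  d <- minor_dosage(gm, stratum, subjects = sel$subject_id)
  is_hyper <- sel$group == "hyper"
  if (all(is_hyper) || !any(is_hyper))
    stop("both hyper and hypo groups required")

  res <- lapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    ok <- !is.na(x)
    n <- sum(ok)
    row <- data.frame(variant_id = colnames(d)[j], stratum = stratum,
                      maf = NA_real_, rarity = NA_character_,
                      method = "none", statistic = NA_real_,
                      p_value = NA_real_, direction = "0", n = n,
                      stringsAsFactors = FALSE)
    if (n == 0) return(row)
    row$maf <- compute_maf(x)
    if (row$maf == 0) return(row)                 # monomorphic: no test
    row$rarity <- classify_rarity(row$maf, maf_threshold)
    tab <- allele_table(x, is_hyper)
    f_hyper <- tab["minor_hyper"] / (tab["minor_hyper"] + tab["major_hyper"])
    f_hypo <- tab["minor_hypo"] / (tab["minor_hypo"] + tab["major_hypo"])
    if (row$rarity == "rare") {
      row$method <- "fisher"
      row$p_value <- fisher_exact_two_sided(tab["minor_hyper"],
                                            tab["minor_hypo"],
                                            tab["major_hyper"],
                                            tab["major_hypo"])
      row$direction <- if (f_hyper > f_hypo) "+"
                       else if (f_hyper < f_hypo) "-" else "0"
    } else {
      row$method <- "logistic"
      lt <- logistic_additive(x, is_hyper)
      row$statistic <- lt$beta
      row$p_value <- lt$p_value
      row$direction <- if (lt$beta > 0) "+" else if (lt$beta < 0) "-" else "0"
    }
    row
  })
  do.call(rbind, res)
}

#' Signed -log10 p-value
#'
#' Magnitude `-log10(p)` signed by effect direction: `+` for minor
#' alleles/burdens enriched in the hyper group (risk), `-` for
#' enrichment in the hypo group (protective); a null direction maps to
#' `+`.
#'
#' @param p_value p-value in (0, 1].
#' @param direction `"+"`, `"-"` or `"0"`.
#' @return signed numeric.
#' @export
signed_neglog10 <- function(p_value, direction) {
  if (any(p_value <= 0 | p_value > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  sgn <- ifelse(direction == "-", -1, 1)
  sgn * -log10(p_value)
}

#' Bonferroni significance threshold
#'
#' `alpha / m` for `m` tests; the exact value is retained and a display
#' value rounded to one significant figure is attached, matching the
#' convention of quoting e.g. 0.05/235 as 0.0002.
#'
#' @param alpha family-wise error rate, default 0.05.
#' @param m number of tests.
#' @return list with `threshold` (exact) and `display` (1 s.f.).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("'m' must be at least 1")
  th <- alpha / m
  list(threshold = th, display = signif(th, 1))
}
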