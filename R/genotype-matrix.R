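#' Genotype matrix container
#'
#' Holds diploid genotype dosages for a cohort: a subjects x variants
#' integer matrix of alternate-allele counts (0, 1, 2; `NA` = missing call),
#' plus per-subject ancestry stratum labels and a per-stratum flag saying
#' whether the alternate allele is the *major* allele in that stratum (in
#' which case dosages are flipped on access so analyses always count the
#' minor allele).
#'
#' @param dosage integer matrix, subjects x variants, alternate-allele
#'   counts in \{0, 1, 2\} with `NA` for missing calls. Must have rownames
#'   (subject ids) and colnames (variant ids).
#' @param stratum character vector of ancestry stratum labels, one per
#'   subject (named by subject id, or in row order).
#' @return An object of class `genotype_matrix`.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, 0L, 0L, 1L), nrow = 3,
#'             dimnames = list(paste0("S", 1:3), c("v1", "v2")))
#' gm <- genotype_matrix(d, stratum = c("EA", "EA", "AA"))
#' minor_dosage(gm, "EA")
#' @export
genotype_matrix <- function(dosage, stratum) {
  if (!is.matrix(dosage)) stop("'dosage' must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("'dosage' needs subject rownames and variant colnames")
  storage.mode(dosage) <- "integer"
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (!is.null(names(stratum))) {
    if (!all(rownames(dosage) %in% names(stratum)))
      stop("subjects missing from stratum map: ",
           paste(setdiff(rownames(dosage), names(stratum)), collapse = ", "))
    stratum <- stratum[rownames(dosage)]
  }
  if (length(stratum) != nrow(dosage))
    stop("one stratum label required per subject")
  stratum <- as.character(stratum)
  names(stratum) <- rownames(dosage)

  # flip flag per variant x stratum: TRUE when alt is the major allele there
  strata <- sort(unique(stratum))
  flipped <- vapply(strata, function(s) {
    sub <- dosage[stratum == s, , drop = FALSE]
    af <- colMeans(sub, na.rm = TRUE) / 2   # alt-allele frequency
    af[is.nan(af)] <- 0
    af > 0.5
  }, logical(ncol(dosage)))
  if (is.null(dim(flipped)))
    flipped <- matrix(flipped, nrow = ncol(dosage),
                      dimnames = list(colnames(dosage), strata))

  structure(list(dosage = dosage, stratum = stratum, flipped = flipped),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "subjects x",
      ncol(x$dosage), "variants\n")
  tab <- table(x$stratum)
  cat("strata:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subject ids, variant ids
#' @param gm a `genotype_matrix`
#' @export
subject_ids <- function(gm) rownames(gm$dosage)

#' @rdname subject_ids
#' @export
variant_ids <- function(gm) colnames(gm$dosage)

#' Minor-allele dosage within a stratum
#'
#' Returns the subjects x variants dosage matrix restricted to one ancestry
#' stratum (or all subjects), recoded so every variant counts its *minor*
#' allele in that stratum: columns whose alternate-allele frequency exceeds
#' 0.5 are flipped (dosage -> 2 - dosage). Missing calls stay `NA`.
#'
#' @param gm a `genotype_matrix`
#' @param stratum stratum label, or `NULL` for all subjects (flip then
#'   decided on the pooled frequency).
#' @param subjects optional character vector restricting rows further
#'   (e.g. the selected extremes).
#' @return integer matrix of minor-allele dosages.
#' @export
minor_dosage <- function(gm, stratum = NULL, subjects = NULL) {
  if (is.null(stratum)) {
    d <- gm$dosage
    af <- colMeans(d, na.rm = TRUE) / 2
    af[is.nan(af)] <- 0
    flip <- af > 0.5
  } else {
    if (!stratum %in% gm$stratum)
      stop("no subjects in stratum '", stratum, "'")
    d <- gm$dosage[gm$stratum == stratum, , drop = FALSE]
    flip <- gm$flipped[, stratum]
  }
  if (any(flip)) d[, flip] <- 2L - d[, flip, drop = FALSE]
  if (!is.null(subjects)) {
    miss <- setdiff(subjects, rownames(d))
    if (length(miss)) stop("subjects not in matrix/stratum: ",
                           paste(miss, collapse = ", "))
    d <- d[subjects, , drop = FALSE]
  }
  d
}

#' Minor allele frequency of a dosage vector
#'
#' Complete-case MAF: missing calls are dropped from both numerator and
#' denominator. The frequency is folded so the result never exceeds 0.5,
#' regardless of which allele the vector counts.
#'
#' @param dosage integer vector of allele counts (0/1/2), `NA` = missing.
#' @return frequency in \[0, 0.5\].
#' @examples
#' compute_maf(c(1L, rep(0L, 52)))  # 1/106
#' @export
compute_maf <- function(dosage) {
  ok <- !is.na(dosage)
  if (!any(ok)) stop("undefined frequency: all calls missing")
  f <- sum(dosage[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Classify a variant as rare or common
#'
#' A variant is rare when its MAF is strictly below the threshold and
#' common otherwise (so a MAF exactly at the threshold is common); the
#' partition is exhaustive and exclusive.
#'
#' @param maf minor allele frequency (vectorised), each in \[0, 0.5\].
#' @param threshold rarity boundary, default 0.05.
#' @return character vector, `"rare"` or `"common"`.
#' @export
classify_rarity <- function(maf, threshold = 0.05) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]")
  ifelse(maf < threshold, "rare", "common")
}
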