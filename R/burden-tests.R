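# Multi-variant burden tests comparing hyper- vs hypo-phenotype groups:
# CMC carrier collapsing with a 1-df chi-square, the Madsen-Browning
# weighted-sum rank test with a permutation null, and the C-alpha
# dispersion test. Within burden sets a missing genotype call counts as
# dosage 0 (non-carrier), so per-subject scores and rank sums stay
# comparable across subjects with different call rates.

#' Burden-test configuration
#'
#' @param maf_threshold rarity boundary for `rare_only` filtering.
#' @param n_permutations permutation count B for the weighted-sum (and
#'   C-alpha permutation) null; default 2000. The permutation p-value is
#'   `(k + 1) / (B + 1)`, so its minimum attainable value is `1/(B + 1)`.
#' @param rarity_filter `"rare_only"` or `"all"`.
#' @param rng_seed optional integer; when given, the permutation stream is
#'   seeded for exact reproducibility.
#' @return list of class `burden_config`.
#' @export
burden_config <- function(maf_threshold = 0.05, n_permutations = 2000,
                          rarity_filter = c("rare_only", "all"),
                          rng_seed = NULL) {
  if (n_permutations < 1) stop("'n_permutations' must be >= 1")
  list(maf_threshold = maf_threshold,
       n_permutations = as.integer(n_permutations),
       rarity_filter = match.arg(rarity_filter),
       rng_seed = rng_seed)
}

#' Collapse a rare-variant set to a per-subject carrier indicator
#'
#' Indicator is 1 iff the subject carries at least one minor allele at at
#' least one variant of the set; a missing call is treated as non-carrier
#' at that variant.
#'
#' @param dosage subjects x variants minor-allele dosage matrix (`NA`
#'   missing).
#' @return integer 0/1 vector, one per subject.
#' @export
collapse_carriers <- function(dosage) {
  if (NCOL(dosage) == 0) stop("variant set is empty")
  d <- as.matrix(dosage)
  d[is.na(d)] <- 0L
  as.integer(rowSums(d) > 0)
}

.new_burden_result <- function(method, statistic, p_value, direction,
                               n_variants, n_subjects, extra = list()) {
  structure(c(list(method = method, statistic = statistic,
                   p_value = p_value, direction = direction,
                   n_variants = n_variants, n_subjects = n_subjects),
              extra),
            class = "burden_test")
}

#' @export
print.burden_test <- function(x, ...) {
  cat("\n\t", switch(x$method,
                     cmc = "CMC carrier-collapsing test",
                     ws = "Weighted-sum (Madsen-Browning) burden test",
                     calpha = "C-alpha dispersion test"), "\n\n")
  cat(sprintf("variants = %d, subjects = %d\n", x$n_variants, x$n_subjects))
  if (!is.null(x$statistic) && !is.na(x$statistic))
    cat(sprintf("statistic = %.4g\n", x$statistic))
  cat(sprintf("p-value = %s, direction = %s\n",
              format.pval(x$p_value, digits = 4), x$direction))
  if (!is.null(x$p_analytic))
    cat(sprintf("analytic (normal approximation) p = %s\n",
                format.pval(x$p_analytic, digits = 4)))
  invisible(x)
}

#' CMC collapsing test
#'
#' Collapses the rare-variant set to a carrier indicator
#' ([collapse_carriers()]) and tests carrier status against group with a
#' 1-df Pearson chi-square (no continuity correction). When any expected
#' cell count falls below 5 the chi-square approximation is unreliable and
#' the test falls back to the two-sided Fisher exact test on the same
#' carrier x group table.
#'
#' @param dosage subjects x variants minor-allele dosage matrix of the
#'   rare-variant set (`NA` missing).
#' @param is_hyper logical case indicator per subject.
#' @param config a [burden_config()] (only `maf_threshold` is consulted
#'   here; filtering is the caller's job via [burden_suite()]).
#' @return a `burden_test` result.
#' @export
cmc_test <- function(dosage, is_hyper, config = burden_config()) {
  if (NCOL(dosage) == 0)
    stop("no rare variants in set: CMC refuses to run")
  carrier <- collapse_carriers(dosage)
  tab <- rbind(carrier = c(sum(carrier[is_hyper]), sum(carrier[!is_hyper])),
               non = c(sum(!carrier[is_hyper]), sum(!carrier[!is_hyper])))
  colnames(tab) <- c("hyper", "hypo")
  rate_hyper <- tab[1, 1] / sum(is_hyper)
  rate_hypo <- tab[1, 2] / sum(!is_hyper)
  dir <- if (rate_hyper > rate_hypo) "+"
         else if (rate_hyper < rate_hypo) "-" else "0"
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts < 5)) {
    p <- fisher_exact_two_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    return(.new_burden_result("cmc", NA_real_, p, dir, NCOL(dosage),
                              length(is_hyper),
                              list(fallback = "fisher", table = tab)))
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  .new_burden_result("cmc", unname(ct$statistic), ct$p.value, dir,
                     NCOL(dosage), length(is_hyper),
                     list(fallback = "none", table = tab))
}

# Weighted-sum rank statistic (Madsen-Browning): controls (hypo) estimate
# per-variant frequencies with a +1 pseudocount, weights are the inverse
# binomial sd, and the statistic is the rank sum of case genetic scores.
# Recomputed in full for every permuted labelling, as in the original
# construction.
.ws_stat <- function(d0, okm, is_hyper) {
  ctrl <- !is_hyper
  m_ctrl <- colSums(d0[ctrl, , drop = FALSE])
  n_ctrl <- colSums(okm[ctrl, , drop = FALSE])
  q <- (m_ctrl + 1) / (2 * n_ctrl + 2)
  n_all <- colSums(okm)
  w <- sqrt(n_all * q * (1 - q))
  gamma <- as.vector(d0 %*% (1 / w))
  sum(rank(gamma)[is_hyper])
}

#' Weighted-sum (Madsen-Browning) burden test
#'
#' Per-variant minor-allele frequencies are estimated in the hypo
#' (control) group with a +1 pseudocount, `q_j = (m_j + 1)/(2 n_j + 2)`;
#' each variant gets weight `w_j = sqrt(n_j q_j (1 - q_j))` (`n_j` =
#' subjects genotyped at j) and each subject the score
#' `gamma_i = sum_j dosage_ij / w_j`. The statistic is the rank sum
#' (midranks on ties) of the hyper subjects' scores among all subjects.
#' The p-value is the one-sided permutation p `(k + 1)/(B + 1)` where `k`
#' counts label permutations whose rank sum is at least the observed one;
#' frequencies, weights and scores are re-estimated for every permuted
#' labelling. A standardized `z = (x - mean_perm)/sd_perm` is also
#' reported.
#'
#' @inheritParams cmc_test
#' @param config a [burden_config()]; `n_permutations` is B.
#' @return a `burden_test` result with extra fields `z`, `q`, `weights`.
#' @export
ws_test <- function(dosage, is_hyper, config = burden_config()) {
  if (NCOL(dosage) == 0) stop("variant set is empty")
  if (all(is_hyper) || !any(is_hyper))
    stop("both groups must be non-empty")
  B <- config$n_permutations
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  d <- as.matrix(dosage)
  okm <- !is.na(d)
  d0 <- d; d0[!okm] <- 0L
  x <- .ws_stat(d0, okm, is_hyper)
  n <- length(is_hyper)
  xperm <- vapply(seq_len(B), function(b)
    .ws_stat(d0, okm, sample(is_hyper)), numeric(1))
  sdp <- stats::sd(xperm)
  # observed workspace quantities, kept for auditability
  q <- (colSums(d0[!is_hyper, , drop = FALSE]) + 1) /
    (2 * colSums(okm[!is_hyper, , drop = FALSE]) + 2)
  w <- sqrt(colSums(okm) * q * (1 - q))
  gamma <- as.vector(d0 %*% (1 / w))
  p <- if (length(unique(gamma)) == 1) 1 else (sum(xperm >= x) + 1) / (B + 1)
  mu <- mean(xperm)
  dir <- if (x > mu) "+" else if (x < mu) "-" else "0"
  .new_burden_result("ws", x, p, dir, ncol(d), n,
                     list(z = if (isTRUE(sdp > 0)) (x - mu) / sdp else NA_real_,
                          q = q, weights = w, scores = gamma,
                          n_permutations = B))
}

#' C-alpha dispersion test
#'
#' Tests whether the case/control split of minor-allele copies is
#' over-dispersed relative to a binomial with case fraction
#' `p0 = n_hyper / n_subjects`, without aggregating variants — so it keeps
#' power when variant effects point in opposite directions. With `n_i`
#' total minor copies at variant i and `y_i` of them in cases,
#' `T = sum_i [(y_i - n_i p0)^2 - n_i p0 (1 - p0)]` and its null variance
#' `c = sum_i sum_u dbinom(u, n_i, p0) [(u - n_i p0)^2 - n_i p0 (1-p0)]^2`
#' (singleton variants contribute nothing to `c`). The analytic one-sided
#' upper-tail p-value comes from `z = T / sqrt(c)`; a permutation p-value
#' under label permutation is always reported alongside (and is the only p
#' when `c = 0`).
#'
#' @inheritParams ws_test
#' @return a `burden_test` result; `p_value` is the permutation p,
#'   `p_analytic` the normal-approximation p, `z` the z-score.
#' @export
c_alpha_test <- function(dosage, is_hyper, config = burden_config()) {
  d <- as.matrix(dosage)
  d[is.na(d)] <- 0L
  n_i <- colSums(d)
  keep <- n_i >= 1
  if (!any(keep)) stop("no variant with an observed minor allele")
  d <- d[, keep, drop = FALSE]
  n_i <- n_i[keep]
  p0 <- mean(is_hyper)
  if (p0 <= 0 || p0 >= 1) stop("both groups must be non-empty")

  t_stat <- function(lab) {
    y <- colSums(d[lab, , drop = FALSE])
    sum((y - n_i * p0)^2 - n_i * p0 * (1 - p0))
  }
  T_obs <- t_stat(is_hyper)
  cvar <- sum(vapply(n_i, function(ni) {
    u <- 0:ni
    sum(stats::dbinom(u, ni, p0) *
          ((u - ni * p0)^2 - ni * p0 * (1 - p0))^2)
  }, numeric(1)))
  z <- if (cvar > 0) T_obs / sqrt(cvar) else NA_real_
  p_an <- if (cvar > 0) stats::pnorm(z, lower.tail = FALSE) else NA_real_

  B <- config$n_permutations
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  Tperm <- vapply(seq_len(B), function(b) t_stat(sample(is_hyper)),
                  numeric(1))
  p_perm <- (sum(Tperm >= T_obs) + 1) / (B + 1)
  dir <- if (T_obs > 0) "+" else if (T_obs < 0) "-" else "0"
  .new_burden_result("calpha", T_obs, p_perm, dir, ncol(d),
                     length(is_hyper),
                     list(z = z, p_analytic = p_an, variance = cvar,
                          n_permutations = B))
}

#' Burden-test grid over functional classes and rarity filters
#'
#' Runs the Table-style burden grid within one ancestry stratum:
#' functional-class sets (default missense & synonymous combined,
#' missense only, synonymous only) crossed with \{CMC on rare variants,
#' WS on rare variants, WS on all variants\}. Set membership and rarity
#' are decided from the complete-case MAF among the selected extremes of
#' the stratum; variants monomorphic there do not count toward a cell's
#' `n`. An empty cell is reported as "no test" with a missing p-value.
#'
#' @param gm a [genotype_matrix].
#' @param annotations annotation data.frame, rows aligned with
#'   `variant_ids(gm)`.
#' @param cohort selected cohort data.frame (`subject_id`, `stratum`,
#'   `group`).
#' @param stratum ancestry stratum to analyse.
#' @param class_sets named list of functional-class vectors.
#' @param config a [burden_config()]; each cell reseeds the permutation
#'   stream from `rng_seed` plus a cell offset when a seed is given.
#' @return data.frame with one row per cell: `stratum`, `classes`,
#'   `method`, `rarity_filter`, `n_variants`, `statistic`, `p_value`,
#'   `direction`, `note`.
#' @export
burden_suite <- function(gm, annotations, cohort, stratum,
                         class_sets = list(
                           missense_synonymous = c("missense", "synonymous"),
                           missense = "missense",
                           synonymous = "synonymous"),
                         config = burden_config()) {
  sel <- cohort[cohort$stratum == stratum &
                  cohort$group %in% c("hyper", "hypo"), ]
  d_all <- minor_dosage(gm, stratum, subjects = sel$subject_id)
  is_hyper <- sel$group == "hyper"
  maf <- apply(d_all, 2, function(x) {
    if (all(is.na(x))) NA_real_ else compute_maf(x)
  })
  rare <- !is.na(maf) & maf > 0 & maf < config$maf_threshold
  seen <- !is.na(maf) & maf > 0

  cells <- expand.grid(set = names(class_sets),
                       spec = c("cmc:rare_only", "ws:rare_only", "ws:all"),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    set_name <- cells$set[i]
    method <- sub(":.*", "", cells$spec[i])
    filt <- sub(".*:", "", cells$spec[i])
    in_class <- annotations$func_class %in% class_sets[[set_name]]
    keep <- in_class & (if (filt == "rare_only") rare else seen)
    row <- data.frame(stratum = stratum, classes = set_name,
                      method = method, rarity_filter = filt,
                      n_variants = sum(keep), statistic = NA_real_,
                      p_value = NA_real_, direction = "0", note = "",
                      stringsAsFactors = FALSE)
    if (sum(keep) == 0) {
      row$note <- "no test"
      return(row)
    }
    cfg <- config
    if (!is.null(cfg$rng_seed)) cfg$rng_seed <- cfg$rng_seed + i
    d <- d_all[, keep, drop = FALSE]
    r <- if (method == "cmc") cmc_test(d, is_hyper, cfg)
         else ws_test(d, is_hyper, cfg)
    row$statistic <- if (is.null(r$statistic)) NA_real_ else r$statistic
    row$p_value <- r$p_value
    row$direction <- r$direction
    if (identical(r$fallback, "fisher")) row$note <- "fisher fallback"
    row
  })
  do.call(rbind, out)
}
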