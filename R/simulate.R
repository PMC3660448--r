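# Synthetic cohort generator. Emulates the statistical structure the
# pipeline assumes -- a two-stratum cohort with stratum-specific
# rare-variant loads, blockwise LD, one common causal intronic variant
# plus an exonic (synonymous) burden effect, three correlated agonist
# phenotypes with covariate effects, and missing genotype calls -- so
# every analysis stage can be exercised without access-restricted data.

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed for:
#' two ancestry strata with about 190 subjects each (so the all-three-
#' agonist quartile rule selects roughly 104 extremes), a 235-variant
#' panel with 30 exonic variants (16 missense, 14 synonymous), target
#' rare-variant counts of 108 (AA) vs 45 (EA) at MAF < 5%, mean genotype
#' missingness 8.6%, inter-agonist phenotype correlation 0.8, one common
#' intronic causal variant explaining 39% (AA) / 16% (EA) of latent
#' phenotype variance, and a synonymous burden effect acting in the EA
#' stratum only.
#'
#' @param n_subjects named integer vector, subjects per stratum.
#' @param n_variants panel size.
#' @param class_counts named integer vector of functional-class counts
#'   summing to `n_variants`.
#' @param rare_freq,common_freq frequency ranges for rare and common
#'   variants in the haplotype pool.
#' @param ld_block_size,ld_block_r contiguous LD block size and latent
#'   (Gaussian copula) within-block correlation.
#' @param var_explained_intronic named vector: fraction of latent
#'   phenotype variance explained by the designated common intronic
#'   variant, per stratum.
#' @param beta_burden named vector: per-minor-allele effect of the
#'   designated synonymous burden set on the latent phenotype, per
#'   stratum.
#' @param pheno_cor inter-agonist phenotype correlation.
#' @param pheno_mean,pheno_sd location/scale mapping the latent score to
#'   percent aggregation (clipped to \[0, 100\]).
#' @param missing_rate genotype missingness rate (MCAR).
#' @param n_novel number of novel (no-rsID) variants.
#' @param quartile selection tail used downstream.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = c(AA = 190, EA = 195),
                       n_variants = 235,
                       class_counts = c(missense = 16, synonymous = 14,
                                        utr3 = 8, utr5 = 5,
                                        intergenic = 20, intronic = 172),
                       rare_freq = c(0.004, 0.040),
                       common_freq = c(0.07, 0.45),
                       ld_block_size = 5,
                       ld_block_r = 0.5,
                       var_explained_intronic = c(AA = 0.39, EA = 0.16),
                       beta_burden = c(AA = 0, EA = 0.25),
                       pheno_cor = 0.8,
                       pheno_mean = 50, pheno_sd = 15,
                       missing_rate = 0.086,
                       n_novel = 61,
                       quartile = 0.25) {
  stopifnot(sum(class_counts) == n_variants,
            missing_rate >= 0, missing_rate < 1,
            pheno_cor >= 0, pheno_cor <= 1,
            ld_block_r >= 0, ld_block_r <= 1)
  if (any(var_explained_intronic + 0 > pheno_cor))
    stop("intronic variance target cannot exceed the shared phenotype ",
         "correlation")
  structure(as.list(environment()), class = "sim_config")
}

# Per-variant, per-stratum pool frequencies. Categories: shared_common,
# shared_rare, rare private to one stratum (frequency 0 in the other).
# Exonic classes get a fixed category split so the visible exonic panel
# per stratum resembles a targeted resequencing study (EA sees 7 missense
# + 8 synonymous, AA sees more); noncoding counts are chosen so the
# stratum rare-variant totals hit 108 (AA) vs 45 (EA).
.assign_frequencies <- function(config, func_class) {
  n <- length(func_class)
  strata <- names(config$n_subjects)
  cat_of <- character(n)
  split_for <- function(cls) switch(cls,
    synonymous = c(sc = 7, sr = 1, ar = 6, er = 0),
    missense = c(sc = 3, sr = 2, ar = 9, er = 2),
    c(sc = NA, sr = NA, ar = NA, er = NA))
  for (cls in c("missense", "synonymous")) {
    idx <- which(func_class == cls)
    sp <- split_for(cls)
    stopifnot(length(idx) == sum(sp))
    cat_of[idx] <- sample(rep(c("shared_common", "shared_rare",
                                "aa_rare", "ea_rare"), sp))
  }
  nc <- which(!func_class %in% c("missense", "synonymous"))
  sp_nc <- c(shared_common = length(nc) - 110, shared_rare = 20,
             aa_rare = 70, ea_rare = 20)
  stopifnot(all(sp_nc >= 0))
  cat_of[nc] <- sample(rep(names(sp_nc), sp_nc))

  draw <- function(range, k) stats::runif(k, range[1], range[2])
  jitter_freq <- function(f, lo, hi)
    pmin(pmax(f * exp(stats::rnorm(length(f), 0, 0.15)), lo), hi)
  freq <- matrix(0, n, 2, dimnames = list(NULL, c("AA", "EA")))
  for (cat in unique(cat_of)) {
    idx <- which(cat_of == cat)
    if (cat == "shared_common") {
      base <- draw(config$common_freq, length(idx))
      freq[idx, "AA"] <- jitter_freq(base, 0.06, 0.48)
      freq[idx, "EA"] <- jitter_freq(base, 0.06, 0.48)
    } else if (cat == "shared_rare") {
      base <- draw(config$rare_freq, length(idx))
      freq[idx, "AA"] <- jitter_freq(base, 0.002, 0.045)
      freq[idx, "EA"] <- jitter_freq(base, 0.002, 0.045)
    } else if (cat == "aa_rare") {
      freq[idx, "AA"] <- draw(config$rare_freq, length(idx))
    } else {
      freq[idx, "EA"] <- draw(config$rare_freq, length(idx))
    }
  }
  list(freq = freq, category = cat_of)
}

#' Generate the per-stratum haplotype pools
#'
#' Haplotypes are built blockwise with a Gaussian copula: within each
#' contiguous block of `ld_block_size` variants a shared latent factor
#' with loading `sqrt(ld_block_r)` induces positive LD, and each variant's
#' allele is the latent value thresholded at its target pool frequency;
#' blocks are mutually independent. A within-block target correlation of
#' 1 therefore reproduces duplicated columns only when the block's
#' frequencies agree; if they differ the achievable r-squared is capped by
#' the frequency mismatch and a warning is raised.
#'
#' @param config a [sim_config()].
#' @param freq variants x strata matrix of target pool frequencies (from
#'   the internal assignment; exposed for testing).
#' @return named list, one `2 * n_subjects` x `n_variants` 0/1 haplotype
#'   matrix per stratum.
#' @export
generate_haplotype_pool <- function(config, freq) {
  n_var <- nrow(freq)
  blocks <- split(seq_len(n_var),
                  ceiling(seq_len(n_var) / config$ld_block_size))
  rho <- config$ld_block_r
  if (rho == 1 &&
      any(vapply(blocks, function(blk) {
        any(vapply(colnames(freq), function(s) {
          f <- freq[blk, s]
          length(unique(f[f > 0])) > 1
        }, logical(1)))
      }, logical(1))))
    warning("within-block r2 target 1 infeasible for unequal ",
            "frequencies; capped at the feasible maximum")
  pools <- lapply(names(config$n_subjects), function(s) {
    H <- 2 * config$n_subjects[[s]]
    hap <- matrix(0L, H, n_var)
    for (blk in blocks) {
      latent_common <- stats::rnorm(H)
      for (j in blk) {
        if (freq[j, s] <= 0) next
        lat <- sqrt(rho) * latent_common +
          sqrt(1 - rho) * stats::rnorm(H)
        hap[, j] <- as.integer(lat < stats::qnorm(freq[j, s]))
      }
    }
    hap
  })
  names(pools) <- names(config$n_subjects)
  pools
}

#' Generate a full synthetic cohort
#'
#' Draws per-stratum haplotype pools, pairs haplotypes into diploid
#' genotypes, builds the annotation panel (positions in a ~29 kb target
#' region, functional classes, novelty flags, rsIDs), and simulates the
#' three agonist phenotypes from a latent aggregation score
#' `L = beta_intronic * G_intronic + beta_burden * sum(burden dosages) +
#' shared noise`, with per-agonist unique noise sized so the inter-agonist
#' correlation hits `pheno_cor`, plus additive covariate effects; percent
#' phenotypes are `pheno_mean + pheno_sd * score` clipped to \[0, 100\].
#' Covariates are drawn from plausible adult ranges (age 52 +/- 13 etc.).
#' Missingness is applied MCAR at `missing_rate` via
#' [apply_missingness()].
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed; the run is fully reproducible given the
#'   seed.
#' @return list with `gm` (a [genotype_matrix]), `cohort` (phenotype/
#'   covariate data.frame), `annotations` (with `causal_intronic` and
#'   `burden_set` flag columns), and `freq` (the target pool
#'   frequencies).
#' @export
generate_cohort <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  n_var <- config$n_variants
  strata <- names(config$n_subjects)

  # exonic variants occupy one contiguous gene-body stretch so the
  # coding panel can show blockwise LD; noncoding classes are shuffled
  # over the remaining positions
  n_exonic <- config$class_counts[["missense"]] +
    config$class_counts[["synonymous"]]
  ex_start <- sample.int(n_var - n_exonic + 1, 1)
  ex_idx <- ex_start:(ex_start + n_exonic - 1)
  func_class <- character(n_var)
  func_class[ex_idx] <- sample(rep(c("missense", "synonymous"),
                                   c(config$class_counts[["missense"]],
                                     config$class_counts[["synonymous"]])))
  nc_counts <- config$class_counts[
    setdiff(names(config$class_counts), c("missense", "synonymous"))]
  func_class[-ex_idx] <- sample(rep(names(nc_counts), nc_counts))
  fa <- .assign_frequencies(config, func_class)
  freq <- fa$freq

  # designated causal variants: one shared-common intronic variant, and
  # the synonymous variants visible in EA as the burden set
  intronic_common <- which(func_class == "intronic" &
                             fa$category == "shared_common")
  causal_idx <- sample(intronic_common, 1)
  freq[causal_idx, ] <- c(AA = 0.35, EA = 0.40)
  burden_set <- which(func_class == "synonymous" & freq[, "EA"] > 0)

  pos <- sort(sample(156863190:156892394, n_var))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "x")
  rare_any <- freq[, "AA"] < 0.05 | freq[, "EA"] < 0.05
  novel <- rep(FALSE, n_var)
  novel[sample(which(rare_any), config$n_novel)] <- TRUE
  rsid <- ifelse(novel, "-",
                 paste0("rs", sample.int(89000000, n_var) + 1000000L))
  annotations <- data.frame(
    chrom = "1", pos = pos, rsid = rsid, ref_allele = ref,
    alt_allele = alt, func_class = func_class, novel = novel,
    causal_intronic = seq_len(n_var) == causal_idx,
    burden_set = seq_len(n_var) %in% burden_set,
    stringsAsFactors = FALSE)

  pools <- generate_haplotype_pool(config, freq)

  dosage <- NULL; stratum <- character(0)
  for (s in strata) {
    hap <- pools[[s]]
    N <- config$n_subjects[[s]]
    d <- hap[seq(1, 2 * N, by = 2), ] + hap[seq(2, 2 * N, by = 2), ]
    dosage <- rbind(dosage, d)
    stratum <- c(stratum, rep(s, N))
  }
  rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  colnames(dosage) <- paste0("1:", pos)
  n_all <- nrow(dosage)

  # covariates from plausible adult ranges
  cohort <- data.frame(
    subject_id = rownames(dosage), stratum = stratum,
    age = round(stats::rnorm(n_all, 52, 13), 1),
    sex = stats::rbinom(n_all, 1, 0.45),
    diabetes = stats::rbinom(n_all, 1, 0.10),
    hypertension = stats::rbinom(n_all, 1, 0.30),
    bmi = round(stats::rnorm(n_all, 29.5, 5.5), 1),
    ldl = round(stats::rnorm(n_all, 127, 32), 1),
    smoking = stats::rbinom(n_all, 1, 0.18),
    fibrinogen = round(stats::rnorm(n_all, 355, 75), 1),
    stringsAsFactors = FALSE)

  # latent aggregation score, per stratum: shared genetic + shared noise
  # (total shared variance = pheno_cor), plus per-agonist unique noise
  shared <- numeric(n_all)
  for (s in strata) {
    idx <- which(stratum == s)
    f_int <- freq[causal_idx, s]
    v_int <- config$var_explained_intronic[[s]]
    beta_int <- sqrt(v_int / (2 * f_int * (1 - f_int)))
    g_int <- beta_int * (dosage[idx, causal_idx] - 2 * f_int)
    bsum <- rowSums(dosage[idx, burden_set, drop = FALSE])
    g_bur <- config$beta_burden[[s]] * (bsum - mean(bsum))
    v_shared_noise <- max(config$pheno_cor - v_int -
                            stats::var(g_bur), 0.01)
    shared[idx] <- g_int + g_bur +
      stats::rnorm(length(idx), 0, sqrt(v_shared_noise))
  }
  cov_effect <- with(cohort,
    0.010 * (age - 52) + -0.10 * sex + 0.15 * diabetes +
      0.10 * hypertension + 0.012 * (bmi - 29.5) +
      0.002 * (ldl - 127) + 0.12 * smoking +
      0.0012 * (fibrinogen - 355))
  v_unique <- 1 - config$pheno_cor
  for (ph in c("pheno_col", "pheno_epi", "pheno_adp")) {
    score <- shared + cov_effect + stats::rnorm(n_all, 0, sqrt(v_unique))
    cohort[[ph]] <- pmin(pmax(config$pheno_mean +
                                config$pheno_sd * score, 0), 100)
  }

  gm <- genotype_matrix(dosage, stratum = stats::setNames(stratum,
                                                          rownames(dosage)))
  if (config$missing_rate > 0)
    gm <- apply_missingness(gm, config$missing_rate)
  list(gm = gm, cohort = cohort, annotations = annotations, freq = freq)
}

#' Apply missing-completely-at-random genotype missingness
#'
#' Masks each genotype call independently with probability `rate`
#' (already-missing calls stay missing). Uses the current RNG stream
#' unless `seed` is given.
#'
#' @param gm a [genotype_matrix].
#' @param rate missingness probability in \[0, 1).
#' @param seed optional integer seed.
#' @return a new [genotype_matrix] with calls masked.
#' @export
apply_missingness <- function(gm, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("'rate' must lie in [0, 1)")
  if (rate == 0) return(gm)
  if (!is.null(seed)) set.seed(seed)
  d <- gm$dosage
  mask <- matrix(stats::runif(length(d)) < rate, nrow(d), ncol(d))
  d[mask] <- NA_integer_
  genotype_matrix(d, stratum = gm$stratum)
}

#' Simulate a case/control genotype block with per-variant enrichment
#'
#' Small direct generator for calibration and power studies: draws
#' binomial(2, f) genotypes for hypo (control) subjects at the given
#' minor-allele frequencies and for hyper (case) subjects at frequencies
#' shifted to the requested per-allele odds ratio,
#' `f_case = OR f / (1 - f + OR f)`. Variants are in linkage
#' equilibrium.
#'
#' @param n_hyper,n_hypo group sizes.
#' @param maf per-variant control minor-allele frequencies.
#' @param or per-allele odds ratio (scalar or per-variant); 1 = null.
#' @param seed optional integer seed.
#' @return list with `dosage` (subjects x variants, cases first) and
#'   `is_hyper` logical vector.
#' @export
sim_case_control <- function(n_hyper, n_hypo, maf, or = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(maf)
  or <- rep_len(or, m)
  f_case <- or * maf / (1 - maf + or * maf)
  d_case <- vapply(seq_len(m), function(j)
    stats::rbinom(n_hyper, 2, f_case[j]), integer(n_hyper))
  d_ctrl <- vapply(seq_len(m), function(j)
    stats::rbinom(n_hypo, 2, maf[j]), integer(n_hypo))
  dosage <- rbind(matrix(d_case, n_hyper, m), matrix(d_ctrl, n_hypo, m))
  rownames(dosage) <- sprintf("S%03d", seq_len(n_hyper + n_hypo))
  colnames(dosage) <- sprintf("v%03d", seq_len(m))
  list(dosage = dosage,
       is_hyper = rep(c(TRUE, FALSE), c(n_hyper, n_hypo)))
}
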