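# Independent oracles and small fixture builders used across the suite.

# Two-sided Fisher p by brute-force enumeration of the hypergeometric
# support, with point probabilities from log-factorials (independent of
# dhyper and of the package implementation).
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b          # minor margin
  n1 <- a + c_        # hyper alleles
  n2 <- b + d         # hypo alleles
  if (m == 0) return(1)
  lp <- function(x) {
    # log P(table with a = x | margins), multivariate hypergeometric form
    lchoose(n1, x) + lchoose(n2, m - x) - lchoose(n1 + n2, m)
  }
  support <- max(0, m - n2):min(m, n1)
  probs <- exp(lp(support))
  obs <- exp(lp(a))
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Textbook 1-df Pearson chi-square on a 2x2 table (no correction).
oracle_chisq_p <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

# Haplotype frequencies by direct counting on known phase.
oracle_hap_freqs <- function(hap_a, hap_b) {
  c(pAB = mean(hap_a == 1 & hap_b == 1),
    pAb = mean(hap_a == 1 & hap_b == 0),
    paB = mean(hap_a == 0 & hap_b == 1),
    pab = mean(hap_a == 0 & hap_b == 0))
}

# Exhaustive minimum tag cover for small r2 matrices.
oracle_min_cover <- function(r2, threshold) {
  m <- nrow(r2)
  covers <- !is.na(r2) & r2 > threshold
  diag(covers) <- TRUE
  for (k in 1:m) {
    combos <- utils::combn(m, k, simplify = FALSE)
    for (S in combos) {
      if (all(apply(covers[, S, drop = FALSE], 1, any))) return(k)
    }
  }
  m
}

# Minimal in-memory VCF writer for read_genotypes tests.
write_test_vcf <- function(path, samples, records) {
  # records: list of lists(chrom, pos, id, ref, alt, gts)
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples), collapse = "\t"))
  for (r in records)
    lines <- c(lines, paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".",
                              "PASS", ".", "GT", r$gts), collapse = "\t"))
  writeLines(lines, path)
  path
}

# Toy genotype_matrix builder: dosage entries given column-wise.
toy_gm <- function(dosage, stratum = NULL) {
  d <- as.matrix(dosage)
  if (is.null(rownames(d))) rownames(d) <- sprintf("S%02d", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- sprintf("v%02d", seq_len(ncol(d)))
  if (is.null(stratum)) stratum <- rep("EA", nrow(d))
  genotype_matrix(d, stratum = stratum)
}

# Covariate frame of the right shape with no real structure.
toy_covariates <- function(n, seed = 99) {
  set.seed(seed)
  data.frame(age = rnorm(n, 52, 13), sex = rbinom(n, 1, 0.5),
             diabetes = rbinom(n, 1, 0.1), hypertension = rbinom(n, 1, 0.3),
             bmi = rnorm(n, 29, 5), ldl = rnorm(n, 127, 30),
             smoking = rbinom(n, 1, 0.2), fibrinogen = rnorm(n, 350, 70))
}

# Cohort table wrapper for a simple one-stratum case/control layout.
toy_selected_cohort <- function(ids, is_hyper, stratum = "EA") {
  data.frame(subject_id = ids, stratum = stratum,
             group = ifelse(is_hyper, "hyper", "hypo"),
             stringsAsFactors = FALSE)
}
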