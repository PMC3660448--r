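# Pairwise linkage disequilibrium from unphased genotypes: two-locus
# haplotype frequencies via EM over the double-heterozygote phase
# ambiguity, D / D' / r-squared, and greedy tag-SNP selection.

#' EM haplotype frequencies for two unphased loci
#'
#' Maximum-likelihood two-locus haplotype frequencies (pAB, pAb, paB, pab)
#' from unphased diploid dosages, where "A"/"B" denote the counted allele
#' at each locus. Every genotype pair resolves its haplotypes uniquely
#' except the double heterozygote, whose mass the EM splits between the
#' AB/ab and Ab/aB configurations. Pairwise complete-case: subjects
#' missing at either locus are dropped. Convergence when the largest
#' frequency change falls below `tol` (default 1e-8), up to `max_iter`
#' (1000) iterations.
#'
#' @param dosage_a,dosage_b dosage vectors (0/1/2, `NA` missing).
#' @param tol,max_iter EM stopping rule.
#' @return named numeric `c(pAB, pAb, paB, pab)` with attributes
#'   `monomorphic` (logical flag) and `n` (subjects used).
#' @export
em_haplotype_freqs <- function(dosage_a, dosage_b, tol = 1e-8,
                               max_iter = 1000) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2) stop("need at least 2 subjects non-missing at both loci")
  a <- dosage_a[ok]; b <- dosage_b[ok]
  n <- length(a)
  pA <- mean(a) / 2; pB <- mean(b) / 2
  mono <- pA %in% c(0, 1) || pB %in% c(0, 1)

  # fixed haplotype contributions from unambiguous genotype pairs; the
  # double het (1,1) contributes 2 haplotypes split by the E-step
  dh <- sum(a == 1 & b == 1)
  nAB <- sum((a == 2) * (b == 2) * 2 + (a == 2) * (b == 1) +
               (a == 1) * (b == 2))
  nAb <- sum((a == 2) * (b == 0) * 2 + (a == 2) * (b == 1) +
               (a == 1) * (b == 0))
  naB <- sum((a == 0) * (b == 2) * 2 + (a == 0) * (b == 1) +
               (a == 1) * (b == 2))
  nab <- sum((a == 0) * (b == 0) * 2 + (a == 0) * (b == 1) +
               (a == 1) * (b == 0))

  p <- c(pAB = pA * pB, pAb = pA * (1 - pB),
         paB = (1 - pA) * pB, pab = (1 - pA) * (1 - pB))
  total <- 2 * n
  for (it in seq_len(max_iter)) {
    coup <- p["pAB"] * p["pab"]
    rep_ <- p["pAb"] * p["paB"]
    f <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    newp <- c(nAB + dh * f, nAb + dh * (1 - f),
              naB + dh * (1 - f), nab + dh * f) / total
    names(newp) <- names(p)
    if (max(abs(newp - p)) < tol) {
      p <- newp
      break
    }
    p <- newp
  }
  attr(p, "monomorphic") <- mono
  attr(p, "n") <- n
  p
}

#' LD statistics from two-locus haplotype frequencies
#'
#' Computes the disequilibrium coefficient `D = pAB - pA pB`, the
#' normalised `D' = |D| / Dmax` (Dmax = `min(pA pb, pa pB)` when D > 0,
#' `min(pA pB, pa pb)` otherwise) and the squared allelic correlation
#' `r2 = D^2 / (pA pa pB pb)`. When either locus is fixed the quantities
#' are undefined and returned as `NA` with `defined = FALSE`.
#'
#' @param hap_freqs numeric `c(pAB, pAb, paB, pab)`, non-negative, summing
#'   to 1 (tolerance 1e-6).
#' @return list of class `ld_pair`: `hap_freqs`, `D`, `D_prime`, `r2`,
#'   `defined`.
#' @export
ld_stats <- function(hap_freqs) {
  if (length(hap_freqs) != 4 || any(hap_freqs < -1e-12))
    stop("'hap_freqs' must be 4 non-negative frequencies")
  if (abs(sum(hap_freqs) - 1) > 1e-6)
    stop("haplotype frequencies must sum to 1")
  p <- pmax(as.numeric(hap_freqs), 0)
  pA <- p[1] + p[2]; pB <- p[1] + p[3]
  pa <- 1 - pA; pb <- 1 - pB
  if (pA <= 0 || pa <= 0 || pB <= 0 || pb <= 0)
    return(structure(list(hap_freqs = p, D = NA_real_, D_prime = NA_real_,
                          r2 = NA_real_, defined = FALSE),
                     class = "ld_pair"))
  D <- p[1] - pA * pB
  dmax <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  dprime <- if (dmax > 0) abs(D) / dmax else 0
  r2 <- D^2 / (pA * pa * pB * pb)
  structure(list(hap_freqs = p, D = D, D_prime = min(dprime, 1),
                 r2 = min(r2, 1), defined = TRUE),
            class = "ld_pair")
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("ld_pair: D = %.4f, D' = %.4f, r2 = %.4f\n",
              x$D, x$D_prime, x$r2))
  invisible(x)
}

#' Pairwise r-squared (and D') matrices for a set of variants
#'
#' Runs [em_haplotype_freqs()] + [ld_stats()] over all variant pairs,
#' pairwise complete-case. Undefined pairs (a locus fixed) get `NA`;
#' the diagonal is exactly 1.
#'
#' @param dosage subjects x variants dosage matrix.
#' @return list with symmetric matrices `r2` and `d_prime`.
#' @export
ld_matrix <- function(dosage) {
  d <- as.matrix(dosage)
  m <- ncol(d)
  r2 <- matrix(NA_real_, m, m, dimnames = list(colnames(d), colnames(d)))
  dp <- r2
  diag(r2) <- 1; diag(dp) <- 1
  if (m < 2) return(list(r2 = r2, d_prime = dp))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    st <- ld_stats(em_haplotype_freqs(d[, i], d[, j]))
    r2[i, j] <- r2[j, i] <- st$r2
    dp[i, j] <- dp[j, i] <- st$D_prime
  }
  list(r2 = r2, d_prime = dp)
}

#' Greedy tag-SNP selection
#'
#' Greedy maximum-coverage set cover on the pairwise r-squared matrix:
#' repeatedly pick the variant covering the most still-uncovered variants
#' at `r2 > r2_threshold` (strict; a variant always covers itself, r2 = 1),
#' breaking ties by higher MAF and then smaller genomic position, until
#' every variant is covered.
#'
#' @param r2_matrix square symmetric r-squared matrix with unit diagonal
#'   (`NA` entries count as not-covering).
#' @param r2_threshold coverage threshold, default 0.7 (strict `>`).
#' @param maf,pos optional per-variant tie-breakers (same order as the
#'   matrix).
#' @return list of class `tag_set`: `tags` (variant ids in selection
#'   order), `coverage` (named vector variant -> covering tag),
#'   `r2_threshold`.
#' @export
greedy_tags <- function(r2_matrix, r2_threshold = 0.7,
                        maf = NULL, pos = NULL) {
  m <- nrow(r2_matrix)
  stopifnot(m == ncol(r2_matrix))
  ids <- rownames(r2_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  if (is.null(maf)) maf <- rep(0, m)
  if (is.null(pos)) pos <- seq_len(m)
  covers <- !is.na(r2_matrix) & r2_matrix > r2_threshold
  diag(covers) <- TRUE
  uncovered <- rep(TRUE, m)
  tags <- character(0)
  coverage <- stats::setNames(rep(NA_character_, m), ids)
  while (any(uncovered)) {
    gain <- colSums(covers & uncovered)
    best <- which(gain == max(gain))
    if (length(best) > 1) {
      best <- best[order(-maf[best], pos[best])]
    }
    k <- best[1]
    newly <- which(covers[, k] & uncovered)
    coverage[newly] <- ids[k]
    uncovered[newly] <- FALSE
    tags <- c(tags, ids[k])
  }
  structure(list(tags = tags, coverage = coverage,
                 r2_threshold = r2_threshold),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat("tag_set:", length(x$tags), "tag(s) covering",
      length(x$coverage), "variants at r2 >", x$r2_threshold, "\n")
  cat(paste(x$tags, collapse = ", "), "\n")
  invisible(x)
}
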