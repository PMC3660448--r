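---
title: "Extreme-phenotype resequencing association: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extreme-phenotype resequencing association: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extremevar)
```

## The problem

Targeted resequencing studies of platelet aggregation (and of quantitative
traits generally) often sequence only the tails of the trait distribution:
subjects whose covariate-adjusted aggregation after aspirin lies in the
upper quartile for all three agonists (collagen, epinephrine, ADP) are
*hyper*-aggregators, those below the lower quartile for all three are
*hypo*-aggregators, and the association analysis contrasts the two groups
within each ancestry stratum. Sampling extremes enriches the tails for
causal alleles and makes a small sequencing budget informative, at the cost
of turning a quantitative trait into a case/control contrast.

`extremevar` implements that full analysis path — cohort selection,
MAF-stratified single-variant tests, three rare/common-variant burden
tests with permutation nulls, EM-based LD estimation with tag-SNP
reduction — together with a synthetic cohort generator, because the real
genotype data such studies rest on are typically access-restricted.

## Design stage

Each agonist phenotype (percent aggregation, 0–100) is adjusted by
ordinary least squares on eight covariates — age, sex, diabetes,
hypertension, BMI, LDL, smoking, fibrinogen — *within* each ancestry
stratum, and extremes are selected on the residuals. Choices worth
stating:

* **Quantile rule.** Empirical quantiles with linear interpolation
  (`quantile()` type 7), with *strict* inequalities: a residual exactly at
  the quartile is unselected. Selection is therefore invariant to any
  strictly monotone transform of the residuals.
* **All-three rule.** A subject qualifies only if it is in the same tail
  for all three agonists. With independent phenotypes this selects about
  `0.25^3 = 1.6%` per tail; with the inter-agonist correlation of 0.8 the
  generator assumes, about 13.5% per tail.
* **Missing covariates.** Rows with missing covariates are dropped from
  the fit (count reported); a constant covariate is dropped as aliased
  with a warning rather than failing the stratum.
* **Strata with fewer than 8 subjects are refused** — quartiles carry no
  meaning there.

## Single-variant tests

Variants are tested within stratum among the selected extremes, dispatched
on the complete-case minor allele frequency:

* **Rare (MAF < 0.05, strict):** two-sided Fisher exact test on the
  2×2 *allele-count* table (minor/major × hyper/hypo). Allele counting —
  not genotype counting — is what reproduces the singleton p-values
  printed in studies of this design (a single minor allele among 102 gives
  p = 48/102 ≈ 0.4706 when carried in the 48-allele group, and exactly 1
  when carried in the larger group). The two-sided p is the
  probability-mass rule: the sum of hypergeometric probabilities of every
  table no more probable than the observed one, with a relative tie
  tolerance of 1e-7. A variant with MAF exactly 0.05 is common: the
  boundary is assigned once, strictly.
* **Common (MAF ≥ 0.05):** additive logistic regression of group on
  dosage (0/1/2); the Wald p-value is reported. Wald rather than
  likelihood-ratio is the long-standing default of standard software;
  with ~50 subjects per stratum the difference is immaterial. Complete
  separation or non-convergence (detected from exploding estimates or
  standard errors) flags the result and leaves the p-value missing.
* **Monomorphic in stratum:** no test, reported as `NA` rather than p = 1.
* No covariates enter these models: adjustment happened before selection,
  so re-adjusting would be circular.

Reporting uses signed `-log10(p)` (`+` = minor allele enriched in
hyper-aggregators) and a Bonferroni threshold `0.05 / m` over the `m`
variants actually tested, displayed at one significant figure
(`0.05/235` displays as `0.0002`).

## Burden tests

All burden tests compare hyper vs hypo within a stratum on a variant set
defined by functional class (missense & synonymous, missense, synonymous)
and a rarity filter. Membership is decided from the MAF among the
*selected* subjects, so a cell's `n` counts variants actually observed
there. Inside a set, a missing call counts as dosage 0 (non-carrier):
dropping subjects instead would make per-subject scores and rank sums
incomparable across patterns of missingness.

* **CMC (collapsing):** the set collapses to a carrier indicator
  (≥ 1 minor allele at ≥ 1 set variant), tested by a 1-df Pearson
  chi-square without continuity correction; when any expected cell is
  below 5 the test falls back to the Fisher exact test on the same table.
  The full multivariate Hotelling form of the original CMC proposal is
  unnecessary here because the rare-only filter leaves a single collapsed
  group; this divergence is deliberate and documented.
* **Weighted sum (Madsen–Browning):** control-group frequencies with a
  +1 pseudocount, `q_j = (m_j + 1)/(2 n_j + 2)`; weights
  `w_j = sqrt(n_j q_j (1 - q_j))`; per-subject scores
  `sum_j dosage_ij / w_j`; statistic = rank sum of case scores (midranks
  on ties). The p-value is the add-one permutation rule `(k + 1)/(B + 1)`
  over `B` label permutations (default 2,000), with frequencies, weights
  and scores re-estimated per permutation, as in the original
  construction. The smallest attainable p is `1/(B + 1)`.
* **C-alpha:** tests over-dispersion of the case/control split of minor
  allele copies around the case fraction `p0`, variant by variant, without
  aggregating — so it retains power when effects point in opposite
  directions. Both the analytic one-sided `z = T/sqrt(c)` p-value and a
  permutation p under the same scheme are reported; when the variance
  `c` is 0 (all singletons, degenerate) only the permutation p remains.
  Each variant is its own category; singletons are not pooled.

Permutations are seeded; reruns are byte-identical.

## LD and tag SNPs

Two-locus haplotype frequencies are estimated from unphased genotypes by
EM over the double-heterozygote ambiguity (tolerance 1e-8, ≤ 1,000
iterations; pairwise complete-case), then `D`, `D'` and `r²` follow in
closed form. Tag selection is a greedy maximum-coverage set cover at
`r² > 0.7` (strict), ties broken by higher MAF then smaller position.
Greedy cover is not guaranteed minimal, but on random 8-variant panels it
matches the exhaustive minimum in the large majority of instances (this
is exercised in the test suite); the heuristics of the original
Haploview/Tagger software are not replicated.

## The synthetic cohort generator

`sim_config()` encodes the study conditions as defaults:

| quantity | default | rationale |
|---|---|---|
| subjects per stratum | 190 AA / 195 EA | with the all-three quartile rule and correlation 0.8, ≈ 13.5% select per tail, giving ≈ 104 extremes |
| variant panel | 235 (16 missense, 14 synonymous, 13 UTR, 20 intergenic, 172 intronic) | targeted-region panel with a contiguous exonic stretch |
| rare-variant loads | 108 (AA) vs 45 (EA) at MAF < 5% | stratum-specific site-frequency structure, achieved by stratum-private rare variants |
| missingness | 8.6% MCAR | mean missing rate of capillary-sequencing genotype calls |
| inter-agonist correlation | 0.8 | three phenotypes share one latent aggregation score |
| intronic causal variant | explains 39% (AA) / 16% (EA) of latent variance, MAF 0.35/0.40 | a strong common regulatory-variant signal in one stratum, weaker in the other |
| synonymous burden | +0.25 latent units per minor allele, EA only | a multi-variant coding signal detectable by WS but not by single-variant tests |
| novel variants | 61, all rare, rsID "-" | resequencing panels discover mostly rare unnamed sites |

Haplotypes are drawn blockwise with a Gaussian copula: a shared latent
factor per block (size 5, loading `sqrt(0.5)`) thresholded at each
variant's target frequency. This yields positive within-block LD and
independence across blocks. With the default latent correlation of 0.5
the allele-level `r²` among common variants is mostly below the 0.7
tagging threshold, so tag reduction on simulated panels is modest; a
within-block correlation of 1 with equal frequencies reproduces exact
duplicates (and warns when unequal frequencies make the unit target
infeasible). Phenotypes are linear-Gaussian in the latent score, scaled
to percent and clipped to [0, 100] — the simplest structure supporting
quartile selection.

What the generator does **not** emulate: family structure (the real
cohorts are sibships analysed with GEE), population admixture within
strata, coalescent site-frequency spectra, informative missingness, and
haplotype blocks with realistic decay. Passing tests therefore show the
*methods* behave correctly under the stated model, not that the study's
specific p-values are recovered — its raw genotypes are access-restricted,
and the published headline burden p-values are explicitly out of reach.

## Numerical choices and degenerate inputs

* Fisher tie tolerance `1e-7` (relative), matching standard practice.
* MAF folding: alternate-allele frequencies above 0.5 are flipped per
  stratum before any analysis; all reported MAFs are ≤ 0.5.
* Zero minor-allele margin → Fisher p = 1 by convention; in scan reports
  monomorphic variants show `NA` ("no test") instead.
* Rank-deficient covariate designs drop aliased terms with a warning.
* Permutation p-values use `(k + 1)/(B + 1)` and can never be 0.
* Empty burden cells are "no test", never a fabricated p.
* EM with a fixed locus returns flagged degenerate frequencies; LD is
  `NA` there.

## Problem sizes used in validation

The packaged checks calibrate type-I error on 2,000 null cohorts of
25 + 27 subjects with 15 rare variants (WS at B = 500), measure burden
power/recovery on 200 replicates of an EA-like 15-variant exonic panel
with a per-allele odds ratio of 2 on the 8 synonymous variants, verify
the Fisher implementation exhaustively against an enumeration oracle on
every 2×2 table with margins ≤ 30, and check LD/tagging against phased
and exhaustive set-cover oracles on 8-variant panels. These sizes keep
the full validation run comfortably on one CPU while leaving the
binomial error bands tight enough to detect miscalibration of a few
percentage points.

## Known limitations

* The CMC variant here is the collapsing chi-square, not the multivariate
  Hotelling test of the original proposal.
* The analytic C-alpha p-value relies on a normal approximation that is
  poor when few minor-allele copies are observed; the permutation p is
  reported alongside and preferred for sparse sets.
* Greedy tagging is heuristic; minimality is typical, not guaranteed.
* The logistic single-variant test reports no p-value under separation —
  exact logistic regression is out of scope.
* Strata are analysed fully independently; no pooled or meta-analysis is
  provided.
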