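test_that("cohort generation is fully deterministic given the seed", {
  a <- generate_cohort(sim_config(), seed = 101)
  b <- generate_cohort(sim_config(), seed = 101)
  expect_identical(a$gm$dosage, b$gm$dosage)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$annotations, b$annotations)
  c_ <- generate_cohort(sim_config(), seed = 102)
  expect_false(identical(a$gm$dosage, c_$gm$dosage))
})

test_that("stratum rare-variant loads land near the configured targets", {
  for (seed in c(1, 2, 3)) {
    sim <- generate_cohort(sim_config(), seed = seed)
    for (s in c("AA", "EA")) {
      d <- minor_dosage(sim$gm, s)
      maf <- apply(d, 2, function(x)
        if (all(is.na(x))) NA_real_ else compute_maf(x))
      n_rare <- sum(!is.na(maf) & maf > 0 & maf < 0.05)
      target <- c(AA = 108, EA = 45)[[s]]
      expect_gte(n_rare, target - 10)
      expect_lte(n_rare, target + 10)
    }
  }
})

test_that("the variant panel matches the configured composition", {
  sim <- generate_cohort(sim_config(), seed = 5)
  ann <- sim$annotations
  expect_equal(nrow(ann), 235)
  expect_equal(sum(ann$func_class == "missense"), 16)
  expect_equal(sum(ann$func_class == "synonymous"), 14)
  expect_equal(sum(ann$novel), 61)
  expect_true(all(ann$rsid[ann$novel] == "-"))
  expect_equal(sum(ann$causal_intronic), 1)
  expect_equal(ann$func_class[ann$causal_intronic], "intronic")
  expect_true(all(ann$func_class[ann$burden_set] == "synonymous"))
  expect_true(all(diff(ann$pos) > 0))
})

test_that("MCAR missingness hits the configured rate and leaves values alone", {
  set.seed(77)
  d <- matrix(sample(0:2, 104 * 235, replace = TRUE), 104, 235,
              dimnames = list(sprintf("S%03d", 1:104),
                              sprintf("v%03d", 1:235)))
  gm <- genotype_matrix(d, rep(c("AA", "EA"), 52))
  gm0 <- apply_missingness(gm, 0)
  expect_identical(gm0$dosage, gm$dosage)
  gm86 <- apply_missingness(gm, 0.086, seed = 3)
  realized <- mean(is.na(gm86$dosage))
  expect_gt(realized, 0.086 - 0.006)
  expect_lt(realized, 0.086 + 0.006)
  kept <- !is.na(gm86$dosage)
  expect_identical(gm86$dosage[kept], gm$dosage[kept])
})

test_that("the causal intronic variant is enriched in hyper-aggregators", {
  diffs <- vapply(1:20, function(seed) {
    sim <- generate_cohort(sim_config(), seed = seed)
    co <- suppressMessages(adjust_cohort(sim$cohort))
    co <- select_extremes(co)
    j <- which(sim$annotations$causal_intronic)
    out <- numeric(0)
    for (s in c("AA", "EA")) {
      sel <- co[co$stratum == s & co$group %in% c("hyper", "hypo"), ]
      d <- minor_dosage(sim$gm, s, subjects = sel$subject_id)[, j]
      f_hyper <- mean(d[sel$group == "hyper"], na.rm = TRUE)
      f_hypo <- mean(d[sel$group == "hypo"], na.rm = TRUE)
      out <- c(out, f_hyper - f_hypo)
    }
    mean(out)
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.8)
  expect_gt(mean(diffs), 0)
})

test_that("inter-agonist correlation is recovered at large n", {
  cfg <- sim_config(n_subjects = c(AA = 1000, EA = 1000))
  sim <- generate_cohort(cfg, seed = 9)
  for (s in c("AA", "EA")) {
    idx <- sim$cohort$stratum == s
    cors <- cor(sim$cohort[idx, c("pheno_col", "pheno_epi", "pheno_adp")])
    off <- cors[upper.tri(cors)]
    expect_true(all(abs(off - 0.8) < 0.05))
  }
})

test_that("a null configuration produces uniform scan p-values", {
  cfg <- sim_config(var_explained_intronic = c(AA = 0, EA = 0),
                    beta_burden = c(AA = 0, EA = 0))
  sim <- generate_cohort(cfg, seed = 13)
  co <- suppressMessages(adjust_cohort(sim$cohort))
  co <- select_extremes(co)
  ps <- unlist(lapply(c("AA", "EA"), function(s)
    single_variant_scan(sim$gm, co, s)$p_value))
  ps <- ps[!is.na(ps)]
  frac <- mean(ps < 0.05)
  # conservative discrete Fisher p-values pull the rate below nominal
  expect_lt(frac, 0.08)
  expect_gt(mean(ps), 0.35)
})

test_that("single-block copula with unit correlation duplicates columns", {
  cfg <- sim_config(n_subjects = c(AA = 50, EA = 50), n_variants = 4,
                    class_counts = c(missense = 0, synonymous = 0, utr3 = 0,
                                     utr5 = 0, intergenic = 0, intronic = 4),
                    ld_block_size = 4, ld_block_r = 1)
  freq <- matrix(0.3, 4, 2, dimnames = list(NULL, c("AA", "EA")))
  set.seed(4)
  pool <- generate_haplotype_pool(cfg, freq)
  expect_equal(pool$AA[, 1], pool$AA[, 2])
  expect_equal(pool$EA[, 3], pool$EA[, 4])
  freq2 <- freq; freq2[1, ] <- 0.1
  expect_warning(generate_haplotype_pool(cfg, freq2), "infeasible")
})

test_that("variants in different blocks are essentially independent", {
  cfg <- sim_config(n_subjects = c(AA = 2500, EA = 10), n_variants = 10,
                    class_counts = c(missense = 0, synonymous = 0, utr3 = 0,
                                     utr5 = 0, intergenic = 0, intronic = 10),
                    ld_block_size = 5, ld_block_r = 0.9)
  freq <- matrix(0.3, 10, 2, dimnames = list(NULL, c("AA", "EA")))
  set.seed(21)
  pool <- generate_haplotype_pool(cfg, freq)$AA
  cross <- abs(cor(pool[, 1:5], pool[, 6:10]))^2
  expect_lt(mean(cross), 0.02)
  within <- cor(pool[, 1:5])[upper.tri(diag(5))]
  expect_gt(mean(within), 0.3)
})
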