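test_that("carrier collapsing follows the >= 1 minor allele rule", {
  d <- rbind(c(0L, 0L, 2L), c(0L, 0L, 0L), c(NA, 1L, 0L), c(NA, NA, NA))
  rownames(d) <- paste0("S", 1:4); colnames(d) <- paste0("v", 1:3)
  expect_equal(collapse_carriers(d), c(1L, 0L, 1L, 0L))
  expect_error(collapse_carriers(d[, 0]), "empty")
})

test_that("carrier frequency matches its closed form under equilibrium", {
  set.seed(8)
  q <- runif(6, 0.01, 0.05)
  sim <- sim_case_control(2500, 2500, maf = q, or = 1)
  expected <- 1 - prod((1 - q)^2)
  observed <- mean(collapse_carriers(sim$dosage))
  expect_equal(observed, expected, tolerance = 0.02)
})

test_that("CMC matches the textbook chi-square and is null on equal rates", {
  # identical carrier rates -> statistic 0, p 1 (expected cells >= 5)
  d <- matrix(c(rep(1L, 10), rep(0L, 40), rep(1L, 10), rep(0L, 40)),
              ncol = 1)
  rownames(d) <- paste0("S", 1:100); colnames(d) <- "v1"
  r0 <- cmc_test(d, rep(c(TRUE, FALSE), each = 50))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$direction, "0")

  # 20/50 vs 5/50 carriers against the hand-computed chi-square
  d2 <- matrix(c(rep(1L, 20), rep(0L, 30), rep(1L, 5), rep(0L, 45)),
               ncol = 1)
  rownames(d2) <- paste0("S", 1:100); colnames(d2) <- "v1"
  r2 <- cmc_test(d2, rep(c(TRUE, FALSE), each = 50))
  tab <- rbind(c(20, 5), c(30, 45))
  expect_equal(r2$p_value, oracle_chisq_p(tab), tolerance = 1e-12)
  expect_equal(r2$direction, "+")
  expect_equal(r2$fallback, "none")
})

test_that("CMC falls back to Fisher when expected cells are small", {
  d <- matrix(c(rep(1L, 3), rep(0L, 22), rep(0L, 27)), ncol = 1)
  rownames(d) <- paste0("S", 1:52); colnames(d) <- "v1"
  r <- cmc_test(d, rep(c(TRUE, FALSE), c(25, 27)))
  expect_equal(r$fallback, "fisher")
  expect_equal(r$p_value,
               oracle_fisher_p(3, 0, 22, 27), tolerance = 1e-12)
  expect_error(cmc_test(d[, 0], rep(TRUE, 52)), "refuses")
})

test_that("weighted-sum workspace uses the control pseudocount formula", {
  # variant absent in 27 hypo subjects -> q = 1/56
  set.seed(15)
  d <- cbind(v1 = c(rep(1L, 3), rep(0L, 49)),
             v2 = c(rep(0L, 25), rep(1L, 2), rep(0L, 25)))
  rownames(d) <- paste0("S", 1:52)
  is_hyper <- rep(c(TRUE, FALSE), c(25, 27))
  r <- ws_test(d, is_hyper, burden_config(n_permutations = 50, rng_seed = 1))
  expect_equal(unname(r$q["v1"]), 1 / 56)
  expect_equal(unname(r$q["v2"]), 3 / 56)
  expect_equal(unname(r$weights), sqrt(52 * r$q * (1 - r$q)),
               ignore_attr = TRUE)
  # rank-sum bounds for 25 of 52 subjects
  expect_gte(r$statistic, sum(1:25))
  expect_lte(r$statistic, sum(28:52))
})

test_that("permutation p respects the add-one rule and its floor", {
  # carriers exactly the cases: observed rank sum is maximal
  d <- matrix(rep(c(2L, 0L), c(20, 20)), ncol = 1)
  rownames(d) <- paste0("S", 1:40); colnames(d) <- "v1"
  r <- ws_test(d, rep(c(TRUE, FALSE), each = 20),
               burden_config(n_permutations = 400, rng_seed = 5))
  expect_equal(r$p_value, 1 / 401)
  # and on random null data p stays within [1/(B+1), 1]
  set.seed(6)
  for (i in 1:5) {
    sim <- sim_case_control(15, 17, maf = runif(5, 0.02, 0.2), or = 1)
    p <- ws_test(sim$dosage, sim$is_hyper,
                 burden_config(n_permutations = 99, rng_seed = i))$p_value
    expect_gte(p, 1 / 100)
    expect_lte(p, 1)
  }
  # constant scores give p = 1
  d0 <- matrix(0L, 30, 2,
               dimnames = list(paste0("S", 1:30), c("a", "b")))
  d0[1, ] <- NA
  r0 <- ws_test(d0, rep(c(TRUE, FALSE), 15),
                burden_config(n_permutations = 50, rng_seed = 2))
  expect_equal(r0$p_value, 1)
})

test_that("burden statistics ignore subject ordering", {
  set.seed(12)
  sim <- sim_case_control(25, 27, maf = runif(8, 0.02, 0.2), or = 1.5)
  perm <- sample(nrow(sim$dosage))
  cfg <- burden_config(n_permutations = 200, rng_seed = 9)
  r1 <- ws_test(sim$dosage, sim$is_hyper, cfg)
  r2 <- ws_test(sim$dosage[perm, ], sim$is_hyper[perm], cfg)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)   # same seeded permutation stream
  c1 <- cmc_test(sim$dosage, sim$is_hyper)
  c2 <- cmc_test(sim$dosage[perm, ], sim$is_hyper[perm])
  expect_equal(c1$p_value, c2$p_value)
  a1 <- c_alpha_test(sim$dosage, sim$is_hyper, cfg)
  a2 <- c_alpha_test(sim$dosage[perm, ], sim$is_hyper[perm], cfg)
  expect_equal(a1$statistic, a2$statistic)
  expect_equal(a1$z, a2$z)
})

test_that("C-alpha is non-positive without overdispersion", {
  # every variant splits its copies exactly at the case fraction
  d <- cbind(v1 = rep(c(1L, 1L, 0L, 0L), 5),
             v2 = rep(c(1L, 0L, 1L, 0L), 5))
  rownames(d) <- paste0("S", 1:20)
  is_hyper <- rep(c(TRUE, FALSE), each = 10)
  r <- c_alpha_test(d, is_hyper, burden_config(n_permutations = 100,
                                               rng_seed = 3))
  expect_lte(r$statistic, 0)
  expect_gte(r$p_analytic, 0.5)
})

test_that("C-alpha variance matches direct binomial summation", {
  set.seed(30)
  sim <- sim_case_control(25, 27, maf = runif(6, 0.05, 0.2), or = 1)
  r <- c_alpha_test(sim$dosage, sim$is_hyper,
                    burden_config(n_permutations = 50, rng_seed = 4))
  d0 <- sim$dosage
  n_i <- colSums(d0); n_i <- n_i[n_i >= 1]
  p0 <- 25 / 52
  cvar <- 0
  for (ni in n_i) for (u in 0:ni)
    cvar <- cvar + dbinom(u, ni, p0) *
      ((u - ni * p0)^2 - ni * p0 * (1 - p0))^2
  expect_equal(r$variance, cvar, tolerance = 1e-10)
  expect_equal(r$z, r$statistic / sqrt(cvar), tolerance = 1e-10)
})

test_that("C-alpha keeps power under opposite effect directions", {
  set.seed(44)
  B <- 60; n_rep <- 80
  rej_ca <- 0; rej_ws <- 0
  for (i in 1:n_rep) {
    sim <- sim_case_control(25, 27, maf = rep(0.08, 10),
                            or = rep(c(3, 1 / 3), each = 5))
    cfg <- burden_config(n_permutations = B, rng_seed = i)
    ca <- c_alpha_test(sim$dosage, sim$is_hyper, cfg)
    ws <- ws_test(sim$dosage, sim$is_hyper, cfg)
    rej_ca <- rej_ca + (ca$p_analytic < 0.05)
    rej_ws <- rej_ws + (ws$p_value < 0.05)
  }
  expect_gt(rej_ca, rej_ws)
})

test_that("single-variant CMC agrees with the variant's own carrier table", {
  set.seed(18)
  sim <- sim_case_control(30, 30, maf = 0.15, or = 2)
  d <- sim$dosage[, 1, drop = FALSE]
  r <- cmc_test(d, sim$is_hyper)
  carrier <- as.integer(d[, 1] > 0)
  tab <- table(factor(carrier, c(1, 0)), factor(sim$is_hyper, c(TRUE, FALSE)))
  if (all(outer(rowSums(tab), colSums(tab)) / sum(tab) >= 5))
    expect_equal(r$p_value, oracle_chisq_p(unclass(tab)), tolerance = 1e-12)
  else expect_equal(r$p_value,
                    oracle_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1],
                                    tab[2, 2]), tolerance = 1e-12)
})

test_that("the burden grid mirrors the class-by-rarity layout", {
  set.seed(61)
  n <- 52
  maf <- c(runif(7, 0.08, 0.3),            # 7 common missense
           runif(5, 0.1, 0.3), runif(3, 0.015, 0.04))  # 8 synonymous
  sim <- sim_case_control(25, 27, maf = maf, or = 1)
  ann <- data.frame(chrom = "1", pos = seq_len(15) * 10,
                    rsid = paste0("rs", 1:15), ref_allele = "A",
                    alt_allele = "G",
                    func_class = rep(c("missense", "synonymous"), c(7, 8)),
                    novel = FALSE)
  colnames(sim$dosage) <- paste0("v", 1:15)
  gm <- toy_gm(sim$dosage)
  co <- toy_selected_cohort(rownames(sim$dosage), sim$is_hyper)
  grid <- burden_suite(gm, ann, co, "EA",
                       config = burden_config(n_permutations = 50,
                                              rng_seed = 10))
  expect_equal(nrow(grid), 9)
  all_row <- grid[grid$classes == "missense_synonymous" &
                    grid$method == "ws" & grid$rarity_filter == "all", ]
  expect_equal(all_row$n_variants, 15)
  # cells with no qualifying variants are reported as no test
  ann2 <- ann; ann2$func_class <- rep("missense", 15)
  grid2 <- burden_suite(gm, ann2, co, "EA",
                        config = burden_config(n_permutations = 50,
                                               rng_seed = 10))
  syn_cells <- grid2[grid2$classes == "synonymous", ]
  expect_true(all(syn_cells$note == "no test"))
  expect_true(all(is.na(syn_cells$p_value)))
})
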