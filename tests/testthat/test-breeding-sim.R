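test_that("sex assignment splits 1:1 with the extra individual as a dam", {
  g4 <- random_geno(4, 5, seed = 1)
  s4 <- assign_sexes(g4, seed = 3)
  expect_equal(length(s4$dams), 2L)
  expect_equal(length(s4$sires), 2L)

  g5 <- random_geno(5, 5, seed = 1)
  s5 <- assign_sexes(g5, seed = 3)
  expect_equal(length(s5$dams), 3L)
  expect_equal(length(s5$sires), 2L)
  expect_identical(assign_sexes(g5, seed = 3), assign_sexes(g5, seed = 3))
  expect_error(assign_sexes(random_geno(1, 5, seed = 1)), ">= 2 parents")
})

test_that("Mendelian transmission: fixation persists, het x het is 1:2:1", {
  fixed <- make_geno(matrix(0L, 4, 10))
  off <- withr::with_seed(1, mate_randomly(fixed, 1:2, 3:4, 50))
  expect_true(all(off$calls == 0L))

  hets <- make_geno(matrix(1L, 2, 1))
  off2 <- withr::with_seed(2, mate_randomly(hets, 1, 2, 10000))
  counts <- table(factor(off2$calls, levels = 0:2))
  chi <- chisq.test(counts, p = c(0.25, 0.5, 0.25))
  expect_gt(chi$p.value, 0.001)
})

test_that("transmission is unbiased in allele frequency", {
  parents <- random_geno(20, 50, p = 0.4, seed = 3)
  sexes <- withr::with_seed(4, assign_sexes(parents))
  off <- withr::with_seed(5, mate_randomly(parents, sexes$dams, sexes$sires,
                                           1000))
  # expected offspring frequency = mean of dam-pool and sire-pool freqs
  p_dam <- mean(parents$calls[sexes$dams, ]) / 2
  p_sire <- mean(parents$calls[sexes$sires, ]) / 2
  p_exp <- (p_dam + p_sire) / 2
  p_obs <- mean(off$calls) / 2
  se <- sqrt(p_exp * (1 - p_exp) / (2 * 1000 * 50))
  expect_lt(abs(p_obs - p_exp), 4 * se)
  expect_error(mate_randomly(make_geno(matrix(NA_integer_, 2, 1)), 1, 2, 5),
               "impute")
})

test_that("monomorphic donors stay monomorphic over generations", {
  mono <- make_geno(matrix(2L, 6, 8))
  cfg <- sim_config(donor_counts = 2, n_offspring = 30, generations = 5,
                    checkpoints = c(1, 3, 5), n_boot = 1)
  tr <- withr::with_seed(1, simulate_generations(mono, cfg))
  expect_true(all(tr$he == 0))
  expect_true(all(tr$pl_pct == 0))
})

test_that("a fixed locus never re-polymorphises", {
  g <- random_geno(10, 20, p = 0.5, seed = 6)
  g$calls[, 1] <- 2L
  cfg <- sim_config(donor_counts = 2, n_offspring = 50, generations = 8,
                    checkpoints = 8, n_boot = 1)
  tr <- withr::with_seed(2, simulate_generations(g, cfg, keep_genotypes = TRUE))
  final <- attr(tr, "genotypes")[["8"]]
  expect_true(all(final$calls[, 1] == 2L))
})

test_that("He decay follows the closed-form drift expectation", {
  # founders at p = 0.5 everywhere; 2 donors -> Ne 2 in generation 1,
  # then a population of 200 (the decay after generation 1 is ~1/(2*200))
  n_rep <- 120
  L <- 40
  he_t3 <- withr::with_seed(11, replicate(n_rep, {
    donors <- make_geno(matrix(rbinom(2 * L, 2, 0.5), 2, L))
    cfg <- sim_config(donor_counts = 2, n_offspring = 200, generations = 3,
                      checkpoints = 3, n_boot = 1)
    simulate_generations(donors, cfg)$he
  }))
  he0 <- 0.5
  expected <- expected_he_decay(he0, 1, 1, 1) * (1 - 1 / (2 * 200))^3
  mc_se <- sd(he_t3) / sqrt(n_rep)
  expect_lt(abs(mean(he_t3) - expected), 3 * mc_se + 0.002)
})

test_that("allele frequencies are martingales under random mating", {
  p0 <- 0.3
  L <- 30
  freqs <- withr::with_seed(12, replicate(150, {
    donors <- make_geno(matrix(rbinom(10 * L, 2, p0), 10, L))
    cfg <- sim_config(donor_counts = 2, n_offspring = 60, generations = 10,
                      checkpoints = 10, n_boot = 1)
    tr <- simulate_generations(donors, cfg, keep_genotypes = TRUE)
    mean(attr(tr, "genotypes")[["10"]]$calls) / 2
  }))
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - p0), 3 * se)
})

test_that("donor sweep summarises He/PL with drift-driven structure", {
  wild <- withr::with_seed(13, {
    p <- runif(60, 0.05, 0.5)
    make_geno(matrix(rbinom(40 * 60, 2, rep(p, each = 40)), 40, 60))
  })
  cfg <- sim_config(donor_counts = c(2, 6, 20), n_offspring = 100,
                    generations = 25, checkpoints = c(1, 25), n_boot = 25,
                    seed = 5)
  sweep <- donor_sweep(wild, cfg)
  expect_s3_class(sweep, "sim_result")
  expect_equal(nrow(sweep), 3 * 2 * 2)

  he_f1 <- dplyr::filter(tibble::as_tibble(sweep), metric == "he",
                         generation == 1)
  he_f1 <- he_f1[order(he_f1$donor_count), ]
  expect_true(all(diff(he_f1$mean) > -3 * he_f1$se[-1]))

  pl <- tidyr::pivot_wider(
    dplyr::filter(tibble::as_tibble(sweep), metric == "pl_pct"),
    id_cols = "donor_count", names_from = "generation",
    values_from = "mean")
  expect_true(all(pl[["25"]] < pl[["1"]]))
  expect_error(donor_sweep(wild, sim_config(donor_counts = 200)),
               "exceeds pool")
})

test_that("using the whole pool as donors preserves pool He at F1", {
  pool <- withr::with_seed(14, {
    p <- runif(80, 0.2, 0.5)
    make_geno(matrix(rbinom(30 * 80, 2, rep(p, each = 30)), 30, 80))
  })
  p_pool <- colMeans(pool$calls) / 2
  he_pool <- mean(2 * p_pool * (1 - p_pool))
  cfg <- sim_config(donor_counts = 30, n_offspring = 500, generations = 1,
                    checkpoints = 1, n_boot = 20, seed = 7)
  sw <- donor_sweep(pool, cfg)
  he_f1 <- dplyr::filter(tibble::as_tibble(sw), metric == "he")$mean
  expect_lt(abs(he_f1 - he_pool) / he_pool, 0.05)
})

test_that("expected He decay closed form", {
  expect_equal(expected_he_decay(0.4, 5, 5, 0), 0.4)
  expect_equal(expected_he_decay(0.4, 1, 1, 1), 0.3)  # Ne = 2
  expect_equal(expected_he_decay(0.4, 1e9, 1e9, 50), 0.4, tolerance = 1e-6)
  expect_error(expected_he_decay(0.4, 0, 3, 1), "positive")
})

test_that("sweep cells are reproducible and independent of sweep makeup", {
  wild <- random_geno(25, 30, p = 0.3, seed = 15)
  cfg_a <- sim_config(donor_counts = c(2, 6), n_offspring = 40,
                      generations = 3, checkpoints = 3, n_boot = 5, seed = 9)
  cfg_b <- sim_config(donor_counts = c(6), n_offspring = 40,
                      generations = 3, checkpoints = 3, n_boot = 5, seed = 9)
  sw_a <- donor_sweep(wild, cfg_a)
  sw_b <- donor_sweep(wild, cfg_b)
  a6 <- dplyr::filter(tibble::as_tibble(sw_a), donor_count == 6)
  b6 <- tibble::as_tibble(sw_b)
  expect_equal(a6$mean, b6$mean, tolerance = 1e-12)
})
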