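test_that("the generator is deterministic in (config, seed)", {
  cfg <- synth_config(n_loci = 100, n_ind_per_pop = 20, seed = 42)
  g1 <- generate_wild_populations(cfg)
  g2 <- generate_wild_populations(cfg)
  expect_identical(g1$calls, g2$calls)
  expect_identical(g1$loci, g2$loci)
  g3 <- generate_wild_populations(synth_config(n_loci = 100,
                                               n_ind_per_pop = 20, seed = 43))
  expect_false(identical(g1$calls, g3$calls))

  b1 <- scenario_full_study(seed = 3, n_loci = 120)
  b2 <- scenario_full_study(seed = 3, n_loci = 120)
  expect_identical(b1$genotypes$calls, b2$genotypes$calls)
})

test_that("fst_target 0 gives undifferentiated populations", {
  cfg <- synth_config(n_loci = 2000, fst_target = 0, maf_lo = 0.1,
                      maf_hi = 0.5, missing_rate = 0, seed = 7)
  g <- generate_wild_populations(cfg)
  th <- wc_theta(g, g$individuals$population == "warm",
                 g$individuals$population == "cool")
  expect_lt(abs(th$theta), 0.01)
})

test_that("estimated theta tracks fst_target 0.08", {
  ths <- sapply(1:5, function(s) {
    cfg <- synth_config(n_loci = 2000, fst_target = 0.08, seed = s)
    g <- generate_wild_populations(cfg)
    wc_theta(g, g$individuals$population == "warm",
             g$individuals$population == "cool")$theta
  })
  expect_lt(abs(mean(ths) - 0.08), 0.02)
})

test_that("realised missingness is close to the configured rate", {
  cfg <- synth_config(n_loci = 200, n_ind_per_pop = 50, seed = 2)
  g <- generate_wild_populations(cfg)   # 20,000 calls
  expect_lt(abs(mean(is.na(g$calls)) - 0.183), 0.01)
})

test_that("uniform contributions without selfing keep donor frequencies", {
  donors <- withr::with_seed(3, {
    p <- runif(150, 0.1, 0.5)
    make_geno(matrix(rbinom(40 * 150, 2, rep(p, each = 40)), 40, 150))
  })
  f1 <- generate_hatchery_cohort(donors, hatchery_config(
    n_offspring = 400, contribution_concentration = Inf,
    selfing_rate = 0, missing_rate = 0, seed = 4))
  p_d <- colMeans(donors$calls) / 2
  p_o <- colMeans(f1$calls) / 2
  se <- sqrt(mean(p_d * (1 - p_d)) / (2 * 400))
  expect_lt(abs(mean(p_o) - mean(p_d)), 4 * se)
  expect_equal(unique(f1$individuals$cohort), "hatchery")
  expect_equal(sort(unique(f1$individuals$age_months)), c(5L, 7L, 9L))
})

test_that("strong concentration skew collapses the realised parent set", {
  donors <- random_geno(100, 50, p = 0.3, seed = 5)
  f1 <- generate_hatchery_cohort(donors, hatchery_config(
    n_offspring = 80, contribution_concentration = 0.1, seed = 6))
  expect_lt(attr(f1, "truth")$n_distinct_parents, 50)
  f1_even <- generate_hatchery_cohort(donors, hatchery_config(
    n_offspring = 80, contribution_concentration = Inf, seed = 6))
  expect_gt(attr(f1_even, "truth")$n_distinct_parents,
            attr(f1, "truth")$n_distinct_parents)
  expect_error(generate_hatchery_cohort(random_geno(1, 5, seed = 1),
                                        hatchery_config()), ">= 2 donors")
})

test_that("obligate selfing of one donor inflates FIS", {
  one <- withr::with_seed(8, make_geno(matrix(rbinom(400, 2, 0.5), 1, 400),
                                       population = "warm"))
  two <- geno(rbind(one$calls, one$calls),
              individuals = tibble::tibble(individual_id = c("d1", "d2"),
                                           population = "warm"))
  f1 <- generate_hatchery_cohort(geno_subset(two, 1:2),
                                 hatchery_config(n_offspring = 60,
                                                 selfing_rate = 1,
                                                 missing_rate = 0, seed = 9))
  f2 <- generate_hatchery_cohort(f1, hatchery_config(n_offspring = 60,
                                                     selfing_rate = 1,
                                                     missing_rate = 0,
                                                     seed = 10))
  expect_gt(fis(f2, n_boot = 100, seed = 1)$fis, 0)
})

test_that("selected-locus shifts move cohort frequencies", {
  donors <- random_geno(60, 40, p = 0.1, seed = 11)
  sel <- tibble::tibble(locus_id = c("L3", "L7"), delta = 0.4)
  f1 <- generate_hatchery_cohort(donors, hatchery_config(
    n_offspring = 200, selected_loci = sel, missing_rate = 0, seed = 12))
  p_o <- colMeans(f1$calls) / 2
  p_d <- colMeans(donors$calls, na.rm = TRUE) / 2
  expect_gt(p_o[3] - p_d[3], 0.2)
  expect_gt(p_o[7] - p_d[7], 0.2)
})

test_that("the full-study bundle has the designed shape", {
  b <- scenario_full_study(seed = 1, n_loci = 300)
  g <- b$genotypes
  tab <- table(g$individuals$population, g$individuals$cohort)
  expect_equal(tab["warm", "wild"], 100L)
  expect_equal(tab["cool", "wild"], 100L)
  expect_equal(tab["warm", "hatchery"], 62L)
  expect_equal(tab["cool", "hatchery"], 36L)
  expect_equal(length(b$truth$hatchery_selected), 15L)
  expect_equal(length(b$truth$provenance_divergent), 27L)
  expect_equal(length(intersect(b$truth$hatchery_selected,
                                b$truth$provenance_divergent)), 0L)
})

test_that("offspring He matches parental He after the drift correction", {
  diffs <- sapply(1:50, function(s) withr::with_seed(100 + s, {
    p <- runif(80, 0.1, 0.5)
    nd <- 50
    donors <- make_geno(matrix(rbinom(nd * 80, 2, rep(p, each = nd)),
                               nd, 80))
    f1 <- generate_hatchery_cohort(donors, hatchery_config(
      n_offspring = 200, contribution_concentration = Inf,
      selfing_rate = 0, missing_rate = 0, seed = s))
    p_d <- colMeans(donors$calls) / 2
    p_o <- colMeans(f1$calls) / 2
    he_d <- mean(2 * p_d * (1 - p_d))
    # conditional on the realised donors, per-offspring parent draws are
    # unbiased: the only expected He loss is the finite-offspring
    # frequency-estimation factor 1 - 1/(2 n)
    mean(2 * p_o * (1 - p_o)) - he_d * (1 - 1 / (2 * 200))
  }))
  tt <- t.test(diffs)
  expect_gt(tt$p.value, 0.01)
})

test_that("scenario files round-trip through the manifest", {
  dir <- withr::local_tempdir()
  b <- scenario_full_study(seed = 4, n_loci = 80)
  write_scenario(b, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 4)
  g <- read_genotypes(file.path(dir, man$genotypes))
  expect_identical(unname(g$calls), unname(b$genotypes$calls))
  expect_equal(length(man$hatchery_selected), 15L)
})
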