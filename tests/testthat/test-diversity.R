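test_that("observed heterozygosity matches direct counts", {
  g <- make_geno(matrix(c(0L, 1L, 1L, 2L), 4, 1))
  expect_equal(observed_heterozygosity(g)$ho, 0.5)
  expect_equal(mean_ho(observed_heterozygosity(g)), 0.5)

  g1 <- make_geno(matrix(1L, 3, 2))
  expect_equal(observed_heterozygosity(g1)$ho, c(1, 1))
  g2 <- make_geno(matrix(c(0L, 2L), 2, 1))
  expect_equal(observed_heterozygosity(g2)$ho, 0)
  expect_error(observed_heterozygosity(make_geno(matrix(NA_integer_, 2, 1))),
               "no valid calls")
})

test_that("expected heterozygosity and its unbiased correction", {
  g <- make_geno(matrix(c(0L, 1L, 1L, 2L), 4, 1))  # p = 0.5, n = 4
  he <- expected_heterozygosity(g)
  uhe <- expected_heterozygosity(g, unbiased = TRUE)
  expect_equal(he$he, 0.5)
  expect_equal(uhe$he, 2 * 0.5 * 0.5 * 8 / 7, tolerance = 1e-12)
  expect_equal(round(uhe$he, 4), 0.5714)

  mono <- make_geno(matrix(2L, 5, 1))
  expect_equal(expected_heterozygosity(mono)$he, 0)
})

test_that("uHe >= He and both are invariant to allele relabelling", {
  for (seed in 1:10) {
    g <- random_geno(8, 12, p = 0.3, miss = 0.15, seed = seed)
    he <- expected_heterozygosity(g)$he
    uhe <- expected_heterozygosity(g, unbiased = TRUE)$he
    expect_true(all(uhe >= he - 1e-12, na.rm = TRUE))
    flipped <- g
    flipped$calls <- 2L - g$calls
    expect_equal(expected_heterozygosity(flipped)$he, he)
  }
})

test_that("percent polymorphic loci counts segregating loci only", {
  fixed <- make_geno(matrix(rep(c(0L, 2L), each = 4), 4, 2))
  expect_equal(polymorphic_loci_pct(fixed), 0)

  g <- make_geno(cbind(c(0L, 0L, 1L), matrix(0L, 3, 3)))
  expect_equal(polymorphic_loci_pct(g), 25)
})

test_that("rarefied allelic richness matches the hypergeometric closed form", {
  # 7 ref + 1 alt copies, draw 4: AR = 1 + (1 - C(7,4)/C(8,4)) = 1.5
  both <- make_geno(matrix(rep(c(1L, 0L, 0L, 0L), 2), 8, 1),
                    population = rep(c("a", "b"), each = 4))
  ar <- rarefied_allelic_richness(both, "population", g_copies = 4)
  expect_equal(ar$ar, c(1.5, 1.5))

  fixed <- make_geno(matrix(0L, 6, 1), population = rep(c("a", "b"), 3))
  expect_equal(rarefied_allelic_richness(fixed, "population",
                                         g_copies = 4)$ar, c(1, 1))

  # g equal to all copies: both alleles certainly seen
  gb <- make_geno(matrix(c(1L, 1L, 0L, 2L), 4, 1),
                  population = rep("a", 4))
  expect_equal(hatchgen:::ar_closed_form(8, 4, 8), 2)
})

test_that("closed-form AR equals the empirical without-replacement mean", {
  cases <- list(c(7, 1, 4), c(6, 6, 5), c(9, 3, 6), c(11, 1, 10))
  for (cs in cases) {
    closed <- hatchgen:::ar_closed_form(cs[1] + cs[2], cs[2], cs[3])
    emp <- ar_empirical(cs[1], cs[2], cs[3], n_draws = 1e5, seed = 2)
    expect_equal(closed, emp, tolerance = 0.01)
  }
})

test_that("private alleles are counted per group against all others", {
  m <- matrix(0L, 4, 10)
  m[1:2, 1:3] <- 1L      # alt allele only in group A; ref shared everywhere
  ga <- geno(m, individuals = tibble::tibble(
    individual_id = paste0("i", 1:4),
    population = rep(c("A", "B"), each = 2)))
  pa <- private_alleles_pct(ga, "population")
  expect_equal(pa$pa_pct[pa$group == "A"], 30)
  expect_equal(pa$pa_pct[pa$group == "B"], 0)

  same <- geno(matrix(rep(c(0L, 1L, 2L, 1L), 4), 4, 4),
               individuals = tibble::tibble(
                 individual_id = paste0("i", 1:4),
                 population = rep(c("A", "B"), 2)))
  expect_true(all(private_alleles_pct(same, "population")$pa_pct == 0))
  expect_error(private_alleles_pct(ga, rep("A", 4)), ">= 2 groups")
})

test_that("FIS sign and extremes behave as heterozygote excess/deficit", {
  # all heterozygous: strong excess, FIS < 0
  allhet <- make_geno(matrix(1L, 10, 5))
  expect_lt(fis(allhet, n_boot = 50, seed = 1)$fis, 0)

  # complete heterozygote deficit: FIS = 1
  deficit <- make_geno(matrix(rep(c(0L, 0L, 2L, 2L), 5), 4, 5))
  expect_equal(fis(deficit, n_boot = 50, seed = 1)$fis, 1)

  # near-exact HW proportions at many loci: FIS ~ 0
  hw <- make_geno(matrix(rep(c(rep(0L, 25), rep(1L, 50), rep(2L, 25)), 20),
                         100, 20))
  f <- fis(hw, n_boot = 200, seed = 1)
  expect_lt(abs(f$fis), 0.02)
  expect_error(fis(make_geno(matrix(0L, 4, 3))), "no polymorphic")
})

test_that("FIS bootstrap CI brackets the point estimate", {
  g <- random_geno(30, 40, p = 0.3, seed = 3)
  f <- fis(g, n_boot = 300, seed = 2)
  expect_lte(f$ci_lo, f$fis)
  expect_gte(f$ci_hi, f$fis)
  expect_equal(f$n_boot, 300L)
})

test_that("diversity report is order-invariant and flags empty subsets", {
  b <- scenario_full_study(seed = 2, n_loci = 200)
  g <- b$genotypes
  rep1 <- diversity_report(g, "population_cohort", n_boot = 50, seed = 1)
  perm <- withr::with_seed(4, sample(n_individuals(g)))
  g2 <- geno_subset(g, individuals = perm)
  rep2 <- diversity_report(g2, "population_cohort", n_boot = 50, seed = 1)
  expect_equal(rep1$ho, rep2$ho, tolerance = 1e-12)
  expect_equal(rep1$he, rep2$he, tolerance = 1e-12)

  part0 <- structure(list(neutral = g$loci$locus_id,
                          provenance = character(0),
                          hatchery = character(0),
                          overlap = character(0)), class = "locus_partition")
  rep3 <- diversity_report(g, "population_cohort", partition = part0,
                           n_boot = 20, seed = 1)
  expect_true(all(rep3$empty[rep3$subset == "provenance"]))
  expect_false(any(rep3$empty[rep3$subset == "neutral"]))
})

test_that("the synthetic bundle shows the designed diversity contrast", {
  b <- scenario_full_study(seed = 5)
  g <- b$genotypes
  wild <- geno_subset(g, g$individuals$cohort == "wild")
  neutral <- setdiff(g$loci$locus_id,
                     c(b$truth$hatchery_selected, b$truth$provenance_divergent))
  he_cool <- mean_ho(expected_heterozygosity(
    wild, wild$individuals$population == "cool", neutral))
  he_warm <- mean_ho(expected_heterozygosity(
    wild, wild$individuals$population == "warm", neutral))
  expect_gt(he_cool, he_warm)
  expect_gt(he_cool / he_warm, 1.8)
})
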