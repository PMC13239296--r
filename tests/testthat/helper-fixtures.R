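# Shared fixtures and independent oracles used across test files.

# Small genotype object from a plain matrix, with optional metadata.
make_geno <- function(calls, population = NULL, cohort = NULL, ...) {
  calls <- as.matrix(calls)
  ind <- tibble::tibble(individual_id = paste0("i", seq_len(nrow(calls))))
  if (!is.null(population)) ind$population <- population
  if (!is.null(cohort)) ind$cohort <- cohort
  geno(calls, individuals = ind, ...)
}

# Random genotype matrix with given missingness, reproducible.
random_geno <- function(n, L, p = 0.3, miss = 0, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n * L, 2, p), n, L)
    if (miss > 0) m[runif(n * L) < miss] <- NA_integer_
    make_geno(m)
  })
}

# Independent Weir-Cockerham oracle via nested ANOVA mean squares on allele
# indicators: a = (MSP - MSI)/(2 nc), b = (MSI - MSG)/2, c = MSG, a route
# genuinely different from the package's direct component formulas.
wc_theta_aov <- function(calls_a, calls_b) {
  per_locus <- function(xa, xb) {
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) return(c(a = NA, b = NA, c = NA))
    # two gene copies per individual; heterozygote = one of each allele
    expand <- function(x) t(vapply(x, function(d)
      switch(as.character(d), `0` = c(0, 0), `1` = c(1, 0), `2` = c(1, 1)),
      numeric(2)))
    ga <- expand(xa); gb <- expand(xb)
    y <- c(t(ga), t(gb))
    ind <- factor(rep(seq_len(length(xa) + length(xb)), each = 2))
    pop <- factor(rep(c("A", "B"), times = 2 * c(length(xa), length(xb))))
    n_i <- c(length(xa), length(xb))
    r <- 2
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    ss_total <- sum((y - mean(y))^2)
    mu_pop <- tapply(y, pop, mean)
    ss_pop <- sum(2 * n_i * (mu_pop - mean(y))^2)
    mu_ind <- tapply(y, ind, mean)
    ss_ind <- sum(2 * (mu_ind - mu_pop[as.character(pop[seq(1, length(y), 2)])])^2)
    ss_gam <- ss_total - ss_pop - ss_ind
    msp <- ss_pop / (r - 1)
    msi <- ss_ind / (sum(n_i) - r)
    msg <- ss_gam / sum(n_i)
    c(a = (msp - msi) / (2 * nc), b = (msi - msg) / 2, c = msg)
  }
  comps <- vapply(seq_len(ncol(calls_a)), function(j)
    per_locus(calls_a[, j], calls_b[, j]), numeric(3))
  keep <- !is.na(comps[1, ])
  sum(comps[1, keep]) / sum(comps[, keep])
}

# Empirical rarefaction oracle: mean distinct-allele count over explicit
# without-replacement draws of g copies.
ar_empirical <- function(n_ref, n_alt, g, n_draws = 1e5, seed = 1) {
  pool <- rep(c(0L, 1L), times = c(n_ref, n_alt))
  withr::with_seed(seed, {
    mean(replicate(n_draws, length(unique(sample(pool, g)))))
  })
}

# Procrustes RMS after optimal rotation/reflection/translation (no scaling
# needed for exact recovery checks).
procrustes_rms <- function(x, y) {
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  rot <- s$u %*% t(s$v)
  sqrt(mean((yc %*% rot - xc)^2))
}

# Null RDA background plus an optional planted locus perfectly separating
# the two predictor levels.
rda_fixture <- function(n = 100, L = 500, plant = TRUE, seed = 1) {
  withr::with_seed(seed, {
    pred <- rep(c("wild", "hatchery"), each = n / 2)
    p <- runif(L, 0.1, 0.5)
    m <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
    if (plant) m[, 1] <- ifelse(pred == "wild", 0L, 2L)
    list(g = geno(m, individuals = tibble::tibble(
      individual_id = paste0("i", 1:n), cohort = pred)), pred = pred)
  })
}

# Wright-Fisher cohort of size N after `gens` generations of random mating,
# founded from HW draws at uniform frequencies.
wf_population <- function(N = 50, L = 500, gens = 12, p_lo = 0.2, p_hi = 0.8,
                          seed = 1) {
  withr::with_seed(seed, {
    p <- runif(L, p_lo, p_hi)
    founders <- make_geno(matrix(rbinom(N * L, 2, rep(p, each = N)), nrow = N))
    cfg <- sim_config(donor_counts = 2, n_offspring = N, generations = gens,
                      checkpoints = gens, n_boot = 1)
    tr <- simulate_generations(founders, cfg, keep_genotypes = TRUE)
    attr(tr, "genotypes")[[as.character(gens)]]
  })
}
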