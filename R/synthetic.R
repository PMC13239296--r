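#' Configuration for the synthetic wild-population generator
#'
#' Defaults emulate a DArTseq SNP panel for two differentiated kelp
#' populations: 2 populations of 100 donors, 1600 biallelic loci, target
#' Wright's F of 0.08 between populations, low ancestral minor-allele
#' frequencies (most reduced-representation SNPs in this system are rare-
#' allele loci, giving mean expected heterozygosity on the 0.01 scale),
#' 18.3% missing calls, mean read depth 6.79, and a fraction of loci
#' sharing a sequenced fragment (secondaries).
#'
#' `he_scale` shrinks the ancestral allele frequencies per population to
#' mimic unequal standing diversity (e.g. a warm-edge population holding a
#' half to a third of the diversity of a cool population) without modelling
#' demography.
#'
#' @param n_pops Number of populations.
#' @param n_ind_per_pop Individuals per population.
#' @param n_loci Number of loci.
#' @param fst_target Wright's F in `[0, 1)` used by the Balding–Nichols
#'   draw.
#' @param maf_lo,maf_hi Ancestral alternate-allele frequency range
#'   (uniform).
#' @param he_scale Per-population multiplier on the ancestral frequency
#'   (length `n_pops`).
#' @param missing_rate Fraction of calls set missing.
#' @param depth_mean,depth_sd Mean read-depth distribution (gamma-
#'   parameterised by mean and sd).
#' @param reproducibility_min_gen Lower bound of the uniform
#'   reproducibility score.
#' @param fraction_secondaries Fraction of loci assigned a shared
#'   `clone_id` (a second SNP on an existing fragment).
#' @param pop_names Population labels.
#' @param seed RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_pops = 2, n_ind_per_pop = 100, n_loci = 1600,
                         fst_target = 0.08, maf_lo = 0.001, maf_hi = 0.018,
                         he_scale = rep(1, n_pops), missing_rate = 0.183,
                         depth_mean = 6.79, depth_sd = 1.5,
                         reproducibility_min_gen = 0.96,
                         fraction_secondaries = 0.1,
                         pop_names = c("warm", "cool"), seed = 1L) {
  stopifnot(fst_target >= 0, fst_target < 1,
            missing_rate >= 0, missing_rate <= 1,
            maf_lo <= maf_hi, length(he_scale) == n_pops,
            length(pop_names) >= n_pops)
  structure(list(n_pops = n_pops, n_ind_per_pop = n_ind_per_pop,
                 n_loci = n_loci, fst_target = fst_target,
                 maf_lo = maf_lo, maf_hi = maf_hi, he_scale = he_scale,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 depth_sd = depth_sd,
                 reproducibility_min_gen = reproducibility_min_gen,
                 fraction_secondaries = fraction_secondaries,
                 pop_names = pop_names[seq_len(n_pops)],
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate wild donor populations under the Balding–Nichols model
#'
#' Per locus an ancestral frequency `p` is drawn uniformly; each
#' population's frequency is drawn from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with `F = fst_target`
#' (identical frequencies when `F = 0`), after applying the population's
#' `he_scale` to the ancestral frequency. Genotypes are Hardy–Weinberg
#' draws within population; DArT-style metadata (depth, reproducibility,
#' clone ids) and uniform missingness are injected.
#'
#' @param cfg A [synth_config()].
#' @return A [geno()] object with `cohort = "wild"` and true per-population
#'   frequencies in attribute `"truth"`.
#' @export
generate_wild_populations <- function(cfg = synth_config()) {
  withr::with_seed(cfg$seed, {
    L <- cfg$n_loci
    p_anc <- stats::runif(L, cfg$maf_lo, cfg$maf_hi)
    f <- cfg$fst_target
    pop_freq <- matrix(NA_real_, L, cfg$n_pops)
    for (k in seq_len(cfg$n_pops)) {
      pk <- pmin(pmax(p_anc * cfg$he_scale[k], 0), 1)
      pop_freq[, k] <- if (f == 0) pk else
        stats::rbeta(L, pk * (1 - f) / f, (1 - pk) * (1 - f) / f)
    }
    n <- cfg$n_ind_per_pop
    calls <- do.call(rbind, lapply(seq_len(cfg$n_pops), function(k) {
      matrix(stats::rbinom(n * L, 2, rep(pop_freq[, k], each = n)), nrow = n)
    }))
    # missingness
    nas <- stats::runif(length(calls)) < cfg$missing_rate
    calls[nas] <- NA_integer_

    # locus metadata
    depth_shape <- (cfg$depth_mean / cfg$depth_sd)^2
    depth <- stats::rgamma(L, shape = depth_shape,
                           rate = depth_shape / cfg$depth_mean)
    repro <- stats::runif(L, cfg$reproducibility_min_gen, 1)
    clone <- paste0("frag", seq_len(L))
    n_sec <- floor(cfg$fraction_secondaries * L)
    if (n_sec > 0 && L > n_sec) {
      sec <- sample(seq_len(L), n_sec)
      clone[sec] <- clone[sample(setdiff(seq_len(L), sec), n_sec,
                                 replace = TRUE)]
    }
    loci <- tibble::tibble(
      locus_id = sprintf("L%04d", seq_len(L)),
      clone_id = clone, read_depth = depth, reproducibility = repro,
      ref_allele = "A", alt_allele = "T")
    individuals <- tibble::tibble(
      individual_id = paste0(rep(cfg$pop_names, each = n), "_w",
                             rep(seq_len(n), cfg$n_pops)),
      population = rep(cfg$pop_names, each = n),
      cohort = "wild")
    g <- geno(calls, loci = loci, individuals = individuals)
    attr(g, "truth") <- list(p_ancestral = p_anc, pop_freq = pop_freq)
    g
  })
}

#' Configuration for a mass-spawned hatchery cohort
#'
#' @param n_offspring Cohort size.
#' @param contribution_concentration Dirichlet concentration for per-donor
#'   reproductive weights; small values give strong parental skew, `Inf`
#'   gives equal contributions.
#' @param selfing_rate Probability that an offspring's sire is its dam.
#' @param selected_loci Tibble/data frame with `locus_id` and `delta`
#'   (allele-frequency shift applied post hoc at "hatchery-selected" loci),
#'   or `NULL`.
#' @param missing_rate Missing-call rate injected into the cohort.
#' @param seed RNG seed.
#' @return A list of class `hatchery_config`.
#' @export
hatchery_config <- function(n_offspring = 50,
                            contribution_concentration = 1,
                            selfing_rate = 0, selected_loci = NULL,
                            missing_rate = 0.183, seed = 1L) {
  stopifnot(selfing_rate >= 0, selfing_rate <= 1,
            contribution_concentration > 0)
  structure(list(n_offspring = as.integer(n_offspring),
                 contribution_concentration = contribution_concentration,
                 selfing_rate = selfing_rate,
                 selected_loci = selected_loci,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "hatchery_config")
}

#' Generate a hatchery F1 cohort from wild donors
#'
#' Each offspring draws a dam from Dirichlet-weighted donor probabilities;
#' with probability `selfing_rate` the sire is the same individual,
#' otherwise a different donor is drawn from the same weights. Transmission
#' is Mendelian per unlinked locus (missing donor calls are imputed from
#' donor-pool frequencies first). Genotypes at `selected_loci` are then
#' resampled from frequencies shifted by `delta`, emulating loci responding
#' to the hatchery environment. Offspring are labelled
#' `cohort = "hatchery"` with ages assigned round-robin over 5, 7, 9
#' months.
#'
#' @param donors A [geno()] object (>= 2 individuals).
#' @param hcfg A [hatchery_config()].
#' @return A [geno()] object; attribute `"truth"` records realised parental
#'   weights and the distinct parents used.
#' @export
generate_hatchery_cohort <- function(donors, hcfg = hatchery_config()) {
  if (n_individuals(donors) < 2) stop(">= 2 donors required", call. = FALSE)
  withr::with_seed(hcfg$seed, {
    nd <- n_individuals(donors)
    w <- if (is.infinite(hcfg$contribution_concentration)) rep(1, nd) else
      stats::rgamma(nd, shape = hcfg$contribution_concentration)
    if (sum(w) == 0) w <- rep(1, nd)
    w <- w / sum(w)

    m <- impute_pool(donors$calls)
    no <- hcfg$n_offspring
    dam <- sample.int(nd, no, replace = TRUE, prob = w)
    self <- stats::runif(no) < hcfg$selfing_rate
    sire <- integer(no)
    sire[self] <- dam[self]
    for (i in which(!self)) {
      repeat {
        s <- sample.int(nd, 1, prob = w)
        if (s != dam[i] || nd == 1) break
      }
      sire[i] <- s
    }
    dm <- m[dam, , drop = FALSE]
    sm <- m[sire, , drop = FALSE]
    L <- ncol(m)
    off <- matrix(stats::rbinom(no * L, 1, dm / 2) +
                    stats::rbinom(no * L, 1, sm / 2), nrow = no)

    if (!is.null(hcfg$selected_loci) && nrow(hcfg$selected_loci) > 0) {
      pos <- match(hcfg$selected_loci$locus_id, donors$loci$locus_id)
      if (anyNA(pos)) stop("selected_loci ids not found in donors",
                           call. = FALSE)
      p0 <- colSums(m[, pos, drop = FALSE]) / (2 * nd)
      p1 <- pmin(pmax(p0 + hcfg$selected_loci$delta, 0), 1)
      for (k in seq_along(pos)) {
        off[, pos[k]] <- stats::rbinom(no, 2, p1[k])
      }
    }

    nas <- stats::runif(length(off)) < hcfg$missing_rate
    off[nas] <- NA_integer_

    pop <- unique(donors$individuals$population)
    pop <- if (length(pop) == 1) pop else NA_character_
    g <- geno(off, loci = donors$loci, individuals = tibble::tibble(
      individual_id = paste0(ifelse(is.na(pop), "hx", pop), "_f1_",
                             seq_len(no)),
      population = pop, cohort = "hatchery",
      age_months = rep(c(5L, 7L, 9L), length.out = no)))
    attr(g, "truth") <- list(weights = w, dam = dam, sire = sire,
                             n_distinct_parents = length(unique(c(dam, sire))))
    g
  })
}

#' Full synthetic study bundle: two wild populations and their F1 cohorts
#'
#' One call yields a dataset shaped like a two-provenance hatchery study:
#' warm and cool wild donor populations (n = 100 each; the warm population
#' carries roughly a third of the cool population's diversity; background
#' differentiation F = 0.08), 27 designated provenance-divergent loci
#' (extra frequency divergence injected between the wild populations), and
#' mass-spawned F1 cohorts (warm n = 62 with strong parental skew and
#' elevated selfing; cool n = 36 with milder skew) sharing 15 designated
#' hatchery-selected loci.
#'
#' @param seed Master seed.
#' @param n_loci Number of loci.
#' @param n_hatchery Named vector: F1 cohort sizes.
#' @param concentration Named vector: Dirichlet concentrations per
#'   provenance.
#' @param selfing Named vector: selfing rates per provenance.
#' @param delta_hatchery Frequency shift at hatchery-selected loci.
#' @param delta_provenance Frequency shift injected at provenance-divergent
#'   loci.
#' @return A list of class `study_bundle`: `genotypes` (all four cohorts in
#'   one [geno()]; groups identified by `population` x `cohort`) and
#'   `truth` (designated locus ids, per-cohort parental weights, generator
#'   parameters).
#' @export
scenario_full_study <- function(seed = 1L, n_loci = 1600,
                                n_hatchery = c(warm = 62, cool = 36),
                                concentration = c(warm = 0.15, cool = 1),
                                selfing = c(warm = 0.3, cool = 0.1),
                                delta_hatchery = 0.3,
                                delta_provenance = 0.35) {
  seed <- as.integer(seed)
  cfg <- synth_config(n_loci = n_loci, he_scale = c(0.35, 1),
                      pop_names = c("warm", "cool"), seed = seed)
  wild <- generate_wild_populations(cfg)

  # designate provenance-divergent loci: resample warm wild genotypes from
  # frequencies pushed away from the cool population
  withr::with_seed(seed + 7L, {
    prov_idx <- sample.int(n_loci, 27)
    warm_rows <- which(wild$individuals$population == "warm")
    truth_freq <- attr(wild, "truth")$pop_freq
    for (k in prov_idx) {
      p_new <- min(1, truth_freq[k, 2] + delta_provenance)
      wild$calls[warm_rows, k] <- ifelse(
        is.na(wild$calls[warm_rows, k]), NA_integer_,
        stats::rbinom(length(warm_rows), 2, p_new))
    }
    hatch_idx <- sample(setdiff(seq_len(n_loci), prov_idx), 15)
  })
  hatch_ids <- wild$loci$locus_id[hatch_idx]
  prov_ids <- wild$loci$locus_id[prov_idx]
  sel <- tibble::tibble(locus_id = hatch_ids, delta = delta_hatchery)

  cohorts <- list(wild)
  truth_parents <- list()
  for (popn in c("warm", "cool")) {
    donors <- geno_subset(wild,
                          wild$individuals$population == popn &
                            wild$individuals$cohort == "wild")
    hc <- hatchery_config(
      n_offspring = n_hatchery[[popn]],
      contribution_concentration = concentration[[popn]],
      selfing_rate = selfing[[popn]], selected_loci = sel,
      missing_rate = cfg$missing_rate,
      seed = (seed + match(popn, c("warm", "cool")) * 101L) %% 2147483647L)
    f1 <- generate_hatchery_cohort(donors, hc)
    truth_parents[[popn]] <- attr(f1, "truth")
    cohorts[[length(cohorts) + 1]] <- f1
  }
  g_all <- do.call(geno_rbind, cohorts)
  structure(list(
    genotypes = g_all,
    truth = list(hatchery_selected = hatch_ids,
                 provenance_divergent = prov_ids,
                 parents = truth_parents,
                 config = cfg, seed = seed)),
    class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle> seed = ", x$truth$seed, "\n", sep = "")
  print(x$genotypes)
  cat("  designated: ", length(x$truth$provenance_divergent),
      " provenance-divergent, ", length(x$truth$hatchery_selected),
      " hatchery-selected loci\n", sep = "")
  invisible(x)
}

#' Write a study bundle to disk (genotype-csv + manifest)
#'
#' Emits the genotype CSV, its locus-metadata sidecar, and a JSON manifest
#' naming the files, the seed and the designated locus sets, so a full
#' pipeline run can be reproduced from disk.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gpath <- file.path(dir, "genotypes.csv")
  write_genotypes(bundle$genotypes, gpath)
  manifest <- list(
    genotypes = "genotypes.csv",
    locus_metadata = "genotypes.loci.csv",
    seed = bundle$truth$seed,
    hatchery_selected = bundle$truth$hatchery_selected,
    provenance_divergent = bundle$truth$provenance_divergent)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
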