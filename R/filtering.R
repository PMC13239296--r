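#' Configuration for the sequential SNP/individual filtering pipeline
#'
#' Defaults reproduce a standard DArTseq cleaning workflow for reduced-
#' representation SNP data: depth window 5–12, reproducibility at least 0.96,
#' one SNP retained per sequenced fragment ("secondaries" removed at random),
#' loci with minor allele frequency at or below 1% excluded, then missingness
#' filters (loci with < 90% missing data kept, individuals with < 80% missing
#' data kept) and removal of monomorphic loci.
#'
#' The missingness thresholds follow the literal "kept if below" convention;
#' they are unusually lenient (a locus typed in just over 10% of individuals
#' survives), so both are exposed here rather than hard-coded.
#'
#' @param depth_min,depth_max Inclusive mean read-depth window.
#' @param reproducibility_min Minimum DArT reproducibility score.
#' @param drop_secondaries Keep one locus per `clone_id`?
#' @param maf_exclude_at_or_below Loci with MAF less than or equal to this are
#'   dropped (the boundary itself is excluded).
#' @param locus_missing_max Loci with missingness `>=` this fraction are
#'   dropped.
#' @param individual_missing_max Individuals with missingness `>=` this
#'   fraction are dropped.
#' @param drop_monomorphic Drop loci with no segregating allele?
#' @param rng_seed Seed for the randomised secondary removal.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(depth_min = 5, depth_max = 12,
                          reproducibility_min = 0.96,
                          drop_secondaries = TRUE,
                          maf_exclude_at_or_below = 0.01,
                          locus_missing_max = 0.90,
                          individual_missing_max = 0.80,
                          drop_monomorphic = TRUE,
                          rng_seed = 1L) {
  stopifnot(depth_min <= depth_max,
            reproducibility_min >= 0, reproducibility_min <= 1,
            maf_exclude_at_or_below >= 0, maf_exclude_at_or_below <= 1,
            locus_missing_max >= 0, locus_missing_max <= 1,
            individual_missing_max >= 0, individual_missing_max <= 1)
  structure(list(
    depth_min = depth_min, depth_max = depth_max,
    reproducibility_min = reproducibility_min,
    drop_secondaries = drop_secondaries,
    maf_exclude_at_or_below = maf_exclude_at_or_below,
    locus_missing_max = locus_missing_max,
    individual_missing_max = individual_missing_max,
    drop_monomorphic = drop_monomorphic,
    rng_seed = as.integer(rng_seed)
  ), class = "filter_config")
}

#' Sequential SNP and individual filtering
#'
#' Applies the filtering stages in a fixed order, each on the output of the
#' previous one:
#'
#' 1. read depth inside `[depth_min, depth_max]`
#' 2. reproducibility `>= reproducibility_min`
#' 3. one locus per `clone_id`, chosen by seeded RNG (secondaries removed)
#' 4. loci with MAF `<= maf_exclude_at_or_below` dropped (MAF over all
#'    retained individuals pooled)
#' 5. loci with missingness `>= locus_missing_max` dropped, then individuals
#'    with missingness `>= individual_missing_max` dropped
#' 6. monomorphic loci dropped
#'
#' @param g A [geno()] object.
#' @param cfg A [filter_config()].
#' @return A list with `genotypes` (the filtered [geno()]) and `log`, a
#'   tibble with one row per stage (`stage`, `loci_before`, `loci_after`,
#'   `individuals_before`, `individuals_after`).
#' @export
apply_filters <- function(g, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  validate_geno(g)
  log <- list()
  note <- function(stage, before, g2) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage,
      loci_before = ncol(before$calls), loci_after = ncol(g2$calls),
      individuals_before = nrow(before$calls),
      individuals_after = nrow(g2$calls))
    g2
  }

  if (!is.na(cfg$depth_min)) {
    if (all(is.na(g$loci$read_depth)) && ncol(g$calls) > 0) {
      stop("filter stage 'read_depth' enabled but loci metadata field ",
           "'read_depth' is absent", call. = FALSE)
    }
    keep <- !is.na(g$loci$read_depth) &
      g$loci$read_depth >= cfg$depth_min & g$loci$read_depth <= cfg$depth_max
    g <- note("read_depth", g, geno_subset(g, loci = keep))
  }

  if (!is.na(cfg$reproducibility_min)) {
    if (all(is.na(g$loci$reproducibility)) && ncol(g$calls) > 0) {
      stop("filter stage 'reproducibility' enabled but loci metadata field ",
           "'reproducibility' is absent", call. = FALSE)
    }
    keep <- !is.na(g$loci$reproducibility) &
      g$loci$reproducibility >= cfg$reproducibility_min
    if (ncol(g$calls) == 0) keep <- logical(0)
    g <- note("reproducibility", g, geno_subset(g, loci = keep))
  }

  if (isTRUE(cfg$drop_secondaries)) {
    keep <- withr::with_seed(cfg$rng_seed, {
      idx <- seq_len(ncol(g$calls))
      shuffled <- sample(idx)
      picked <- shuffled[!duplicated(g$loci$clone_id[shuffled])]
      sort(picked)
    })
    g <- note("secondaries", g, geno_subset(g, loci = keep))
  }

  if (!is.na(cfg$maf_exclude_at_or_below)) {
    maf <- minor_allele_frequency(g)$maf
    keep <- !is.na(maf) & maf > cfg$maf_exclude_at_or_below
    g <- note("maf", g, geno_subset(g, loci = keep))
  }

  lmiss <- colMeans(is.na(g$calls))
  g <- note("locus_missingness", g,
            geno_subset(g, loci = lmiss < cfg$locus_missing_max))
  imiss <- rowMeans(is.na(g$calls))
  if (ncol(g$calls) == 0) imiss <- rep(0, nrow(g$calls))
  g <- note("individual_missingness", g,
            geno_subset(g, individuals = imiss < cfg$individual_missing_max))

  if (isTRUE(cfg$drop_monomorphic)) {
    maf <- minor_allele_frequency(g)$maf
    keep <- !is.na(maf) & maf > 0
    g <- note("monomorphic", g, geno_subset(g, loci = keep))
  }

  list(genotypes = g, log = dplyr::bind_rows(log))
}
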