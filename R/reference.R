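#' Reference diversity metrics for the emulated study system
#'
#' A small reference table of per-cohort neutral-locus diversity metrics
#' (percent polymorphic loci, rarefied allelic richness, private alleles,
#' observed/expected heterozygosity, FIS) for the warm/cool wild donor
#' populations and their hatchery F1 cohorts that the synthetic generator
#' emulates, together with the locus bookkeeping (total SNPs, provenance
#' and hatchery outlier counts, neutral remainder). Used for table-derived
#' summaries such as the hatchery-induced decline in observed
#' heterozygosity.
#'
#' @return `reference_cohort_metrics()`: a tibble with one row per
#'   population x cohort; `reference_locus_counts()`: a named integer
#'   vector.
#' @export
reference_cohort_metrics <- function() {
  path <- system.file("extdata", "reference_cohort_metrics.csv",
                      package = "hatchgen", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname reference_cohort_metrics
#' @export
reference_locus_counts <- function() {
  path <- system.file("extdata", "reference_locus_counts.csv",
                      package = "hatchgen", mustWork = TRUE)
  df <- utils::read.csv(path)
  stats::setNames(as.integer(df$count), df$quantity)
}

#' Table-derived hatchery impact summaries
#'
#' Computed from [reference_cohort_metrics()] and
#' [reference_locus_counts()]:
#' outlier percentages (outliers / total SNPs), the mean relative decline
#' in neutral observed heterozygosity from wild to hatchery cohorts
#' (averaged over provenances), and the relative decline in the warm
#' population's percent polymorphic loci.
#'
#' @return A named list of percentages.
#' @export
reference_impact_summaries <- function() {
  m <- reference_cohort_metrics()
  k <- reference_locus_counts()
  decline <- function(pop, col) {
    w <- m[m$population == pop & m$cohort == "wild", ][[col]]
    h <- m[m$population == pop & m$cohort == "hatchery", ][[col]]
    100 * (w - h) / w
  }
  list(
    provenance_outlier_pct = 100 * k[["provenance_outliers"]] / k[["snps_total"]],
    hatchery_outlier_pct = 100 * k[["hatchery_outliers"]] / k[["snps_total"]],
    neutral_ho_decline_pct = mean(c(decline("warm", "ho"),
                                    decline("cool", "ho"))),
    warm_neutral_pl_decline_pct = decline("warm", "pl_pct")
  )
}
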