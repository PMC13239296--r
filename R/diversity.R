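#' Observed heterozygosity
#'
#' Per locus, the fraction of non-missing individuals carrying a heterozygous
#' call; the summary value is the mean over loci with at least one valid
#' call.
#'
#' @inheritParams allele_frequencies
#' @return A tibble (`locus_id`, `ho`, `n_valid`) with attribute `mean`,
#'   also returned by [mean_ho()].
#' @export
observed_heterozygosity <- function(g, group = NULL, loci = NULL) {
  ii <- resolve_group(g, group)
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  m <- g$calls[ii, jj, drop = FALSE]
  n_valid <- colSums(!is.na(m))
  if (length(n_valid) && all(n_valid == 0)) {
    stop("no valid calls at any locus in this group", call. = FALSE)
  }
  ho <- ifelse(n_valid > 0, colSums(m == 1L, na.rm = TRUE) / n_valid, NA_real_)
  out <- tibble::tibble(locus_id = g$loci$locus_id[jj], ho = unname(ho),
                        n_valid = unname(as.integer(n_valid)))
  attr(out, "mean") <- mean(out$ho, na.rm = TRUE)
  out
}

#' Expected heterozygosity (2pq), optionally sample-size-unbiased
#'
#' `He = 2 p (1 - p)` from the group allele frequency; with
#' `unbiased = TRUE` each locus is rescaled by `2n / (2n - 1)` where `n` is
#' the number of valid individuals at the locus (Nei's unbiased gene
#' diversity).
#'
#' @inheritParams allele_frequencies
#' @param unbiased Apply the small-sample correction?
#' @return A tibble (`locus_id`, `he`, `n_valid`) with attribute `mean`.
#' @export
expected_heterozygosity <- function(g, group = NULL, loci = NULL,
                                    unbiased = FALSE) {
  af <- allele_frequencies(g, group, loci)
  if (nrow(af) && all(af$undefined)) {
    stop("no valid calls at any locus in this group", call. = FALSE)
  }
  he <- 2 * af$p_alt * (1 - af$p_alt)
  if (unbiased) {
    he <- ifelse(af$n_valid > 0, he * (2 * af$n_valid) / (2 * af$n_valid - 1),
                 NA_real_)
  }
  out <- tibble::tibble(locus_id = af$locus_id, he = he, n_valid = af$n_valid)
  attr(out, "mean") <- mean(out$he, na.rm = TRUE)
  out
}

#' Mean of a per-locus metric table
#' @param x Tibble returned by a per-locus metric function.
#' @return Numeric scalar mean over defined loci.
#' @export
mean_ho <- function(x) attr(x, "mean")

#' Percentage of polymorphic loci
#'
#' A locus is polymorphic in a group when both alleles are observed there.
#' The denominator is the number of subset loci with at least one valid call
#' in the group (a convention sensitive to sample size for rare alleles).
#'
#' @inheritParams allele_frequencies
#' @return Percentage in `[0, 100]`.
#' @export
polymorphic_loci_pct <- function(g, group = NULL, loci = NULL) {
  af <- allele_frequencies(g, group, loci)
  af <- af[!af$undefined, ]
  if (nrow(af) == 0) stop("no valid calls at any locus in this group",
                          call. = FALSE)
  100 * mean(af$p_alt > 0 & af$p_alt < 1)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random draw of `g_copies` gene
#' copies without replacement, averaged over loci
#' (`sum_a [1 - C(N - N_a, g) / C(N, g)]` with `N` valid copies and `N_a`
#' copies of allele `a`). Loci with fewer than `g_copies` valid copies in any
#' group are dropped from the comparison and reported.
#'
#' @param g A [geno()] object.
#' @param grouping Group specification (metadata column name, factor, or
#'   named list of id vectors), see [diversity_report()].
#' @param loci Optional locus subset.
#' @param g_copies Rarefaction size in gene copies (`>= 2`). Default `NULL`
#'   uses the smallest valid copy count over all loci and groups.
#' @return A tibble with `group`, `ar`, `n_loci_used`, `g_copies`.
#' @export
rarefied_allelic_richness <- function(g, grouping, loci = NULL,
                                      g_copies = NULL) {
  groups <- resolve_groups(g, grouping)
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  copies <- sapply(groups, function(ii)
    2 * colSums(!is.na(g$calls[ii, jj, drop = FALSE])))
  copies <- matrix(copies, nrow = length(jj))
  if (is.null(g_copies)) g_copies <- max(2, min(copies))
  if (g_copies < 2) stop("g_copies must be >= 2", call. = FALSE)
  usable <- apply(copies >= g_copies, 1, all)
  if (!any(usable)) {
    stop("rarefaction size ", g_copies, " exceeds valid copies at every locus",
         call. = FALSE)
  }
  res <- purrr::imap_dfr(groups, function(ii, label) {
    m <- g$calls[ii, jj[usable], drop = FALSE]
    n_valid <- colSums(!is.na(m))
    N <- 2 * n_valid
    n_alt <- colSums(m, na.rm = TRUE)
    ar_locus <- ar_closed_form(N, n_alt, g_copies)
    tibble::tibble(group = label, ar = mean(ar_locus),
                   n_loci_used = sum(usable), g_copies = g_copies)
  })
  res
}

# Hypergeometric closed form: expected allele count in g copies drawn
# without replacement from N copies of which n_alt are the alternate allele.
ar_closed_form <- function(N, n_alt, g_copies) {
  p_alt_seen <- 1 - exp(lchoose(N - n_alt, g_copies) - lchoose(N, g_copies))
  p_ref_seen <- 1 - exp(lchoose(n_alt, g_copies) - lchoose(N, g_copies))
  p_alt_seen + p_ref_seen
}

#' Percentage of loci carrying private alleles
#'
#' Per group, the percentage of subset loci at which some allele observed in
#' that group is observed in no other group. The denominator is the number of
#' subset loci (Table-style "PA (%)" scale).
#'
#' @inheritParams rarefied_allelic_richness
#' @return A tibble with `group`, `pa_pct`, `n_private_loci`, `n_loci`.
#' @export
private_alleles_pct <- function(g, grouping, loci = NULL) {
  groups <- resolve_groups(g, grouping)
  if (length(groups) < 2) stop(">= 2 groups required for private alleles",
                               call. = FALSE)
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  # presence[group, locus, allele]: is the allele observed in the group?
  pres <- lapply(groups, function(ii) {
    m <- g$calls[ii, jj, drop = FALSE]
    alt <- colSums(m, na.rm = TRUE) > 0
    ref <- colSums(2L - m, na.rm = TRUE) > 0
    cbind(ref = ref, alt = alt)
  })
  purrr::imap_dfr(groups, function(ii, label) {
    others <- pres[setdiff(names(pres), label)]
    other_ref <- Reduce(`|`, lapply(others, function(x) x[, "ref"]))
    other_alt <- Reduce(`|`, lapply(others, function(x) x[, "alt"]))
    mine <- pres[[label]]
    private <- (mine[, "ref"] & !other_ref) | (mine[, "alt"] & !other_alt)
    tibble::tibble(group = label,
                   pa_pct = 100 * sum(private) / length(jj),
                   n_private_loci = sum(private),
                   n_loci = length(jj))
  })
}

#' Inbreeding coefficient FIS with a locus bootstrap confidence interval
#'
#' `FIS = 1 - mean(Ho) / mean(uHe)` over polymorphic loci (ratio of means
#' across loci, with unbiased expected heterozygosity in the denominator).
#' The confidence interval is the percentile interval of the statistic over
#' `n_boot` resamples of loci with replacement; the estimate is flagged
#' significant when the interval excludes zero.
#'
#' @inheritParams allele_frequencies
#' @param n_boot Bootstrap replicates (default 1000).
#' @param ci Confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return A one-row tibble: `fis`, `ci_lo`, `ci_hi`, `significant`,
#'   `n_loci`, `n_boot`.
#' @export
fis <- function(g, group = NULL, loci = NULL, n_boot = 1000, ci = 0.95,
                seed = NULL) {
  ho <- observed_heterozygosity(g, group, loci)
  uhe <- expected_heterozygosity(g, group, loci, unbiased = TRUE)
  poly <- !is.na(uhe$he) & uhe$he > 0
  if (sum(poly) < 1) stop("FIS undefined: no polymorphic loci in this group",
                          call. = FALSE)
  ho_l <- ho$ho[poly]
  uhe_l <- uhe$he[poly]
  point <- 1 - mean(ho_l) / mean(uhe_l)
  nl <- length(ho_l)
  boot_stat <- function() {
    idx <- sample.int(nl, nl, replace = TRUE)
    1 - mean(ho_l[idx]) / mean(uhe_l[idx])
  }
  reps <- if (is.null(seed)) replicate(n_boot, boot_stat()) else
    withr::with_seed(seed, replicate(n_boot, boot_stat()))
  qs <- stats::quantile(reps, c((1 - ci) / 2, 1 - (1 - ci) / 2), names = FALSE)
  tibble::tibble(fis = point, ci_lo = qs[1], ci_hi = qs[2],
                 significant = qs[1] > 0 | qs[2] < 0,
                 n_loci = nl, n_boot = as.integer(n_boot))
}

#' Diversity panel per group and locus subset
#'
#' One row per group x locus-subset (x optional age stratum): observed and
#' expected heterozygosity, unbiased He, percent polymorphic loci, rarefied
#' allelic richness, percent loci with private alleles, and FIS with a
#' bootstrap CI.
#'
#' @param g A [geno()] object.
#' @param grouping Group specification (metadata column name such as
#'   `"population_cohort"`, a factor, or a named list of individual ids).
#' @param partition Optional [locus_partition()]; when supplied the panel is
#'   computed per subset (`neutral`, `provenance`, `hatchery`) as well as
#'   `all`. Otherwise only `all`.
#' @param by_age Also stratify each group by `age_months`?
#' @param n_boot,ci,seed Passed to [fis()].
#' @param g_copies Rarefaction size for AR; `NULL` = smallest valid copy
#'   count per subset.
#' @return A tibble, one row per group x subset (x stratum), with columns
#'   `group`, `subset`, `age_months`, `n`, `pl_pct`, `ar`, `pa_pct`, `ho`,
#'   `he`, `uhe`, `fis`, `fis_lo`, `fis_hi`, `fis_significant`, `empty`.
#' @export
diversity_report <- function(g, grouping, partition = NULL, by_age = FALSE,
                             n_boot = 1000, ci = 0.95, seed = 1L,
                             g_copies = NULL) {
  groups <- resolve_groups(g, grouping)
  subsets <- list(all = g$loci$locus_id)
  if (!is.null(partition)) {
    subsets <- c(list(all = g$loci$locus_id),
                 list(neutral = partition$neutral,
                      provenance = partition$provenance,
                      hatchery = partition$hatchery))
  }
  strata <- list()
  for (nm in names(groups)) {
    strata[[length(strata) + 1]] <-
      list(group = nm, age = NA_integer_, idx = groups[[nm]])
    if (by_age) {
      ages <- g$individuals$age_months[groups[[nm]]]
      for (a in sort(unique(ages[!is.na(ages)]))) {
        strata[[length(strata) + 1]] <-
          list(group = nm, age = a, idx = groups[[nm]][!is.na(ages) & ages == a])
      }
    }
  }
  rows <- list()
  for (sub_nm in names(subsets)) {
    sub <- subsets[[sub_nm]]
    for (st in strata) {
      if (length(sub) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          group = st$group, subset = sub_nm, age_months = st$age,
          n = length(st$idx), pl_pct = NA_real_, ar = NA_real_,
          pa_pct = NA_real_, ho = NA_real_, he = NA_real_, uhe = NA_real_,
          fis = NA_real_, fis_lo = NA_real_, fis_hi = NA_real_,
          fis_significant = NA, empty = TRUE)
        next
      }
      idx <- st$idx
      ho_t <- observed_heterozygosity(g, idx, sub)
      he_t <- expected_heterozygosity(g, idx, sub)
      uhe_t <- expected_heterozygosity(g, idx, sub, unbiased = TRUE)
      pl <- polymorphic_loci_pct(g, idx, sub)
      fis_row <- tryCatch(
        fis(g, idx, sub, n_boot = n_boot, ci = ci, seed = seed),
        error = function(e) tibble::tibble(fis = NA_real_, ci_lo = NA_real_,
                                           ci_hi = NA_real_, significant = NA))
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = st$group, subset = sub_nm, age_months = st$age,
        n = length(idx), pl_pct = pl, ar = NA_real_, pa_pct = NA_real_,
        ho = attr(ho_t, "mean"), he = attr(he_t, "mean"),
        uhe = attr(uhe_t, "mean"),
        fis = fis_row$fis, fis_lo = fis_row$ci_lo, fis_hi = fis_row$ci_hi,
        fis_significant = fis_row$significant, empty = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  # AR and PA need all groups together (rarefaction size / privacy are
  # cross-group notions); fill the unstratified rows per subset.
  for (sub_nm in names(subsets)) {
    sub <- subsets[[sub_nm]]
    if (length(sub) == 0 || length(groups) < 2) next
    ar_t <- tryCatch(
      rarefied_allelic_richness(g, grouping, sub, g_copies = g_copies),
      error = function(e) NULL)
    pa_t <- private_alleles_pct(g, grouping, sub)
    for (nm in names(groups)) {
      sel <- out$group == nm & out$subset == sub_nm & is.na(out$age_months)
      if (!is.null(ar_t)) out$ar[sel] <- ar_t$ar[ar_t$group == nm]
      out$pa_pct[sel] <- pa_t$pa_pct[pa_t$group == nm]
    }
  }
  out
}
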