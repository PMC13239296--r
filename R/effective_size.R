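#' Burrows composite linkage disequilibrium between locus pairs
#'
#' For every pair of loci passing the MAF cutoff, the Burrows composite
#' measure of LD over individuals non-missing at both loci: the squared
#' dosage correlation times the small-sample factor `(S/(S-1))^2` (the
#' composite disequilibrium uses the `n-1` sample covariance against ML
#' single-locus variances). Pairs sharing fewer than two individuals are
#' dropped.
#'
#' @param g A [geno()] object.
#' @param group Individual subset (ids/index); `NULL` = all.
#' @param loci Optional locus subset.
#' @param maf_cutoff Loci with group MAF `<=` this value are excluded before
#'   pairing (default 0: use everything segregating).
#' @return A tibble with `locus_a`, `locus_b`, `r2`, `s` (shared
#'   individuals).
#' @export
burrows_r2 <- function(g, group = NULL, loci = NULL, maf_cutoff = 0) {
  st <- ld_pair_stats(g, group, loci, maf_cutoff)
  keep <- upper.tri(st$r2) & !is.na(st$r2) & st$s >= 2
  idx <- which(keep, arr.ind = TRUE)
  tibble::tibble(
    locus_a = st$locus_ids[idx[, 1]],
    locus_b = st$locus_ids[idx[, 2]],
    r2 = st$r2[keep],
    s = st$s[keep]
  )
}

ld_pair_stats <- function(g, group, loci, maf_cutoff) {
  ii <- resolve_group(g, group)
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  maf <- minor_allele_frequency(g, ii, jj)
  use <- !is.na(maf$maf) & maf$maf > maf_cutoff
  if (sum(use) < 2) {
    stop("fewer than 2 usable loci after the MAF cutoff", call. = FALSE)
  }
  m <- g$calls[ii, jj[use], drop = FALSE]
  storage.mode(m) <- "double"
  suppressWarnings(
    r <- stats::cor(m, use = "pairwise.complete.obs")
  )
  obs <- !is.na(m)
  s <- crossprod(obs)
  # Burrows composite r2: the numerator covariance is the n-1 sample
  # covariance while the single-locus denominators are ML (1/n) variances,
  # which multiplies the squared dosage correlation by (S/(S-1))^2. The
  # sampling expectation E[r2|S] used by the Ne back-transform is calibrated
  # for this estimator.
  r2 <- r^2 * ifelse(s > 1, (s / (s - 1))^2, NA_real_)
  list(r2 = r2, s = s, locus_ids = g$loci$locus_id[jj[use]])
}

# Waples (2006) bias-corrected drift expectation of r2 given sample size S,
# and the Ne back-transform, random-mating coefficients.
expected_r2_sample <- function(S) {
  ifelse(S >= 30, 1 / S + 3.19 / S^2, 0.0018 + 0.907 / S + 4.44 / S^2)
}

ne_from_r2prime <- function(r2p, S) {
  if (is.na(r2p) || r2p <= 0) return(Inf)
  if (S >= 30) {
    disc <- 1 / 9 - 2.76 * r2p
    if (disc < 0) return(Inf)
    (1 / 3 + sqrt(disc)) / (2 * r2p)
  } else {
    disc <- 0.308^2 - 2.08 * r2p
    if (disc < 0) return(Inf)
    (0.308 + sqrt(disc)) / (2 * r2p)
  }
}

#' Effective population size from linkage disequilibrium
#'
#' The LD method for a single cohort: overall r-squared is the sample-size-
#' weighted mean of Burrows composite r2 over all locus pairs; the sampling
#' expectation given the harmonic mean pair sample size `S` is
#' `1/S + 3.19/S^2` for `S >= 30` (`0.0018 + 0.907/S + 4.44/S^2` below 30);
#' the drift signal is `r2' = r2 - E[r2|S]` and the random-mating estimator
#' is `Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')` (coefficients 0.308 and
#' 2.08 for `S < 30`). A non-positive drift signal means no detectable drift
#' and `Ne = +Inf`.
#'
#' Confidence intervals: `"jackknife"` (default) is a delete-one-individual
#' jackknife on the overall r2, transformed through the Ne formula;
#' `"parametric"` uses the chi-square interval with degrees of freedom
#' equal to the number of pairs (known to be anti-conservative when pairs
#' share loci).
#'
#' @inheritParams burrows_r2
#' @param ci_method `"jackknife"` (over individuals) or `"parametric"`.
#' @param ci Confidence level.
#' @return A one-row tibble of class `ne_estimate`: `method`, `ne`, `ci_lo`,
#'   `ci_hi`, `overall_r2`, `expected_r2`, `s_harmonic`, `n_pairs`,
#'   `n_loci`, `maf_cutoff`.
#' @export
ld_ne <- function(g, group = NULL, loci = NULL, maf_cutoff = 0,
                  ci_method = c("jackknife", "parametric"), ci = 0.95) {
  ci_method <- match.arg(ci_method)
  ii <- resolve_group(g, group)
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  maf <- minor_allele_frequency(g, ii, jj)
  use <- !is.na(maf$maf) & maf$maf > maf_cutoff
  if (sum(use) < 2) {
    stop("fewer than 2 usable loci after the MAF cutoff", call. = FALSE)
  }
  m <- g$calls[ii, jj[use], drop = FALSE]
  storage.mode(m) <- "double"

  overall_r2_of <- function(mm) {
    if (anyNA(mm)) {
      suppressWarnings(r <- stats::cor(mm, use = "pairwise.complete.obs"))
      s <- crossprod(!is.na(mm))
    } else {
      suppressWarnings(r <- stats::cor(mm))
      s <- matrix(nrow(mm), ncol(mm), ncol(mm))
    }
    keep <- upper.tri(r) & !is.na(r) & s >= 2
    r2v <- r[keep]^2 * (s[keep] / (s[keep] - 1))^2
    w <- s[keep]
    list(r2 = sum(w * r2v) / sum(w),
         s_harm = sum(keep) / sum(1 / s[keep]),
         n_pairs = sum(keep))
  }
  full <- overall_r2_of(m)
  if (full$n_pairs < 1) stop("no usable locus pairs", call. = FALSE)
  overall <- full$r2
  s_harm <- full$s_harm
  e_r2 <- expected_r2_sample(s_harm)
  r2p <- overall - e_r2
  ne <- ne_from_r2prime(r2p, s_harm)

  alpha <- 1 - ci
  if (ci_method == "parametric") {
    df <- full$n_pairs
    r2_lo <- overall * df / stats::qchisq(1 - alpha / 2, df)
    r2_hi <- overall * df / stats::qchisq(alpha / 2, df)
  } else {
    n <- nrow(m)
    jack <- vapply(seq_len(n), function(i) overall_r2_of(m[-i, , drop = FALSE])$r2,
                   numeric(1))
    jack <- jack[is.finite(jack)]
    nj <- length(jack)
    se <- sqrt((nj - 1) / nj * sum((jack - mean(jack))^2))
    zq <- stats::qnorm(1 - alpha / 2)
    r2_lo <- overall - zq * se
    r2_hi <- overall + zq * se
  }
  ne_hi <- ne_from_r2prime(r2_lo - e_r2, s_harm)
  ne_lo <- ne_from_r2prime(r2_hi - e_r2, s_harm)
  out <- tibble::tibble(
    method = "LD", ne = ne, ci_lo = ne_lo, ci_hi = ne_hi,
    overall_r2 = overall, expected_r2 = e_r2, s_harmonic = s_harm,
    n_pairs = full$n_pairs, n_loci = sum(use),
    maf_cutoff = maf_cutoff)
  class(out) <- c("ne_estimate", class(out))
  out
}

#' Effective number of breeders from molecular coancestry
#'
#' Per-pair molecular coancestry from allele sharing: within-individual
#' allele frequencies `q = dosage/2` give a per-locus similarity
#' `s = q_i q_j + (1 - q_i)(1 - q_j)`; each pair's coancestry is the
#' ratio-of-sums correction against the unrelated-pair expectation
#' `s0 = p^2 + (1 - p)^2` (`f_ij = sum(s - s0) / sum(1 - s0)`). The
#' effective number of breeders is `Neb = 1 / (2 * mean f)`; a non-positive
#' mean coancestry gives `+Inf`. The CI is a delete-one-individual jackknife.
#'
#' The reference allele frequencies `p` should come from the parental
#' population (`ref_group`, e.g. the wild donors when the focal group is a
#' hatchery F1 cohort). When no reference is given the focal group's own
#' frequencies are used; mean coancestry measured against self-referenced
#' frequencies is pulled towards zero, which biases `Neb` upwards — use a
#' reference whenever one is available.
#'
#' @inheritParams burrows_r2
#' @param ref_group Individual subset supplying the reference allele
#'   frequencies (default: the focal group itself, with the caveat above).
#' @param ci Confidence level.
#' @return A one-row tibble of class `ne_estimate` (`method`
#'   `"coancestry"`): `ne`, `ci_lo`, `ci_hi`, `f1_mean`, `n_pairs`,
#'   `n_loci`.
#' @export
coancestry_ne <- function(g, group = NULL, loci = NULL, ref_group = NULL,
                          ci = 0.95) {
  ii <- resolve_group(g, group)
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  af <- allele_frequencies(g, if (is.null(ref_group)) ii else
    resolve_group(g, ref_group), jj)
  poly <- !af$undefined & af$p_alt > 0 & af$p_alt < 1
  if (!any(poly)) stop("coancestry Ne undefined on monomorphic-only data",
                       call. = FALSE)
  m <- g$calls[ii, jj[poly], drop = FALSE]
  p <- af$p_alt[poly]
  n <- nrow(m)
  if (n < 2) stop(">= 2 individuals required", call. = FALSE)
  q <- m / 2
  s0 <- p^2 + (1 - p)^2

  pair_f <- function(rows) {
    qq <- q[rows, , drop = FALSE]
    combs <- utils::combn(nrow(qq), 2)
    f <- numeric(ncol(combs))
    for (k in seq_len(ncol(combs))) {
      qi <- qq[combs[1, k], ]; qj <- qq[combs[2, k], ]
      ok <- !is.na(qi) & !is.na(qj)
      s <- qi[ok] * qj[ok] + (1 - qi[ok]) * (1 - qj[ok])
      f[k] <- sum(s - s0[ok]) / sum(1 - s0[ok])
    }
    f
  }
  f_all <- pair_f(seq_len(n))
  f1 <- mean(f_all, na.rm = TRUE)
  neb <- if (is.na(f1) || f1 <= 0) Inf else 1 / (2 * f1)

  # jackknife over individuals on the mean coancestry
  combs <- utils::combn(n, 2)
  jack <- vapply(seq_len(n), function(i) {
    keep <- combs[1, ] != i & combs[2, ] != i
    mean(f_all[keep], na.rm = TRUE)
  }, numeric(1))
  se <- sqrt((n - 1) / n * sum((jack - mean(jack))^2))
  zq <- stats::qnorm(1 - (1 - ci) / 2)
  f_lo <- f1 - zq * se
  f_hi <- f1 + zq * se
  ne_from_f <- function(f) if (is.na(f) || f <= 0) Inf else 1 / (2 * f)
  out <- tibble::tibble(
    method = "coancestry", ne = neb,
    ci_lo = ne_from_f(f_hi), ci_hi = ne_from_f(f_lo),
    f1_mean = f1, n_pairs = length(f_all), n_loci = sum(poly))
  class(out) <- c("ne_estimate", class(out))
  out
}

#' Percentage of donors effectively contributing
#'
#' `100 * Ne / n_donors`, capped at 100 — the share of the donor pool that
#' an idealised population of size Ne represents.
#'
#' @param ne A `ne_estimate` row (or a finite numeric Ne).
#' @param n_donors Number of donor plants used (>= 1).
#' @return Percentage in `(0, 100]`; errors on an infinite estimate.
#' @export
donor_contribution_pct <- function(ne, n_donors) {
  stopifnot(n_donors >= 1)
  val <- if (is.numeric(ne)) ne[1] else ne$ne[1]
  if (!is.finite(val)) {
    stop("donor contribution undefined for an infinite Ne estimate",
         call. = FALSE)
  }
  min(100, 100 * val / n_donors)
}

#' @export
tidy.ne_estimate <- function(x, ...) tibble::as_tibble(unclass(x))
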