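#' Weir–Cockerham variance components and multi-locus theta
#'
#' Method-of-moments variance components per locus from genotype counts:
#' `a` (among populations), `b` (among individuals within populations), `c`
#' (within individuals), following the 1984 estimator, with multi-locus
#' `theta = sum(a) / sum(a + b + c)` (ratio of sums). Negative estimates are
#' reported as computed, never truncated. Loci with fewer than two groups
#' carrying valid calls are dropped.
#'
#' @param g A [geno()] object.
#' @param group_a,group_b Individual subsets (ids or row index) for the two
#'   groups being compared.
#' @param loci Optional locus subset.
#' @return A list with `theta` (multi-locus estimate) and `components`, a
#'   tibble of per-locus `a`, `b`, `c`.
#' @export
wc_theta <- function(g, group_a, group_b, loci = NULL) {
  ii_a <- resolve_group(g, group_a)
  ii_b <- resolve_group(g, group_b)
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  comp <- wc_components(list(g$calls[ii_a, jj, drop = FALSE],
                             g$calls[ii_b, jj, drop = FALSE]),
                        g$loci$locus_id[jj])
  usable <- !is.na(comp$a)
  if (!any(usable)) {
    stop("no locus has >= 2 valid individuals in both groups", call. = FALSE)
  }
  theta <- sum(comp$a[usable]) /
    sum(comp$a[usable] + comp$b[usable] + comp$c[usable])
  list(theta = theta, components = comp)
}

# Per-locus W&C (1984) components for a list of dosage matrices (one per
# group, same loci in columns). Returns tibble(locus_id, a, b, c); NA rows
# where < 2 groups have >= 2 valid calls or the locus is monomorphic overall
# (a = b = c = 0 there; kept as zeros so ratio-of-sums is unaffected).
wc_components <- function(mats, locus_ids) {
  L <- length(locus_ids)
  n <- sapply(mats, function(m) colSums(!is.na(m)))          # L x r
  n <- matrix(n, nrow = L)
  p <- sapply(mats, function(m) colSums(m, na.rm = TRUE))
  p <- matrix(p, nrow = L) / pmax(2 * n, 1)
  h <- sapply(mats, function(m) colSums(m == 1L, na.rm = TRUE))
  h <- matrix(h, nrow = L) / pmax(n, 1)

  a <- b <- cc <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    use <- n[l, ] >= 2
    r <- sum(use)
    if (r < 2) next
    ni <- n[l, use]; pi <- p[l, use]; hi <- h[l, use]
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a[l] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[l] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[l] <- hbar / 2
  }
  tibble::tibble(locus_id = locus_ids, a = a, b = b, c = cc)
}

#' Pairwise Weir–Cockerham FST with locus bootstrap and FDR correction
#'
#' For every pair of groups, the multi-locus theta, a percentile bootstrap
#' CI over `n_boot` resamples of loci with replacement, a one-tailed
#' bootstrap p-value `P(theta_boot <= 0) = (1 + #{theta_b <= 0}) /
#' (n_boot + 1)`, and Benjamini–Hochberg adjusted p-values across all pairs
#' in the call.
#'
#' @param g A [geno()] object.
#' @param grouping Group specification, see [diversity_report()].
#' @param loci Optional locus subset.
#' @param n_boot Bootstrap replicates (default 999).
#' @param ci Confidence level.
#' @param seed RNG seed.
#' @param subset_label Label stored in the `subset` column.
#' @return A tibble of class `fst_result`, one row per pair: `group_a`,
#'   `group_b`, `subset`, `theta`, `ci_lo`, `ci_hi`, `p_value`, `p_adjusted`,
#'   `n_boot`.
#' @export
pairwise_fst <- function(g, grouping, loci = NULL, n_boot = 999, ci = 0.95,
                         seed = 1L, subset_label = "all") {
  groups <- resolve_groups(g, grouping)
  if (length(groups) < 2) stop(">= 2 groups required", call. = FALSE)
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  rows <- withr::with_seed(seed, purrr::map_dfr(pairs, function(pr) {
    comp <- wc_components(list(g$calls[groups[[pr[1]]], jj, drop = FALSE],
                               g$calls[groups[[pr[2]]], jj, drop = FALSE]),
                          g$loci$locus_id[jj])
    comp <- comp[!is.na(comp$a), ]
    if (nrow(comp) == 0) stop("no usable loci for pair ", pr[1], "-", pr[2],
                              call. = FALSE)
    theta <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
    nl <- nrow(comp)
    boot <- replicate(n_boot, {
      idx <- sample.int(nl, nl, replace = TRUE)
      sum(comp$a[idx]) / sum(comp$a[idx] + comp$b[idx] + comp$c[idx])
    })
    qs <- stats::quantile(boot, c((1 - ci) / 2, 1 - (1 - ci) / 2),
                          names = FALSE, na.rm = TRUE)
    tibble::tibble(group_a = pr[1], group_b = pr[2], subset = subset_label,
                   theta = theta, ci_lo = qs[1], ci_hi = qs[2],
                   p_value = (1 + sum(boot <= 0, na.rm = TRUE)) / (n_boot + 1),
                   n_loci = nl, n_boot = as.integer(n_boot))
  }))
  rows$p_adjusted <- stats::p.adjust(rows$p_value, method = "BH")
  class(rows) <- c("fst_result", class(rows))
  rows
}

#' @export
tidy.fst_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
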