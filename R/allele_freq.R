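#' Per-locus alternate-allele frequencies
#'
#' Frequencies are computed over non-missing calls only:
#' `p = (alt allele count) / (2 * n_valid)`. Loci with zero non-missing calls
#' in the group get `NA` frequency and are flagged undefined.
#'
#' @param g A [geno()] object.
#' @param group Individual subset: `NULL` (all individuals), individual ids,
#'   or a logical/integer row index. Must be non-empty.
#' @param loci Optional locus subset (ids or index); `NULL` = all loci.
#' @return A tibble with `locus_id`, `p_alt`, `n_valid` (non-missing
#'   individuals) and `undefined`.
#' @export
#' @examples
#' g <- geno(matrix(c(0L, 1L, 2L), 3, 1))
#' allele_frequencies(g)$p_alt  # 0.5
allele_frequencies <- function(g, group = NULL, loci = NULL) {
  ii <- resolve_group(g, group)
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  m <- g$calls[ii, jj, drop = FALSE]
  n_valid <- colSums(!is.na(m))
  alt <- colSums(m, na.rm = TRUE)
  p <- ifelse(n_valid > 0, alt / (2 * n_valid), NA_real_)
  tibble::tibble(
    locus_id = g$loci$locus_id[jj],
    p_alt = unname(p),
    n_valid = unname(as.integer(n_valid)),
    undefined = unname(n_valid == 0)
  )
}

#' Per-locus minor allele frequency
#'
#' `MAF = min(p, 1 - p)` with `p` the alternate-allele frequency in the
#' group.
#'
#' @inheritParams allele_frequencies
#' @return A tibble with `locus_id`, `maf`, `n_valid`, `undefined`.
#' @export
minor_allele_frequency <- function(g, group = NULL, loci = NULL) {
  ii <- resolve_group(g, group)
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  m <- g$calls[ii, jj, drop = FALSE]
  n_valid <- colSums(!is.na(m))
  alt <- colSums(m, na.rm = TRUE)
  # count-based so ref/alt relabelling is exactly symmetric
  maf <- ifelse(n_valid > 0,
                pmin(alt, 2 * n_valid - alt) / (2 * n_valid), NA_real_)
  tibble::tibble(
    locus_id = g$loci$locus_id[jj],
    maf = unname(maf),
    n_valid = unname(as.integer(n_valid)),
    undefined = unname(n_valid == 0)
  )
}
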