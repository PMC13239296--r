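#' Bitwise (dosage) genetic distance between individuals
#'
#' Mean per-locus absolute dosage difference divided by 2 over pairwise-
#' complete loci, giving a distance in `[0, 1]` (0 = identical genotypes,
#' 1 = opposite homozygotes everywhere). Pairs sharing no typed locus are
#' returned as `NA` (undefined).
#'
#' @param g A [geno()] object (`>= 2` individuals).
#' @param loci Optional locus subset.
#' @return A symmetric numeric matrix with zero diagonal, individual ids as
#'   dimnames.
#' @export
bitwise_distance <- function(g, loci = NULL) {
  if (nrow(g$calls) < 2) stop(">= 2 individuals required", call. = FALSE)
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  m <- g$calls[, jj, drop = FALSE]
  all_missing <- rowSums(!is.na(m)) == 0
  if (any(all_missing)) {
    stop("individual(s) with no valid calls: ",
         paste(g$individuals$individual_id[all_missing], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    di <- abs(sweep(m[(i + 1):n, , drop = FALSE], 2, m[i, ]))
    shared <- rowSums(!is.na(di))
    val <- ifelse(shared > 0, rowSums(di, na.rm = TRUE) / (2 * shared),
                  NA_real_)
    d[i, (i + 1):n] <- val
    d[(i + 1):n, i] <- val
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres `-D^2/2`, eigendecomposes, and scales eigenvectors by the
#' square root of their eigenvalues. Axes with negative eigenvalues are
#' dropped from the coordinates; the eigenvalues themselves are reported.
#' Coordinates are reproducible up to axis sign.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param n_axes Maximum number of axes to return.
#' @return A list of class `pcoa_result`: `coordinates` (individuals x
#'   axes), `eigenvalues`, `pct_variance` (percent of the positive-eigenvalue
#'   total per retained axis).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(d)
  k <- min(n_axes, n - 1)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k,
                                          eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig), 1)
  if (!any(pos)) {
    coords <- matrix(0, n, k, dimnames = list(rownames(d),
                                              paste0("axis", seq_len(k))))
    pct <- rep(0, k)
  } else {
    keep <- seq_len(min(k, sum(pos)))
    coords <- fit$points[, keep, drop = FALSE]
    colnames(coords) <- paste0("axis", keep)
    pct <- 100 * eig[keep] / sum(eig[pos])
  }
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    pct_variance = pct
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("<pcoa_result> ", nrow(x$coordinates), " points, ",
      ncol(x$coordinates), " axes (",
      paste(sprintf("%.1f%%", x$pct_variance), collapse = ", "),
      " variance)\n", sep = "")
  invisible(x)
}

#' @export
tidy.pcoa_result <- function(x, ...) {
  out <- tibble::as_tibble(x$coordinates)
  out$individual_id <- rownames(x$coordinates)
  dplyr::relocate(out, "individual_id")
}

#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(n_axes = ncol(x$coordinates),
                 pct_axis1 = x$pct_variance[1],
                 pct_axis2 = if (length(x$pct_variance) > 1)
                   x$pct_variance[2] else NA_real_,
                 n_negative_eig = sum(x$eigenvalues < 0))
}

#' Ordination scatter plot for a PCoA result
#'
#' @param object A `pcoa_result`.
#' @param groups Optional per-individual labels used for colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_result <- function(object, groups = NULL, ...) {
  df <- tidy.pcoa_result(object)
  if (!is.null(groups)) df$group <- as.character(groups)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::labs(
      x = sprintf("PCoA axis 1 (%.1f%%)", object$pct_variance[1]),
      y = sprintf("PCoA axis 2 (%.1f%%)", object$pct_variance[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}
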