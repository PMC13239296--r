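#' Redundancy-analysis outlier scan against a binary predictor
#'
#' Constrained ordination of the dosage matrix on a single dummy-coded
#' predictor (e.g. provenance warm vs cool, or wild vs hatchery). Missing
#' calls are imputed with the per-locus mean dosage (imputation is confined
#' to the ordination; no other statistic sees imputed data), genotype columns
#' are centred, the fitted-value matrix from the per-locus regressions is
#' decomposed by SVD, and each locus receives a loading on the single
#' constrained axis. Loadings are standardised across loci
#' (`z = (loading - mean) / sd`) and loci with `|z| > sd_threshold` are
#' flagged as outliers — the usual candidate-locus convention for this kind
#' of genotype–environment association scan.
#'
#' @param g A [geno()] object.
#' @param predictor Binary per-individual label: a metadata column name
#'   (`"population"`, `"cohort"`) or a vector of length `n_individuals`.
#'   Both levels must be present.
#' @param loci Optional locus subset.
#' @param sd_threshold Outlier threshold on |z| (default 3).
#' @param scale Standardise genotype columns to unit variance before the
#'   ordination? Default `FALSE` (centred raw dosages, the conventional
#'   choice); with `TRUE` the loading ranking equals the ranking by
#'   absolute point-biserial correlation between dosage and predictor.
#' @return A list of class `rda_result`: `loadings` tibble (`locus_id`,
#'   `loading`, `z`, `outlier`), `predictor`, `sd_threshold`,
#'   `prop_variance` (share of total genotypic variance explained by the
#'   predictor), `n_outliers`.
#' @export
rda_scan <- function(g, predictor, loci = NULL, sd_threshold = 3,
                     scale = FALSE) {
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  x <- predictor_vector(g, predictor)
  lev <- unique(x[!is.na(x)])
  if (length(lev) < 2) stop("predictor is constant: needs both levels",
                            call. = FALSE)
  if (length(lev) > 2) stop("predictor must be binary", call. = FALSE)
  keep <- !is.na(x)
  m <- g$calls[keep, jj, drop = FALSE]
  x01 <- as.numeric(x[keep] == lev[2])

  # locus-mean imputation, then column centring
  mm <- apply(m, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    col[is.na(col)] <- mu
    col
  })
  mm <- base::scale(mm, center = TRUE, scale = FALSE)
  if (scale) {
    sds <- apply(mm, 2, stats::sd)
    sds[sds == 0] <- 1
    mm <- sweep(mm, 2, sds, "/")
  }
  xc <- x01 - mean(x01)

  # one binary predictor: fitted = xc (xc'xc)^-1 xc' Y, rank 1
  beta <- drop(crossprod(xc, mm)) / sum(xc^2)
  fitted <- outer(xc, beta)
  sv <- svd(fitted, nu = 1, nv = 1)
  loading <- sv$v[, 1] * sv$d[1]
  # orient the axis consistently (sign is arbitrary in SVD)
  if (sum(loading * beta) < 0) loading <- -loading

  z <- (loading - mean(loading)) / stats::sd(loading)
  prop_var <- sum(fitted^2) / sum(mm^2)
  out <- tibble::tibble(
    locus_id = g$loci$locus_id[jj],
    loading = loading, z = z,
    outlier = abs(z) > sd_threshold)
  structure(list(loadings = out, predictor = predictor_label(predictor),
                 sd_threshold = sd_threshold, prop_variance = prop_var,
                 n_outliers = sum(out$outlier)),
            class = "rda_result")
}

predictor_vector <- function(g, predictor) {
  if (is.character(predictor) && length(predictor) == 1 &&
      nrow(g$calls) != 1) {
    if (!predictor %in% names(g$individuals)) {
      stop("unknown predictor column: ", predictor, call. = FALSE)
    }
    return(as.character(g$individuals[[predictor]]))
  }
  stopifnot(length(predictor) == nrow(g$calls))
  as.character(predictor)
}

predictor_label <- function(predictor) {
  if (is.character(predictor) && length(predictor) == 1) predictor else
    "custom"
}

#' @export
print.rda_result <- function(x, ...) {
  cat("<rda_result> predictor = ", x$predictor, ", ",
      nrow(x$loadings), " loci, ", x$n_outliers, " outliers (|z| > ",
      x$sd_threshold, ")\n", sep = "")
  cat("  variance explained by predictor: ",
      sprintf("%.2f%%", 100 * x$prop_variance), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.rda_result <- function(x, ...) x$loadings

#' @export
glance.rda_result <- function(x, ...) {
  tibble::tibble(predictor = x$predictor, n_loci = nrow(x$loadings),
                 n_outliers = x$n_outliers, sd_threshold = x$sd_threshold,
                 prop_variance = x$prop_variance)
}

#' Loading plot for an RDA outlier scan
#'
#' @param object An `rda_result`.
#' @param ... Unused.
#' @return A ggplot object: per-locus |z| with the outlier threshold line.
#' @export
autoplot.rda_result <- function(object, ...) {
  df <- object$loadings
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$z,
                                   colour = .data$outlier)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$sd_threshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "locus", y = "loading z-score",
                  title = paste("RDA scan:", object$predictor)) +
    ggplot2::theme_minimal()
}

#' Partition loci into neutral / provenance / hatchery subsets
#'
#' Outlier sets are read from the two scans' flags; neutral is the
#' complement of their union; loci flagged by both are recorded in
#' `overlap` (and belong to both outlier sets, not to neutral).
#'
#' @param locus_ids All locus ids covered by both scans.
#' @param rda_provenance,rda_hatchery `rda_result` objects from
#'   [rda_scan()] on the provenance and wild-vs-hatchery predictors.
#' @return A list of class `locus_partition`: `neutral`, `provenance`,
#'   `hatchery`, `overlap` (character vectors of locus ids).
#' @export
partition_loci <- function(locus_ids, rda_provenance, rda_hatchery) {
  if (!setequal(rda_provenance$loadings$locus_id, locus_ids) ||
      !setequal(rda_hatchery$loadings$locus_id, locus_ids)) {
    stop("locus ids of the two scans do not match the supplied set",
         call. = FALSE)
  }
  prov <- rda_provenance$loadings$locus_id[rda_provenance$loadings$outlier]
  hatch <- rda_hatchery$loadings$locus_id[rda_hatchery$loadings$outlier]
  structure(list(
    neutral = setdiff(locus_ids, union(prov, hatch)),
    provenance = prov,
    hatchery = hatch,
    overlap = intersect(prov, hatch)
  ), class = "locus_partition")
}

#' @export
print.locus_partition <- function(x, ...) {
  cat("<locus_partition> neutral = ", length(x$neutral),
      ", provenance = ", length(x$provenance),
      ", hatchery = ", length(x$hatchery),
      ", overlap = ", length(x$overlap), "\n", sep = "")
  invisible(x)
}
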