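#' Biallelic SNP genotype matrix with locus and individual metadata
#'
#' A `geno` object holds an individuals-by-loci matrix of alternate-allele
#' dosages (0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate, `NA` = missing call) together with a locus metadata table
#' (DArT-style fragment/clone id, mean read depth, reproducibility score) and
#' an individual metadata table (population, cohort, age in months).
#'
#' @param calls Integer matrix (individuals x loci) with values in
#'   `c(0L, 1L, 2L, NA)`. Row/column names, if present, must agree with the
#'   metadata tables.
#' @param loci Data frame with one row per locus: `locus_id` (unique),
#'   and optionally `clone_id`, `read_depth`, `reproducibility`,
#'   `ref_allele`, `alt_allele`. Missing optional columns are filled with
#'   defaults.
#' @param individuals Data frame with one row per individual: `individual_id`
#'   (unique), and optionally `population` (`"warm"`/`"cool"`), `cohort`
#'   (`"wild"`/`"hatchery"`/`"simulated"`), `age_months`.
#'
#' @return An object of class `geno`.
#' @export
#' @examples
#' g <- geno(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'           loci = data.frame(locus_id = c("L1", "L2")),
#'           individuals = data.frame(individual_id = c("i1", "i2")))
#' g
geno <- function(calls, loci = NULL, individuals = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(loci)) {
    loci <- tibble::tibble(
      locus_id = sprintf("L%d", seq_len(ncol(calls))))
  }
  if (is.null(individuals)) {
    individuals <- tibble::tibble(
      individual_id = sprintf("I%d", seq_len(nrow(calls))))
  }
  loci <- tibble::as_tibble(loci)
  individuals <- tibble::as_tibble(individuals)
  if (!"clone_id" %in% names(loci)) loci$clone_id <- loci$locus_id
  if (!"read_depth" %in% names(loci)) loci$read_depth <- NA_real_
  if (!"reproducibility" %in% names(loci)) loci$reproducibility <- NA_real_
  if (!"population" %in% names(individuals)) individuals$population <- NA_character_
  if (!"cohort" %in% names(individuals)) individuals$cohort <- NA_character_
  if (!"age_months" %in% names(individuals)) individuals$age_months <- NA_integer_
  dimnames(calls) <- list(individuals$individual_id, loci$locus_id)
  out <- structure(
    list(calls = calls, loci = loci, individuals = individuals),
    class = "geno"
  )
  validate_geno(out)
}

#' Validate a `geno` object
#'
#' Checks the container invariants: matching dimensions, unique ids, and
#' genotype codes restricted to 0/1/2/NA.
#'
#' @param g A `geno` object.
#' @return `g`, invisibly unchanged, or an error.
#' @export
validate_geno <- function(g) {
  stopifnot(inherits(g, "geno"))
  if (nrow(g$calls) != nrow(g$individuals)) {
    stop("calls has ", nrow(g$calls), " rows but ", nrow(g$individuals),
         " individuals", call. = FALSE)
  }
  if (ncol(g$calls) != nrow(g$loci)) {
    stop("calls has ", ncol(g$calls), " columns but ", nrow(g$loci),
         " loci", call. = FALSE)
  }
  if (anyDuplicated(g$loci$locus_id)) stop("locus IDs must be unique", call. = FALSE)
  if (anyDuplicated(g$individuals$individual_id)) {
    stop("individual IDs must be unique", call. = FALSE)
  }
  bad <- !(g$calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) {
    stop("genotype calls must be 0, 1, 2 or NA; found ",
         paste(unique(g$calls[bad]), collapse = ", "), call. = FALSE)
  }
  rep_ok <- is.na(g$loci$reproducibility) |
    (g$loci$reproducibility >= 0 & g$loci$reproducibility <= 1)
  if (!all(rep_ok)) stop("reproducibility must lie in [0, 1]", call. = FALSE)
  dep_ok <- is.na(g$loci$read_depth) | g$loci$read_depth >= 0
  if (!all(dep_ok)) stop("read_depth must be non-negative", call. = FALSE)
  g
}

#' @export
print.geno <- function(x, ...) {
  cat("<geno> ", nrow(x$calls), " individuals x ", ncol(x$calls), " loci\n",
      sep = "")
  miss <- mean(is.na(x$calls))
  cat("  missing calls: ", sprintf("%.1f%%", 100 * miss), "\n", sep = "")
  pops <- table(x$individuals$population, x$individuals$cohort, useNA = "no")
  if (length(pops)) {
    for (p in rownames(pops)) {
      for (co in colnames(pops)) {
        if (pops[p, co] > 0) cat("  ", p, "/", co, ": n = ", pops[p, co], "\n", sep = "")
      }
    }
  }
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$calls)

#' Number of loci / individuals in a `geno` object
#' @param g A `geno` object.
#' @return Integer count.
#' @export
n_loci <- function(g) ncol(g$calls)

#' @rdname n_loci
#' @export
n_individuals <- function(g) nrow(g$calls)

#' Subset a genotype object by individuals and/or loci
#'
#' @param g A `geno` object.
#' @param individuals Individual ids (character), or a logical/integer index
#'   over rows; `NULL` keeps all.
#' @param loci Locus ids (character), or a logical/integer index over columns;
#'   `NULL` keeps all.
#' @return A `geno` object with the selected rows/columns, metadata subset in
#'   step.
#' @export
geno_subset <- function(g, individuals = NULL, loci = NULL) {
  ii <- resolve_index(individuals, g$individuals$individual_id, "individual")
  jj <- resolve_index(loci, g$loci$locus_id, "locus")
  geno(g$calls[ii, jj, drop = FALSE],
       loci = g$loci[jj, , drop = FALSE],
       individuals = g$individuals[ii, , drop = FALSE])
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) {
      stop("unknown ", what, " id(s): ",
           paste(idx[is.na(pos)], collapse = ", "), call. = FALSE)
    }
    return(pos)
  }
  if (is.logical(idx)) {
    stopifnot(length(idx) == length(ids))
    return(which(idx))
  }
  as.integer(idx)
}

#' Bind two genotype objects over individuals (shared loci)
#'
#' Loci must match exactly (same ids, same order). Used to assemble multi-
#' cohort datasets from per-cohort matrices.
#'
#' @param ... `geno` objects with identical locus tables.
#' @return A single `geno` object.
#' @export
geno_rbind <- function(...) {
  gs <- list(...)
  stopifnot(length(gs) >= 1)
  ids <- gs[[1]]$loci$locus_id
  for (g in gs[-1]) {
    if (!identical(g$loci$locus_id, ids)) {
      stop("locus tables differ between genotype objects", call. = FALSE)
    }
  }
  geno(do.call(rbind, lapply(gs, function(g) g$calls)),
       loci = gs[[1]]$loci,
       individuals = dplyr::bind_rows(lapply(gs, function(g) g$individuals)))
}

#' Long-format view of genotype calls
#'
#' @param x A `geno` object.
#' @param ... Unused.
#' @return A tibble with columns `individual_id`, `locus_id`, `dosage`.
#' @export
tidy.geno <- function(x, ...) {
  tibble::tibble(
    individual_id = rep(x$individuals$individual_id, times = ncol(x$calls)),
    locus_id = rep(x$loci$locus_id, each = nrow(x$calls)),
    dosage = as.integer(x$calls)
  )
}

#' One-row summary of a genotype object
#'
#' @param x A `geno` object.
#' @param ... Unused.
#' @return A tibble with counts and the realised missing-call rate.
#' @export
glance.geno <- function(x, ...) {
  tibble::tibble(
    n_individuals = nrow(x$calls),
    n_loci = ncol(x$calls),
    missing_rate = mean(is.na(x$calls)),
    n_populations = dplyr::n_distinct(x$individuals$population, na.rm = TRUE),
    n_cohorts = dplyr::n_distinct(x$individuals$cohort, na.rm = TRUE)
  )
}

# Resolve a grouping specification to a named list of row indices.
# `grouping` may be a metadata column name ("population", "cohort", or
# "population_cohort"), a factor/character vector of length n_individuals,
# or a named list of individual-id vectors.
resolve_groups <- function(g, grouping) {
  n <- nrow(g$calls)
  if (is.list(grouping) && !is.data.frame(grouping)) {
    return(lapply(grouping, function(idx)
      resolve_index(idx, g$individuals$individual_id, "individual")))
  }
  if (is.character(grouping) && length(grouping) == 1 && n != 1) {
    lab <- if (grouping == "population_cohort") {
      paste(g$individuals$population, g$individuals$cohort, sep = "_")
    } else if (grouping %in% names(g$individuals)) {
      as.character(g$individuals[[grouping]])
    } else {
      stop("unknown grouping column: ", grouping, call. = FALSE)
    }
    return(split(seq_len(n), lab))
  }
  stopifnot(length(grouping) == n)
  split(seq_len(n), as.character(grouping))
}

# Row indices for a `group` argument: NULL = everyone, character ids,
# logical/integer index, all accepted.
resolve_group <- function(g, group) {
  if (is.null(group)) return(seq_len(nrow(g$calls)))
  idx <- resolve_index(group, g$individuals$individual_id, "individual")
  if (length(idx) == 0) stop("group is empty", call. = FALSE)
  idx
}
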