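#' Read a genotype matrix from disk
#'
#' Two on-disk dialects are supported:
#'
#' * `"genotype-csv"`: a UTF-8 comma-separated table; first row holds column
#'   names, leading metadata columns `individual_id`, `population`, `cohort`,
#'   `age_months`, remaining columns one per locus with the locus id as
#'   header; missing calls written as `NA`. An optional sidecar CSV carries
#'   the locus metadata (`locus_id`, `clone_id`, `read_depth`,
#'   `reproducibility`).
#' * `"vcf"`: VCF v4.2 restricted to biallelic SNPs; only the GT field is
#'   used, with `0/0`, `0/1`, `1/1`, `./.` mapped to dosages 0, 1, 2, `NA`.
#'   Parsed with \pkg{vcfR}.
#'
#' Genotype cells that do not parse as one of the recognised codes become
#' missing calls.
#'
#' @param path Path to the genotype file.
#' @param format `"genotype-csv"` (default) or `"vcf"`.
#' @param locus_meta Optional path to the sidecar locus-metadata CSV
#'   (genotype-csv only). Defaults to `<path>` with a `.loci.csv` suffix if
#'   that file exists.
#' @return A [geno()] object.
#' @export
read_genotypes <- function(path, format = c("genotype-csv", "vcf"),
                           locus_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "vcf") return(read_genotypes_vcf(path))

  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  meta_cols <- c("individual_id", "population", "cohort", "age_months")
  if (!"individual_id" %in% names(df)) {
    stop("malformed header in ", path,
         ": first column must be 'individual_id' (line 1)", call. = FALSE)
  }
  present_meta <- intersect(meta_cols, names(df))
  locus_cols <- setdiff(names(df), meta_cols)
  calls <- as.matrix(df[, locus_cols, drop = FALSE])
  suppressWarnings(storage.mode(calls) <- "integer")
  calls[!(calls %in% c(0L, 1L, 2L))] <- NA_integer_

  individuals <- tibble::as_tibble(df[, present_meta, drop = FALSE])
  if ("age_months" %in% names(individuals)) {
    suppressWarnings(individuals$age_months <- as.integer(individuals$age_months))
  }
  individuals$population[individuals$population %in% c("NA", "")] <- NA
  individuals$cohort[individuals$cohort %in% c("NA", "")] <- NA

  loci <- tibble::tibble(locus_id = locus_cols)
  if (is.null(locus_meta)) {
    cand <- sub("\\.csv$", ".loci.csv", path)
    if (file.exists(cand) && cand != path) locus_meta <- cand
  }
  if (!is.null(locus_meta)) {
    lm <- tibble::as_tibble(utils::read.csv(locus_meta, check.names = FALSE))
    if (!"locus_id" %in% names(lm)) {
      stop("malformed locus metadata header in ", locus_meta,
           ": missing 'locus_id' (line 1)", call. = FALSE)
    }
    pos <- match(loci$locus_id, lm$locus_id)
    if (anyNA(pos)) {
      stop("locus metadata missing entries for: ",
           paste(utils::head(loci$locus_id[is.na(pos)], 5), collapse = ", "),
           call. = FALSE)
    }
    loci <- lm[pos, , drop = FALSE]
  }
  geno(calls, loci = loci, individuals = individuals)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 |
    (!is.na(fix[, "ALT"]) & nchar(fix[, "ALT"]) != 1)
  if (any(multi)) {
    ids <- fix[multi, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"])[is.na(ids) | ids == "."]
    stop("non-biallelic-SNP VCF record(s): ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt_clean <- gsub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt_clean %in% c("0/0")] <- 0L
  code[gt_clean %in% c("0/1", "1/0")] <- 1L
  code[gt_clean %in% c("1/1")] <- 2L
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
  loci <- tibble::tibble(locus_id = ids,
                         ref_allele = fix[, "REF"],
                         alt_allele = fix[, "ALT"])
  geno(t(code), loci = loci,
       individuals = tibble::tibble(individual_id = colnames(gt)))
}

#' Write a genotype matrix to disk
#'
#' Inverse of [read_genotypes()]: the written file round-trips with
#' bit-identical calls. `genotype-csv` also writes the locus-metadata sidecar
#' (`<path>` with a `.loci.csv` suffix) so clone ids, read depth and
#' reproducibility survive the round trip.
#'
#' @param g A [geno()] object.
#' @param path Output path.
#' @param format `"genotype-csv"` (default) or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("genotype-csv", "vcf")) {
  format <- match.arg(format)
  validate_geno(g)
  if (format == "vcf") return(write_genotypes_vcf(g, path))
  df <- data.frame(
    individual_id = g$individuals$individual_id,
    population = g$individuals$population,
    cohort = g$individuals$cohort,
    age_months = g$individuals$age_months,
    check.names = FALSE
  )
  df <- cbind(df, as.data.frame(g$calls, check.names = FALSE))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  side <- sub("\\.csv$", ".loci.csv", path)
  if (side == path) side <- paste0(path, ".loci.csv")
  keep <- intersect(c("locus_id", "clone_id", "read_depth", "reproducibility",
                      "ref_allele", "alt_allele"), names(g$loci))
  utils::write.csv(as.data.frame(g$loci[, keep, drop = FALSE]), side,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

write_genotypes_vcf <- function(g, path) {
  ref <- if ("ref_allele" %in% names(g$loci)) g$loci$ref_allele else
    rep("A", n_loci(g))
  alt <- if ("alt_allele" %in% names(g$loci)) g$loci$alt_allele else
    rep("T", n_loci(g))
  ref[is.na(ref)] <- "A"; alt[is.na(alt)] <- "T"
  gmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- t(g$calls)
  gt_str <- matrix("./.", nrow(dos), ncol(dos))
  for (d in 0:2) gt_str[!is.na(dos) & dos == d] <- gmap[[as.character(d)]]
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$individuals$individual_id),
                     collapse = "\t")), con)
  if (n_loci(g) > 0) {
    body <- paste("chr1", seq_len(n_loci(g)), g$loci$locus_id, ref, alt,
                  ".", "PASS", ".", "GT", sep = "\t")
    body <- paste(body, apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
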