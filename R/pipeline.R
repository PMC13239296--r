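#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles the stage configurations with the input paths, output directory
#' and global seed. Defaults reproduce the standard workflow for a two-
#' provenance hatchery study: sequential SNP filtering, RDA outlier scans
#' against provenance and hatchery predictors (|z| > 3), locus
#' partitioning, diversity panels (FIS with 1000 locus bootstraps),
#' pairwise FST (999 locus bootstraps, Benjamini–Hochberg correction),
#' PCoA, LD-based Ne per group, and the donor-number forward simulation.
#'
#' @param genotypes Path to a genotype-csv file (or a [geno()] object).
#' @param out_dir Output directory.
#' @param filter A [filter_config()] or `NULL` to skip filtering.
#' @param sd_threshold RDA outlier threshold.
#' @param fst_boot,fis_boot Bootstrap replicate counts.
#' @param sim A [sim_config()] or `NULL` to skip the simulation stage.
#' @param ne_maf_cutoff MAF cutoff for the LD-Ne stage.
#' @param seed Global seed; every stochastic stage derives its stream from
#'   it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, out_dir = "hatchgen-out",
                            filter = filter_config(), sd_threshold = 3,
                            fst_boot = 999, fis_boot = 1000,
                            sim = NULL, ne_maf_cutoff = 0, seed = 1L) {
  structure(list(genotypes = genotypes, out_dir = out_dir, filter = filter,
                 sd_threshold = sd_threshold, fst_boot = fst_boot,
                 fis_boot = fis_boot, sim = sim,
                 ne_maf_cutoff = ne_maf_cutoff, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full hatchery-genetics analysis pipeline
#'
#' Stages, in order: read (or accept) genotypes; sequential filtering; RDA
#' outlier scans (provenance; wild vs hatchery) and locus partitioning;
#' diversity panel per population x cohort and locus subset; pairwise FST;
#' PCoA on bitwise distances; LD-Ne per group (plus donor-contribution
#' percentages for hatchery cohorts); optional donor-number simulation on
#' the wild donors. All outputs are written as CSV/JSON under
#' `cfg$out_dir`, with a manifest recording the seed, stage row/locus
#' counts and output files. A stage failure stops the run but leaves the
#' completed stages' outputs and an `error.json` report.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `genotypes`,
#'   `filter_log`, `partition`, `rda`, `diversity`, `fst`, `pcoa`, `ne`,
#'   `simulation`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list(), outputs = character())
  res <- list()
  stage <- "read"
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, name)
  }
  tryCatch({
    g <- if (inherits(cfg$genotypes, "geno")) cfg$genotypes else
      read_genotypes(cfg$genotypes)
    manifest$stages$read <- list(individuals = n_individuals(g),
                                 loci = n_loci(g))

    stage <- "filter"
    if (!is.null(cfg$filter)) {
      cfg$filter$rng_seed <- cfg$seed
      fl <- apply_filters(g, cfg$filter)
      g <- fl$genotypes
      res$filter_log <- fl$log
      emit(fl$log, "filter_log.csv")
      manifest$stages$filter <- list(individuals = n_individuals(g),
                                     loci = n_loci(g))
    }
    res$genotypes <- g

    stage <- "outliers"
    rda_prov <- rda_scan(g, "population", sd_threshold = cfg$sd_threshold)
    rda_hatch <- rda_scan(g, "cohort", sd_threshold = cfg$sd_threshold)
    part <- partition_loci(g$loci$locus_id, rda_prov, rda_hatch)
    res$rda <- list(provenance = rda_prov, hatchery = rda_hatch)
    res$partition <- part
    emit(dplyr::bind_rows(provenance = tidy(rda_prov),
                          hatchery = tidy(rda_hatch), .id = "predictor"),
         "rda_loadings.csv")
    jsonlite::write_json(unclass(part),
                         file.path(cfg$out_dir, "locus_partition.json"),
                         auto_unbox = FALSE)
    manifest$outputs <- c(manifest$outputs, "locus_partition.json")
    manifest$stages$outliers <- list(
      provenance = length(part$provenance),
      hatchery = length(part$hatchery), neutral = length(part$neutral))

    stage <- "diversity"
    res$diversity <- diversity_report(g, "population_cohort",
                                      partition = part, by_age = TRUE,
                                      n_boot = cfg$fis_boot, seed = cfg$seed)
    emit(res$diversity, "diversity_report.csv")

    stage <- "fst"
    subsets <- list(all = NULL, neutral = part$neutral,
                    provenance = part$provenance, hatchery = part$hatchery)
    fst_all <- purrr::imap_dfr(subsets, function(sub, lab) {
      if (!is.null(sub) && length(sub) == 0) return(NULL)
      tidy(pairwise_fst(g, "population_cohort", loci = sub,
                        n_boot = cfg$fst_boot, seed = cfg$seed,
                        subset_label = lab))
    })
    fst_all$p_adjusted <- stats::p.adjust(fst_all$p_value, method = "BH")
    res$fst <- fst_all
    emit(fst_all, "fst_pairwise.csv")

    stage <- "pcoa"
    pc <- pcoa(bitwise_distance(g), n_axes = 2)
    res$pcoa <- pc
    emit(tidy(pc), "pcoa_coordinates.csv")

    stage <- "ne"
    groups <- resolve_groups(g, "population_cohort")
    ne_rows <- purrr::imap_dfr(groups, function(ii, lab) {
      est <- tryCatch(
        ld_ne(g, ii, loci = part$neutral, maf_cutoff = cfg$ne_maf_cutoff),
        error = function(e) NULL)
      if (is.null(est)) return(NULL)
      est$group <- lab
      est
    })
    res$ne <- ne_rows
    emit(ne_rows, "ne_estimates.csv")

    stage <- "simulate"
    if (!is.null(cfg$sim)) {
      wild <- geno_subset(g, g$individuals$cohort == "wild")
      cfg$sim$seed <- cfg$seed
      res$simulation <- donor_sweep(wild, cfg$sim)
      emit(tibble::as_tibble(res$simulation), "simulation_sweep.csv")
    }

    manifest$config_hash <- digest_config(cfg)
    res$manifest <- manifest
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    class(res) <- "pipeline_result"
    res
  }, error = function(e) {
    report <- list(failed_stage = stage, message = conditionMessage(e),
                   completed = manifest$outputs)
    jsonlite::write_json(report, file.path(cfg$out_dir, "error.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

# Cheap deterministic fingerprint of the config (no external digest dep).
digest_config <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 257)) %%
            .Machine$integer.max)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$genotypes)
  if (!is.null(x$partition)) print(x$partition)
  invisible(x)
}
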