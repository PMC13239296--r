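#' Configuration for the forward random-mating simulation
#'
#' Defaults mirror a donor-number sweep for a restored, closed population:
#' donor counts 2–10 by two then 20–100 by ten, 500 randomly mating
#' offspring per generation for 100 generations, 100 bootstrap draws of
#' donors per donor count, diversity recorded at generations 1, 3, 10 and
#' 100, 1:1 sex ratio, no selfing.
#'
#' @param donor_counts Integer vector of donor pool sizes.
#' @param n_offspring Offspring per generation.
#' @param generations Number of generations simulated.
#' @param checkpoints Generations at which He/PL are recorded (subset of
#'   `1:generations`).
#' @param n_boot Bootstrap replicates per donor count.
#' @param seed Master seed; replicate streams are derived from it so cells
#'   are independent of sweep composition.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(donor_counts = c(seq(2, 10, by = 2), seq(20, 100, by = 10)),
                       n_offspring = 500, generations = 100,
                       checkpoints = c(1, 3, 10, 100), n_boot = 100,
                       seed = 1L) {
  stopifnot(all(donor_counts >= 2), n_boot >= 1,
            all(checkpoints >= 1), all(checkpoints <= generations))
  structure(list(donor_counts = as.integer(donor_counts),
                 n_offspring = as.integer(n_offspring),
                 generations = as.integer(generations),
                 checkpoints = sort(as.integer(checkpoints)),
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "sim_config")
}

#' Assign parents to dam and sire pools
#'
#' Seeded shuffle then split at a 1:1 ratio; with an odd count the extra
#' individual goes to the dam side.
#'
#' @param parents A [geno()] object (>= 2 individuals).
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @return A list with `dams` and `sires` (row indices into `parents`).
#' @export
assign_sexes <- function(parents, seed = NULL) {
  n <- n_individuals(parents)
  if (n < 2) stop(">= 2 parents required", call. = FALSE)
  shuffle <- if (is.null(seed)) sample.int(n) else
    withr::with_seed(seed, sample.int(n))
  n_dam <- ceiling(n / 2)
  list(dams = shuffle[seq_len(n_dam)], sires = shuffle[(n_dam + 1):n])
}

# Impute missing parental calls by drawing genotypes from the pool allele
# frequency at the locus (HW draws); transmission needs complete genotypes.
impute_pool <- function(m) {
  if (!anyNA(m)) return(m)
  p <- colSums(m, na.rm = TRUE) / pmax(2 * colSums(!is.na(m)), 1)
  for (j in which(colSums(is.na(m)) > 0)) {
    nas <- which(is.na(m[, j]))
    m[nas, j] <- stats::rbinom(length(nas), 2, p[j])
  }
  m
}

#' Random mating between dam and sire pools
#'
#' Each offspring draws a dam and a sire uniformly and independently; at
#' each (unlinked) locus one allele is sampled from each parent, a
#' heterozygote transmitting either allele with probability 1/2. Missing
#' parental calls must be imputed beforehand (see [simulate_generations()]).
#'
#' @param parents A [geno()] object with complete calls.
#' @param dams,sires Row indices into `parents`.
#' @param n_offspring Number of offspring to produce.
#' @return A [geno()] object of offspring (`cohort = "simulated"`).
#' @export
mate_randomly <- function(parents, dams, sires, n_offspring) {
  stopifnot(length(dams) >= 1, length(sires) >= 1)
  m <- parents$calls
  if (anyNA(m)) stop("parental calls contain missing values; impute first",
                     call. = FALSE)
  dam_pick <- dams[sample.int(length(dams), n_offspring, replace = TRUE)]
  sire_pick <- sires[sample.int(length(sires), n_offspring, replace = TRUE)]
  dm <- m[dam_pick, , drop = FALSE]
  sm <- m[sire_pick, , drop = FALSE]
  L <- ncol(m)
  off <- matrix(stats::rbinom(n_offspring * L, 1, dm / 2) +
                  stats::rbinom(n_offspring * L, 1, sm / 2),
                nrow = n_offspring)
  geno(off,
       loci = parents$loci,
       individuals = tibble::tibble(
         individual_id = paste0("off", seq_len(n_offspring)),
         population = parents$individuals$population[dam_pick],
         cohort = "simulated"))
}

#' Simulate a closed, randomly mating restored population
#'
#' Generation 1 is produced by random mating over the donors (sexes assigned
#' 1:1 at random); every later generation is produced by the previous
#' generation's `n_offspring` individuals with sexes reassigned. The
#' population is closed: no migration, mutation or selection, loci unlinked.
#' He (2pq) and PL are recorded at the requested checkpoints; checkpoint
#' genotype matrices can be kept as well.
#'
#' @param donors A [geno()] object of founders.
#' @param cfg A [sim_config()] (its `donor_counts`/`n_boot` are ignored
#'   here; only `n_offspring`, `generations`, `checkpoints` matter).
#' @param keep_genotypes Keep the checkpoint [geno()] objects?
#' @return A tibble (`generation`, `he`, `pl_pct`), with the checkpoint
#'   genotype objects in attribute `"genotypes"` when requested.
#' @export
simulate_generations <- function(donors, cfg = sim_config(),
                                 keep_genotypes = FALSE) {
  donors$calls <- impute_pool(donors$calls)
  current <- donors
  sexes <- assign_sexes(current)
  rows <- list(); kept <- list()
  for (t in seq_len(max(cfg$checkpoints))) {
    current <- mate_randomly(current, sexes$dams, sexes$sires,
                             cfg$n_offspring)
    sexes <- assign_sexes(current)
    if (t %in% cfg$checkpoints) {
      p <- colMeans(current$calls) / 2
      rows[[length(rows) + 1]] <- tibble::tibble(
        generation = t,
        he = mean(2 * p * (1 - p)),
        pl_pct = 100 * mean(p > 0 & p < 1))
      if (keep_genotypes) kept[[as.character(t)]] <- current
    }
  }
  out <- dplyr::bind_rows(rows)
  if (keep_genotypes) attr(out, "genotypes") <- kept
  out
}

#' Donor-number sweep with bootstrap replication
#'
#' For each donor count and bootstrap replicate, donors are drawn without
#' replacement from the wild pool and [simulate_generations()] is run;
#' means and standard errors of He and PL over replicates are returned per
#' donor count and checkpoint. RNG streams are derived hierarchically from
#' the config seed (donor count x replicate), so adding donor counts leaves
#' other cells unchanged.
#'
#' @param wild A [geno()] object (the donor pool; must hold at least
#'   `max(donor_counts)` individuals).
#' @param cfg A [sim_config()].
#' @return A tibble of class `sim_result`: `donor_count`, `generation`,
#'   `metric` (`"he"`/`"pl_pct"`), `mean`, `se`, `n_boot`.
#' @export
donor_sweep <- function(wild, cfg = sim_config()) {
  if (max(cfg$donor_counts) > n_individuals(wild)) {
    stop("donor count ", max(cfg$donor_counts), " exceeds pool size ",
         n_individuals(wild), call. = FALSE)
  }
  cells <- list()
  for (dc in cfg$donor_counts) {
    reps <- purrr::map_dfr(seq_len(cfg$n_boot), function(b) {
      cell_seed <- (cfg$seed * 1000003L + dc * 1009L + b) %% 2147483647L
      withr::with_seed(cell_seed, {
        donors <- geno_subset(wild, individuals =
                                sample.int(n_individuals(wild), dc))
        tr <- simulate_generations(donors, cfg)
        tr$replicate <- b
        tr
      })
    })
    reps$donor_count <- dc
    cells[[length(cells) + 1]] <- reps
  }
  long <- dplyr::bind_rows(cells)
  out <- long |>
    tidyr::pivot_longer(c("he", "pl_pct"), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$donor_count, .data$generation, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      n_boot = dplyr::n(), .groups = "drop")
  class(out) <- c("sim_result", class(out))
  attr(out, "replicates") <- long
  out
}

#' Closed-form expected heterozygosity decay under drift
#'
#' With `Ne = 4 Nd Ns / (Nd + Ns)` for separate sexes, expected
#' heterozygosity decays as `He_t = He_0 (1 - 1/(2 Ne))^t`. Used as the
#' analytical oracle the simulator is validated against.
#'
#' @param he0 Initial expected heterozygosity.
#' @param n_dams,n_sires Breeding females and males (> 0).
#' @param t Generations (>= 0).
#' @return Expected He at generation `t`.
#' @export
expected_he_decay <- function(he0, n_dams, n_sires, t) {
  if (n_dams <= 0 || n_sires <= 0) stop("parent counts must be positive",
                                        call. = FALSE)
  ne <- 4 * n_dams * n_sires / (n_dams + n_sires)
  he0 * (1 - 1 / (2 * ne))^t
}

#' Donor-number sweep plot (mean +/- SE per checkpoint)
#'
#' @param object A `sim_result` from [donor_sweep()].
#' @param metric `"he"` or `"pl_pct"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_result <- function(object, metric = c("he", "pl_pct"), ...) {
  met <- match.arg(metric)
  df <- dplyr::filter(tibble::as_tibble(object), .data$metric == met)
  df$generation <- factor(df$generation,
                          labels = paste0("F", sort(unique(df$generation))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$donor_count, y = .data$mean,
                                   colour = .data$generation)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.2) +
    ggplot2::labs(x = "number of donors",
                  y = if (metric == "he") "expected heterozygosity" else
                    "% polymorphic loci",
                  colour = "generation") +
    ggplot2::theme_minimal()
}
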