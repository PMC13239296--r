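Package: hatchgen
Title: Genetic Risk Assessment for Hatchery-Based Marine Restoration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the genetic consequences of hatchery propagation
    in marine restoration programs, motivated by kelp (Ecklonia radiata)
    restoration hatcheries. Provides a genotype container with DArT-style locus
    metadata, sequential SNP and individual filtering, diversity panels
    (observed/expected heterozygosity, percent polymorphic loci, rarefied
    allelic richness, private alleles, FIS with bootstrap confidence
    intervals), Weir-Cockerham FST with locus bootstrap and FDR correction,
    PCoA on bitwise distances, redundancy-analysis outlier scans and
    neutral/provenance/hatchery locus partitions, linkage-disequilibrium and
    molecular-coancestry effective population size estimators, a forward
    random-mating breeding simulator with donor-number sweeps, and a
    synthetic-data generator emulating two differentiated wild kelp populations
    and their mass-spawned F1 cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
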