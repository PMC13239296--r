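# hatchgen

Genetic risk assessment for hatchery-based marine restoration.

Restoration programs for habitat-forming species — kelps above all — now
mass-produce outplants in hatcheries: sorus tissue from ~100 wild donors
per site is pooled, mass-spawned, and grown into F1 sporophytes. Even at
that donor number, a single hatchery generation can lose substantial
genetic diversity through skewed parental contributions (drift and
bottlenecks), kin mating and selfing (inbreeding), and selection to the
benign culture environment (domestication). `hatchgen` is an R package
for the practitioners and population geneticists monitoring those risks:
it takes a biallelic SNP matrix with DArT-style locus metadata for wild
donor and hatchery cohorts and quantifies what one generation of
propagation did to them — and what donor numbers future generations will
need.

## What it computes

* **Sequential SNP/individual filtering** for reduced-representation
  data: depth window 5–12, reproducibility ≥ 0.96, one SNP per fragment,
  MAF ≤ 1% excluded, missingness margins, monomorphic removal — each
  stage logged (`apply_filters()`).
* **Diversity panel** per population × cohort and locus subset:
  H<sub>o</sub>, H<sub>e</sub> = 2pq (and unbiased uH<sub>e</sub>),
  percent polymorphic loci, rarefied allelic richness (hypergeometric
  closed form), private alleles, and F<sub>IS</sub> = 1 − H̄<sub>o</sub>/ūH<sub>e</sub>
  with a 1000-replicate locus bootstrap CI (`diversity_report()`).
* **Differentiation and structure**: Weir–Cockerham
  θ = Σa / Σ(a+b+c) with a 999-replicate locus bootstrap and
  Benjamini–Hochberg correction across pairs (`pairwise_fst()`); PCoA on
  bitwise dosage distances (`pcoa()`, `bitwise_distance()`).
* **Outlier partitioning**: redundancy-analysis scans against provenance
  and wild-vs-hatchery predictors, flagging loci with |z| > 3 on the
  constrained axis, partitioned into neutral / provenance-associated /
  hatchery-associated subsets (`rda_scan()`, `partition_loci()`).
* **Effective population size**: the linkage-disequilibrium method on
  Burrows composite r², with the Waples-corrected sampling expectation
  E[r²|S] and back-transform
  N̂<sub>e</sub> = (1/3 + √(1/9 − 2.76 r²′)) / (2 r²′), jackknife or
  parametric CIs (`ld_ne()`); molecular-coancestry N<sub>eb</sub> as an
  alternative (`coancestry_ne()`); donor-contribution percentages
  (`donor_contribution_pct()`).
* **Forward breeding simulation**: closed random-mating populations of
  500 offspring per generation for 100 generations, donor counts 2–100,
  100 bootstraps, He and PL at F1/F3/F10/F100, validated against the
  closed-form drift decay He₀·(1 − 1/(2Ne))ᵗ (`donor_sweep()`,
  `expected_he_decay()`).
* **A synthetic-data generator** that emulates the whole study system —
  two Balding–Nichols populations at F<sub>ST</sub> 0.08 with a 2–3×
  diversity contrast, DArT metadata, 18.3% missingness, and mass-spawned
  F1 cohorts with Dirichlet-skewed parentage, selfing, and designated
  selected loci (`scenario_full_study()`) — so the entire pipeline is
  testable offline.

Everything returns tibbles (with `tidy()`/`glance()` methods and
`autoplot()` for ordinations, scans and sweeps) and chains with the
pipe; `run_pipeline()` orchestrates all stages from one config and seed
into CSV/JSON outputs plus a provenance manifest. A thin CLI wrapper
lives at `inst/scripts/hatchgen-cli.R`.

## Worked example

```r
library(hatchgen)

b <- scenario_full_study(seed = 1)   # synthetic two-provenance study
b
#> <study_bundle> seed = 1
#> <geno> 298 individuals x 1600 loci
#>   missing calls: 18.3%
#>   cool/hatchery: n = 36
#>   cool/wild: n = 100
#>   warm/hatchery: n = 62
#>   warm/wild: n = 100
#>   designated: 27 provenance-divergent, 15 hatchery-selected loci

res <- run_pipeline(pipeline_config(b$genotypes, out_dir = "out",
                                    filter = NULL, fst_boot = 199,
                                    fis_boot = 199, ne_maf_cutoff = 0.02,
                                    seed = 1))
res$partition
#> <locus_partition> neutral = 1544, provenance = 41, hatchery = 20, overlap = 5

dplyr::filter(res$diversity, subset == "neutral", is.na(age_months)) |>
  dplyr::select(group, n, pl_pct, ho, he, fis)
#>   group           n pl_pct      ho      he     fis
#> 1 cool_hatchery  36  16.77 0.01535 0.01597 0.05547
#> 2 cool_wild     100  26.62 0.01518 0.01535 0.01698
#> 3 warm_hatchery  62   5.57 0.00502 0.00542 0.08276
#> 4 warm_wild     100  11.14 0.00616 0.00614 0.00257

res$ne |> dplyr::select(group, ne, ci_lo, ci_hi)
#>   group            ne ci_lo ci_hi
#> 1 cool_hatchery  58.1  36.0 143.5
#> 2 cool_wild    4961.6 384.9   Inf
#> 3 warm_hatchery  18.9  12.9  31.7
#> 4 warm_wild       Inf 331.0   Inf
```

Read: the cool wild donors carry about 2.5× the warm donors' expected
heterozygosity (0.015 vs 0.006); one hatchery generation halves the
percentage of polymorphic loci in both provenances (26.6 → 16.8 and
11.1 → 5.6) while H<sub>e</sub> barely moves; F<sub>IS</sub> rises in
both F1 cohorts; and the effective population size collapses from
"indistinguishable from infinite" in the wild samples to 58 (58% of the
100 donors) in the cool cohort and 19 (19%) in the strongly skewed warm
cohort. That asymmetry — heterozygosity stable, rare-allele metrics and
N<sub>e</sub> crashing — is exactly the signature that makes monitoring
heterozygosity alone insufficient. The donor-number sweep
(`donor_sweep()`, `autoplot()`) turns the same machinery around: He
retention plateaus by a few tens of donors, but retaining polymorphic
loci across 100 generations keeps improving all the way to 100 donors.

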