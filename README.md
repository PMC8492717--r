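# mtphylogeo

Intraspecific mitochondrial DNA phylogeography, end to end, in R.

`mtphylogeo` is aimed at population geneticists working with aligned
mtDNA fragments (control region / D-loop, *CYTB*, …) from structured
samples — breeds, localities, metapopulations — who want to go from a
FASTA alignment plus a metadata table to the full set of standard
analyses without leaving R:

* **Haplotype statistics** — haplotype collapsing, polymorphic sites,
  Nei's gene diversity with its sampling standard error,

  h = n/(n−1) · (1 − Σᵢ pᵢ²),  V(h) = 2/[n(n−1)] · {2(n−2)[Σpᵢ³ − (Σpᵢ²)²] + Σpᵢ² − (Σpᵢ²)²};

* **AMOVA** — one- and two-level analysis of molecular variance on
  pairwise sequence distances (Excoffier-style sums of squared
  deviations), Φ-statistics (Φ_ST, Φ_CT, Φ_SC), permutation p-values,
  and pairwise Φ_ST matrices;
* **Ordination** — classical (Torgerson) multidimensional scaling of
  the Φ_ST matrix, with an optional SMACOF refinement;
* **Phylogenetics** — p / K2P / TN93 / pooled-frequency ("composite")
  distances, neighbour-joining with the Studier–Keppler Q-criterion
  and deterministic tie-breaks, site-resampling bootstrap supports,
  and assignment of samples to mtDNA lineages (A–E) against labelled
  reference haplotypes;
* **Median-joining networks** — the Bandelt minimum-spanning-network +
  quasi-median algorithm with ε tolerance, median-vector purging,
  GML/TSV export;
* **ABC** — a single-locus coalescent simulator for population-split
  colonization scenarios (haploid gene-copy Ne, times in generations,
  HKY mutations), DIYABC-style summary statistics (π, rarest-allele
  counts at segregating sites, between-population π, Φ_ST),
  reference-table construction, model choice by polychotomous weighted
  logistic regression on the closest simulations, posterior predictive
  error, parameter estimation by weighted local-linear regression with
  logit-transformed parameters, RMAE validation, and posterior
  predictive goodness-of-fit;
* **Synthetic data** — a generator that emulates the structure of real
  breed surveys (divergent lineages, star-like expansions, an outlier
  breed dominated by the minor lineage, singleton-rich spectra), with
  exact ground truth for testing.

## Worked example

```r
library(mtphylogeo)

gen <- generate_breeds(generator_config(seed = 1))   # 13 breeds x 28 samples
a <- gen$alignment
a
#> mt_alignment: 364 samples x 612 bp; 13 breed(s), 1 metapopulation(s)

head(diversity_table(a), 4)
#>   population  n  k      h    se_h
#> 1    Breed01 28 25 0.9841 0.01793
#> 2    Breed02 28 18 0.9180 0.04362
#> 3    Breed03 28 19 0.8810 0.06001
#> 4    Breed04 28 24 0.9735 0.02375

amova(a)
#> AMOVA (pairwise_difference distance)
#>              source  df     SS sigma2   pct
#>   among_populations  12  645.5  1.849 47.93
#>  within_populations 351  705.2  2.009 52.07
#>               total 363 1350.7     NA    NA
#> Phi:  Phi_ST = 0.4793
```

`h` close to 1 with many singleton haplotypes is the typical signature
of an expanding mtDNA lineage; the large among-breed percentage here is
driven by the generator's outlier breed, which carries 79% of the minor
lineage (remove it and the among-breed component collapses, the same
diagnostic move used for outlier breeds in real surveys).

```r
la <- assign_lineage(a, gen$truth$founders)   # nearest labelled reference
la
#> lineage assignment (min_distance):
#>   A   B
#> 336  28

net <- median_joining(collapse_haplotypes(a))
net
#> haplotype network: 243 nodes (35 median vectors), 266 edges
```

A small ABC run contrasting two colonization routes of the minor
lineage into the Indian subcontinent (inland stepping-stone vs an
independent maritime introduction); the pseudo-observed data were
simulated under the maritime scenario:

```r
scns <- default_scenarios("lineageB")
pri  <- prior_spec()                     # documented placeholder priors
rt   <- build_reference_table(scns, pri, 2000, c(ME=20, MP=20, IS=20),
                              600, seed = 2)
mc   <- model_choice(rt, obs, tolerance = 0.05)
mc
#> ABC model choice (logistic estimator, 200 retained)
#>   1_inland: 0.0646 (0.0000 - 0.1448)
#>   2_sea [winner]: 0.9354 (0.8552 - 1.0000)

estimate_parameters(rt, mc$winner, obs, tolerance = 0.05)
#> ABC posterior for scenario 2_sea ( 100 retained )
#>  parameter    median      q2.5     q97.5
#>        NME 4.304e+04 1.123e+04 9.392e+04
#>        ...
```

The full workflow (diversity → AMOVA/Φ_ST → MDS → lineage assignment →
network → ABC) also runs from a single JSON configuration via
`run_pipeline()` or the CLI wrapper in `inst/cli/mtphylogeo`, which
writes every export plus a manifest of input hashes and seeds.

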