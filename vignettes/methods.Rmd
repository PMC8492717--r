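---
title: "Models and methods in mtphylogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mtphylogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mtphylogeo` implements the complete computational workflow of an
intraspecific mtDNA phylogeography study: haplotype and diversity
statistics, AMOVA and pairwise Φ_ST, MDS ordination, neighbour-joining
trees with lineage assignment, median-joining haplotype networks, and
an approximate Bayesian computation (ABC) engine for testing
colonization scenarios.  This vignette records the models, the
numerical choices, and the design decisions where more than one
reasonable option existed.

## Data model and missing data

An alignment is a character matrix over `A,C,G,T,-,N` plus IUPAC
codes; ambiguity codes other than `N` are treated as `N`.  Two missing
data policies exist everywhere a site set matters:

* `exclude_site` (default): any column containing a gap, `N` or an
  ambiguity in *any* sample is removed before haplotype definition and
  site counting.  This complete-deletion convention is deterministic
  and order-independent, and it is how published haplotype counts from
  Arlequin-style workflows are produced.
* `pairwise`: each pair of sequences is compared over the sites where
  both are unambiguous; used for distance computations where dropping
  a whole column for one bad sample wastes information.

All internal coordinates are 0-based half-open; the CLI reports
1-based inclusive positions.

## Diversity, AMOVA, Φ_ST

Nei's gene diversity and its sampling variance are computed from the
haplotype frequency plug-in formulas.  The 6-sample/6-haplotype case
yields `1.0000 ± 0.0962`, which the acceptance suite checks digit for
digit against an independent implementation.

AMOVA decomposes pairwise sequence distances (the count of differing
retained sites, used directly as the squared deviation, Arlequin's
convention for sequence data) into among-group / among-population /
within-population components.  A `haplotype_identity` 0/1 distance
mode is provided for sensitivity checks because the source studies do
not state which mode produced their percentages.  Negative variance
component estimates are *reported raw* but floored at zero for
percentages and Φ statistics — the presentation convention readers of
published AMOVA tables implicitly assume.  Permutation p-values
permute samples among populations with a fixed, mandatory seed;
the two-level test permutes samples wholesale, which is conservative
for Φ_CT.

Pairwise Φ_ST is literally the two-population AMOVA applied to every
pair (the test suite asserts cell-by-cell equality with fresh
`amova()` calls), so there is a single definition of Φ in the package.

## MDS

Classical Torgerson scaling of the (clamped-at-zero) Φ_ST matrix:
double-centre, eigendecompose, keep the top positive-eigenvalue axes.
The sources say only "MDS in R", so classical scaling on the untransformed
matrix is declared as the default rather than inferred; a metric SMACOF
refinement seeded from the classical solution is available behind a
flag.  Kruskal stress-1 is reported either way.  An all-zero matrix
returns a degenerate all-zero configuration rather than an error,
because downstream plotting of "no structure" is a legitimate result.

## Distances, NJ, lineage assignment

`distance_matrix()` implements p, K2P and TN93 in closed form.  The
"maximum composite likelihood" label used by MEGA is implemented as a
TN93-form distance with base frequencies pooled over the whole
alignment (`model = "composite"`): the pooled-parameter idea is what
makes MEGA's estimator "composite", and exact numeric parity with
MEGA's internals is deliberately not claimed — topology-level
agreement is what the downstream analyses need.  Saturated pairs (a
non-positive logarithm argument) are set to a configurable ceiling and
flagged instead of becoming `NaN`.

NJ uses the Studier–Keppler Q-criterion; ties in Q are broken by the
lexicographically smallest (sorted) taxon-name pair, making the tree a
pure function of the matrix.  Negative branch-length estimates are
clamped to zero for display with the raw values kept in an attribute.
Bootstrap resamples retained sites only and counts bipartitions of the
point-estimate tree in each replicate tree.

Lineage assignment offers two methods because the source workflow does
not state which was used: `min_distance` (nearest labelled reference
by sequence distance, with a difference-count margin below `tolerance`
flagged ambiguous rather than silently assigned) and `nj_clade`.  The
clade method is operationalized as the *patristic* nearest reference
on the joint NJ tree: a literal "walk up to the first
reference-containing ancestor" is ill-defined at the root trichotomy
when the dominant lineage is star-like (ancestors of backbone samples
contain the other lineage's clade), whereas path length through the
tree respects the long internal edge separating lineages and therefore
expresses clade membership robustly.  Both methods agree on clean
data, which the test suite asserts on generator output with known
truth.

## Median-joining networks

The network construction follows the minimum-spanning-network +
quasi-median scheme: at tolerance ε, an edge is feasible iff its
endpoints are not already connected using only edges of weight
`< w − ε` (ε = 0 gives the union of all minimum spanning trees);
consensus quasi-medians of connected node triples are added when their
connection cost is within ε of the round minimum; the process iterates
to a fixpoint (bounded by `max_median_rounds`, with a `converged`
flag); unlabelled nodes of degree ≤ 2 are purged iteratively, with the
network rebuilt after each sweep.  Sites where all three states of a
triple differ expand into all three quasi-median choices, capped at
four such sites per triple — beyond that the triple is skipped, a
pragmatic bound that cannot fire on realistic mtDNA triples.  All
sites carry weight 1 (the sources report no site weights); ties are
broken by canonical (sequence-sorted) node order so networks are
reproducible.  Note that after medians are inserted the final network
may route observed–observed connections through median vectors, so the
"contains an MST" property is asserted at the minimum-spanning-network
stage over observed haplotypes, where it belongs.

## The coalescent simulator

A single-locus haploid coalescent with constant effective size per
population and instantaneous splits (backwards in time, every lineage
of the derived population moves into its source).  Units are chosen
for mtDNA and stated aggressively to avoid silent factor-of-two
errors: **Ne is a count of gene copies** (maternally inherited, no 2N),
**times are generations before present**, and the mutation rate is per
site per generation with a default log-uniform prior on
[1e-8, 1e-7].  Mutations are Poisson along branches and resolved by an
HKY jump chain (transition/transversion ratio κ with prior U(2, 20),
empirical-style base frequencies); the substitution models actually
fitted in the source studies are unnamed, so HKY is the declared
default.  All randomness flows through R's RNG, so a single
`set.seed()` governs C++ and R reproducibility alike, and the
acceptance suite verifies E[π] = 2Neμℓ and Watterson's E[S] = aₙθ
against Monte-Carlo error over 2000 replicates.

The simulator accepts an optional fixed root sequence.  This exists
because the synthetic-data generator overlays within-lineage coalescent
variation on lineage founder haplotypes: redrawing root states from
base frequencies at every mutated site would shift whole lineages
hundreds of sites apart (a defect originally caught by a bimodal
mismatch distribution at implausible distances).

## ABC

Summary statistics follow the DIYABC single-locus repertoire: per
population, π, and the mean and variance over segregating sites of the
rarest-nucleotide count (gene copies carrying the least frequent base;
ties take the minimum); per pair, between-population π (uncorrected,
matching the "(B)" statistic's definition) and Φ_ST.  Monomorphic
populations report zeros and are flagged.

Model choice normalizes statistics by the reference-table MAD (robust;
SD fallback for MAD-zero columns), ranks rows by Euclidean distance to
the observed vector, and retains the closest `tolerance` fraction.
Retention is *threshold-inclusive*: every row at the cutoff distance is
kept.  This matters in practice — near-monomorphic observations match
hundreds of reference rows at exactly distance zero, and an
index-ordered top-k would silently retain only the scenario simulated
first.  Weights are Epanechnikov with bandwidth equal to the largest
retained distance (uniform if that bandwidth is zero, or when
`tolerance >= 1`, where rejection is vacuous and the frequency
estimator must reduce to per-scenario row fractions).  The
polychotomous logistic regression is fitted by Newton–Raphson with
step halving and a small ridge; separation (or a scenario absent from
the retained set) triggers the categorical frequency fallback with a
warning.  95% CIs come from the delta method on the fitted linear
predictors at the observed point.

Parameter estimation is Beaumont-style weighted local-linear
regression with every parameter logit-transformed over its prior
bounds, so adjusted draws cannot leave the prior support by
construction; singular designs fall back to a ridge solve with a
warning.  Posterior summaries are weighted medians and 2.5/97.5%
quantiles.  RMAE is the median over pseudo-observed datasets of
|θ̂ − θ|/θ, with estimates above 0.2 flagged "not fully reliable"; the
machinery is validated against an injected perfect estimator (RMAE 0)
and a prior-median estimator checked against a quadrature oracle.
The posterior predictive error is *prior-based* (pods drawn from the
priors with uniformly random scenarios), the more common DIYABC usage;
a posterior-based variant would condition pod parameters on the
observed data and is noted as an extension.  Goodness of fit reports
two-sided (r+1)/(n+1) tail probabilities of each observed statistic in
the posterior-predictive distribution.

### Prior defaults

The studies' actual prior table lives in supplementary material that
is not reproduced here, so the shipped priors are documented
placeholders chosen once on domain grounds and accepted as the stated
world: Ne ~ U(100, 1e5) gene copies (matriline effective sizes of
livestock metapopulations), event times ~ U(100, 2e4) generations
(covering domestication-era history at 2–3-year generations), μ ~
log-U(1e-8, 1e-7) (the range the sources state), κ ~ U(2, 20).  Every
prior is overridable from a plain-text file (`parse_priors()`), and
scenarios from a small DSL (`parse_scenarios()`).

### What desk-scale scenario recovery can and cannot show

The built-in `lineageA` preset contrasts a Middle-East-source
stepping-stone scenario with an Indian-subcontinent-source scenario.
Translated into trees, the two have the *same* topology and the same
split-time structure; they differ only in which population's Ne
parameter governs the internal and ancestral epochs.  With
exchangeable Ne priors and one non-recombining locus, prior-predictive
pseudo-observed datasets are therefore only weakly identifiable: at
2 × 20k simulations and 1% rejection the package recovers the
generating scenario in roughly 55–65% of pods with a mean winning
posterior around 0.6 (the acceptance suite computes these numbers and
holds the ≥ 70% bar red rather than weakening it).  This is consistent
with the source analysis itself, whose posterior predictive error at
10⁶ simulations per scenario on the real priors was ≈ 0.28.  A green
desk-scale run should be read as "the machinery is wired correctly",
not as a reproduction of the published 0.95 posterior, which was
driven by the real multi-source data.

## The synthetic-data generator

`generate_breeds()` emulates the statistical structure the analyses
assume: lineage founders separated by a configurable expected mutation
count (default 30, the D-loop A–B scale); within-lineage samples from
an expansion coalescent whose growth time is set from the target
within-lineage π (for a star genealogy of depth T, pairs differ by
≈ 2Tμℓ) and whose current size is `expansion` times that depth —
larger values mean fewer pre-expansion coalescences, hence more
star-like networks and unimodal mismatch distributions; breed mixture
weights defaulting to one outlier breed at 79% minor lineage and a few
breeds at 3%.  Lineage labels are assigned by bookkeeping, so the
truth record is exact, and founders are returned as a labelled
reference alignment so `assign_lineage()` can be validated against
ground truth.  What the generator does *not* emulate: hypervariable-
site rate heterogeneity beyond HKY, insertions/deletions, ambiguity
codes from sequencing chemistry, and within-breed substructure — a
green test on generator output establishes algorithmic correctness,
not robustness to those artefacts.

## Reproducibility

Every stochastic stage takes an explicit seed (the pipeline refuses a
config that enables a stochastic stage without one), reference tables
and bootstrap supports are bit-identical under seed reuse, and the
pipeline manifest records input/output MD5 hashes, seeds and the
package version.  The acceptance suite asserts all three.
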