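---
title: "Models and methods behind raftgen"
author: "raftgen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind raftgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftgen)
```

# The scientific problem

raftgen implements a comparative population-genetic workflow for codominant,
highly multiallelic markers (microsatellites) scored in two co-distributed,
morphologically cryptic sister species sampled at the same georeferenced
coastal sites. The motivating question is ecological: does association with a
buoyant macroalga (which can raft between shores) leave a detectable
signature in population-genetic connectivity, relative to a rock-associated
sister species with the same larval biology? Answering it requires a chain of
standard but fiddly analyses, each implemented here as a tested, reusable
component:

1. **Genetic species assignment** — no-admixture Bayesian clustering with a
   Q-value threshold, because the species cannot be told apart reliably in
   the field.
2. **Null-allele handling** — microsatellite null alleles (primer-site
   mutations that stop an allele amplifying) create apparent homozygote
   excess and blank genotypes; their frequency is estimated per population
   and locus by maximum likelihood and the allele frequencies are corrected.
3. **Differentiation statistics** — Jost's D, Weir–Cockerham
   F~ST~ (raw and null-corrected), Hedrick's standardized G″~ST~, and the
   island-model migrant number N~m~.
4. **Spatial structure** — null-aware Cavalli-Sforza & Edwards chord
   distances, Mantel and partial Mantel tests against geographic distance
   and a binary habitat-discontinuity ("gap") indicator, and the spatial
   analysis of shared alleles (SAShA).
5. **A synthetic genotype generator** that reproduces the statistical
   structure these analyses assume, so every stage is testable without any
   external download.

# Data model

`GenotypeData` stores apparent genotypes: two integer allele labels
(fragment sizes in base pairs) per individual and locus, with a fully blank
locus encoded as a missing pair. Half-called genotypes are rejected at parse
time: the scoring pipelines this mirrors produce only full or blank calls.
Sampling site doubles as the population unit. Genepop files carry genotypes
and populations; the richer CSV table format also carries habitat labels and
travels with a sites file (id, latitude, longitude).

Individuals scored at fewer than four of seven loci are dropped by
`filterByScoredLoci()` before anything else; the filter is applied *before*
cluster assignment, since heavily missing genotypes are also the main cause
of ambiguous assignments.

# Cluster assignment

`fitNoAdmixture()` is a Gibbs sampler for the classic no-admixture,
independent-frequency clustering model: each individual carries a single
cluster label `z`; cluster allele frequencies have a symmetric
Dirichlet(λ) prior (λ = 1 by default, the common uninformative choice);
genotype likelihoods are Hardy–Weinberg within clusters (p² for a
homozygote, 2pq for a heterozygote); missing loci contribute likelihood 1.
Q-values are posterior label frequencies over post-burn-in sweeps.

Two practical details matter:

* **Label switching.** Cluster labels are non-identifiable. Each sweep's
  frequency vectors are greedily matched to the previous accepted
  orientation by minimal total-variation distance; chains are aligned to the
  first chain the same way before averaging. For K = 2 well-separated
  clusters this greedy scheme is exact in practice.
* **Convergence.** Chains are compared by the Pearson correlation of their
  Q matrices; a minimum below 0.99 sets a warning flag on the result rather
  than raising an error, so a pipeline run always completes and reports.

Defaults are desk-scale (2,000 burn-in, 10,000 sweeps, 5 chains) and resolve
a two-cluster mixture at divergence F ≈ 0.3 essentially perfectly; much
longer runs are a configuration away. Individuals with max Q exactly at the
threshold are AMBIGUOUS (the threshold is strictly-greater), and AMBIGUOUS
individuals are excluded from all downstream statistics but kept in the
habitat-by-species cross-tabulation.

# Null alleles

`estimateNullEM()` maximizes the observed-data likelihood of one
population-by-locus cell under HWE with one hidden null allele ν:
true classes occur with probabilities p~i~², 2p~i~p~j~, 2p~i~r, r²; true
(i,j) is seen as a heterozygote, (i,i) and (i,ν) both as apparent
homozygote i, (ν,ν) as a blank. The E-step splits each apparent-homozygote
count between (i,i) and (i,ν) as p~i~ : 2r; the M-step re-estimates
{p~i~, r} from expected allele-copy counts. Two blank modes are exposed:

* `blanks-as-nulls` (default): blank loci are counted as the (ν,ν) class —
  appropriate when repeated amplification failure is itself evidence of
  nulls, the argument made for these data;
* `blanks-excluded`: the likelihood is conditioned on a non-blank outcome
  (the E-step imputes the expected number of unseen (ν,ν) individuals).

Convergence is declared when the largest frequency change per iteration
falls below 1e-8 (cap 10,000 iterations). EM converges sublinearly when the
maximizer sits on the boundary r = 0, which can leave a residue of order
1e-5; a final boundary check snaps r to zero whenever the r = 0 profile
costs no observed-data likelihood. The observed-data log-likelihood trace is
retained so monotonicity is assertable in tests, and the suite also checks
the EM against a brute-force likelihood grid.

The Monte-Carlo HWE diagnostic pools the 2n allele copies of a cell,
re-pairs them at random, and counts homozygous pairs; the one-tailed
homozygote-excess p-value carries a +1 pseudo-count so it is never zero.
Because the statistic is a small integer count, the test is slightly
conservative (measured type-I rate ≈ 0.034 at nominal 0.05 for n = 50);
this is a property of any discrete Monte-Carlo test, not a coding artifact.
`diagnoseArtifact()` is deliberately a *simplified* stand-in for a full
scoring-artifact battery: it partitions the heterozygote deficit by
allele-size-difference quartiles and calls "dropout-like" only when more
than half the deficit sits in the largest size-difference quartile
(large-allele dropout removes size-distant heterozygotes preferentially),
"null-allele-like" otherwise.

# Differentiation statistics

Per locus, with p~k,a~ the frequency of allele a in population k, sample
sizes enter through the harmonic mean ñ:

* H~S~ = (ñ/(ñ−1)) · (1 − mean~k~ Σ~a~ p²~k,a~)
* H~T~ = 1 − Σ~a~ p̄²~a~ + H~S~/(kñ)

These are the standard small-sample corrections used by the classic gene
diversity software; over-loci averages are arithmetic. `heterozygosity()`
accepts either raw or null-corrected tables — the corrected table
renormalizes visible-allele frequencies after excluding the null class.
Note that for two samples drawn from literally identical frequencies the
corrections make H~T~ − H~S~ very slightly negative at finite n; the
implementation reports what the formulas give rather than clamping.

**Jost's D** per locus is [(H~T~−H~S~)/(1−H~S~)]·[k/(k−1)] on *raw*
frequencies (the cited D implementation has no null correction, and the
source analyses report D without a correction tag). The 95% CI bootstraps
the data 1,000 times; per locus, allele copies are resampled within
populations when every population passes the HWE screen at that locus, and
whole genotypes otherwise (preserving the genotypic disequilibrium that
made the cell fail HWE). Within-population resampling inflates
between-population differences slightly, so the raw bootstrap percentiles
sit high; the interval reported is the *recentred* percentile CI
(point estimate plus centred bootstrap quantiles), which keeps the point
estimate inside its own interval.

**F~ST~** is Weir–Cockerham θ: per-allele variance components a (among
populations), b (among individuals within), c (within individuals),
combined as Σa / Σ(a+b+c) over alleles and loci. The null-corrected (ENA)
variant rebuilds the components from EM-corrected visible frequencies with
HWE-expected heterozygosities — corrected *individual genotypes* do not
exist, so expectation under HWE is the only consistent choice; it is
documented as an approximation and its purpose is bias reduction, which the
suite verifies by simulation (corrected θ is closer to the generating F
than raw θ under 20% nulls). CIs bootstrap loci (percentile, seeded).

**G″~ST~** = k(H~T~−H~S~) / [(kH~T~−H~S~)(1−H~S~)] with k the number of
populations in the comparison — k = 4 globally, k = 2 for pairs, each pair
recomputing its own H values rather than reusing the global table (that is
what the printed equation's k means). **N~m~** = (1−G″~ST~)/(4F~ST~), using
the ENA F~ST~, with an ∞ sentinel when F~ST~ ≤ 0 (the island-model
transform is indefinite there).

# Distances and spatial tests

The chord distance per locus is d = (2/π)·√(2(1 − Σ~a~ √(p~a~q~a~))),
averaged over loci — the bounded form, maximum (2/π)√2 ≈ 0.9003 for
disjoint allele sets. With `ina = TRUE` each frequency vector is the
corrected visible vector augmented by its own null class, so the null
participates as one shared allelic state. Geographic distances are an
*input* whenever measured routes matter (shortest marine routes cannot be
recomputed from coordinates); `greatCircleMatrix()` (haversine, R =
6371.0088 km) is a documented fallback. The habitat gap enters as a binary
indicator matrix over a two-group partition of sites.

Mantel and partial Mantel tests correlate upper triangles; the null
permutes rows and columns of the *predictor* matrix, and one-sided p-values
use the +1 pseudo-count. The partial correlation is the usual first-order
formula r~xy.z~ = (r~xy~ − r~xz~r~yz~)/√((1−r~xz~²)(1−r~yz~²)), recomputed
per permutation. On 4 sites only 24 distinct permutations exist, so
p-values are coarse by nature; the suite checks the Monte-Carlo p against
exhaustive enumeration.

SAShA treats every allele copy as an instance at its carrier's site. OM is
the mean distance over all unordered same-allele instance pairs pooled
across alleles and loci (within-site pairs at distance 0); EM is the
all-pairs mean per locus, combined over loci with the same pooling weights
(each locus's same-allele pair count). The permutation null shuffles allele
identities within loci, keeping site slots fixed, and the two-sided p
compares |OM−EM| exceedances. Loci whose alleles are all singletons
contribute no pairs and are skipped with a warning.

# The synthetic generator

`simulateGenotypes()` draws ancestral allele frequencies from a symmetric
Dirichlet(1) per locus and population frequencies from the Balding–Nichols
Dirichlet with concentration (1−F)/F — chosen over coalescent simulation
because it parameterizes exactly the F the estimators target, which keeps
recovery tests sharp; no mutation model is needed since all the statistics
are allele-identity-based. Two species are two independent ancestral draws
around a common pool at divergence F~sp~. One shared null allele per locus
(frequency configurable per population and locus) plus an independent
amplification-failure rate generate the observation model: visible/null
pairs appear as homozygotes, null/null and failed amplifications as blanks.
Sites sit on a 1-D coastline mapped to a meridian, optionally with an
inserted habitat gap.

`paperLikeDataset()` is the study-shaped preset: 2 species × 4 shared
sites with per-site sample sizes 18/43/28/35 and 31/31/22/23, seven loci
with 7–41 visible alleles, per-population null frequencies 0.15–0.17,
within-species F = 0.008 (inside the 0.004–0.011 range the statistics
should recover), F~sp~ = 0.3, 10% amplification failure, and site positions
0, 63, 150, 372 km with the long 150→372 stretch playing the role of the
habitat discontinuity. Realized missingness lands near 11–13%, within the
14–23%-ish range real gels produced. What the generator does *not* emulate:
linkage between loci, stepwise mutation (size-neighbouring alleles are no
more similar than distant ones), within-site spatial structure, and
genotyping error other than nulls/failures — so passing tests demonstrate
estimator correctness under the model's assumptions, not robustness to
every real-data pathology.

# Numerical and design choices

* Seeds: every stochastic routine takes an explicit seed; compound routines
  derive per-stage sub-seeds deterministically, so pipeline reruns are
  bit-identical.
* Resampling canonicalization: genotypes within a population-by-locus cell
  (and SAShA instances) are put in a canonical order before any seeded
  resampling, so statistics are invariant to the order individuals appear
  in the file.
* Monomorphic cells: HWE p = 1 by convention; EM returns r = 0 when a cell
  has no homozygotes and no countable blanks (there is no information about
  nulls); G″~ST~ is 0 when H~T~ = 0.
* Degenerate spatial input: constant distance matrices are a hard error for
  Mantel r (zero variance), as is a control matrix perfectly correlated
  with the predictor in the partial test.
* Problem sizes in the test-suite simulations (tens of individuals per
  population, hundreds of bootstrap/permutation replicates, thousands of
  calibration cells) were chosen to give comfortable statistical resolution
  for each assertion while keeping the default suite quick on a laptop;
  the pipeline accepts the full-scale counts (30,000 Mantel permutations,
  200,000 MCMC sweeps, ...) through its configuration.

# Known limitations

* The ENA θ uses HWE-expected heterozygosities; real within-individual
  components from corrected genotypes are unobtainable by construction.
* The artifact diagnostic is a two-way heuristic, not a full published
  battery; verdicts on borderline cells should be read as hints.
* The no-admixture model cannot express hybrids: a true hybrid will show an
  intermediate Q and be discarded as AMBIGUOUS, which is the intended,
  conservative behaviour for species assignment but not a hybrid analysis.
* Mantel-type tests on 4 populations have only 24 permutations; p-values
  below 1/24 are unreachable and "significance" should be interpreted
  accordingly.
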