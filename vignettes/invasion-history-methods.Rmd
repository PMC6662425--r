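---
title: "Methods: inferring the invasion history of a selfing plant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring the invasion history of a selfing plant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfspread)
```

# The problem

`selfspread` reconstructs how a predominantly self-fertilizing invasive
plant spread across a landscape, from two kinds of evidence:

* a biallelic SNP genotype matrix for georeferenced individuals sampled
  across the invaded range (dosage-coded 0/1/2 with missing calls), and
* dated occurrence records (herbarium specimens and field observations).

The motivating system is an annual mustard that invaded the southwestern
United States over roughly a century, forming a handful of genetic
clusters, each presumed to descend from a separate introduction. Three
questions structure the pipeline: how inbred/selfing are the populations;
how is genetic variance organized in space; and where and in what order
did the introductions arrive.

# Models and statistics

## Diversity and the mating system

Per locus, the alternate-allele frequency is computed over non-missing
calls; observed heterozygosity Ho is the fraction of heterozygous calls
and expected heterozygosity is He = 2p(1 − p). The multilocus inbreeding
coefficient is the ratio-of-means estimator

> Fis = 1 − mean(Ho) / mean(He),

clamped to [−1, 1]. Monomorphic loci are included in both means by
default (they shrink both in parallel); a flag excludes them, and Nei's
n/(n − 1) correction to He is likewise optional and off by default. The
standard error attached to Ho and He is the across-locus standard
deviation divided by √L, matching how such tables are usually printed.
We deliberately use the simplest defensible estimator rather than
Weir–Cockerham; users comparing against other software should expect
small differences, and published cluster tables computed by per-site
aggregation may not reproduce the identity Fis = 1 − Ho/He on their
printed means.

Under inbreeding equilibrium with partial self-fertilization, the
selfing rate S and Fis are linked by S = 2Fis/(1 + Fis), equivalently
Fis\* = S/(2 − S); the outcrossing rate is T = 1 − S. These conversions
are exact algebra and are round-trip tested to 1e−12.

A private allele is an allele (reference or alternate) observed in
exactly one cluster's non-missing calls. Counting both alleles matters:
a locus fixed for the alternate everywhere except one cluster makes the
*reference* allele private.

## Hierarchical AMOVA

Genetic variance is partitioned among individuals within localities,
among localities within ecoregions, and among ecoregions, using the
standard sums-of-squares decomposition on pairwise squared Euclidean
distances between dosage vectors. Missing data are handled by
pairwise-complete loci with the squared distance rescaled by
L/L_complete — no imputation. Negative variance components are reported
as-is and flagged rather than truncated; the three Φ statistics
(Φ_ST overall, Φ_SC among localities within regions, Φ_CT among
regions) are attached to the within-localities, between-localities and
between-regions rows respectively. P-values come from label
permutations appropriate to each level (individuals across everything;
individuals among localities within their region; whole localities
among regions), with p = (#{Φ_perm ≥ Φ_obs} + 1)/(B + 1). Null
calibration is tested by a Kolmogorov–Smirnov check on p-values from
simulated unstructured data.

## Index of association

Multilocus linkage disequilibrium is summarized by the standardized
index of association r̄d. Per locus, the distance between two
individuals is |dosage_i − dosage_j|/2 over pairs where both are called;
with V_O the variance over pairs of the distance summed across loci and
V_E the sum of per-locus distance variances,

> r̄d = (V_O − V_E) / (2 Σ_{j<k} √(var_j var_k)).

Perfect repetition of one locus gives r̄d = 1 exactly; free
recombination under random mating gives values near 0; selfing inflates
it because whole genomes are co-inherited. The permutation test
shuffles each locus's calls independently among individuals (one-sided,
upper tail). Per-pair locus sums use pairwise-complete loci without
rescaling; pairs sharing no called locus are dropped with a warning.
A grouping argument computes the statistic within populations as well
as jointly, since "overall" disequilibrium conflates within-population
disequilibrium with population structure.

## Population structure

PCA operates on per-locus mean-imputed, centered dosages. The admixture
estimator is a least-squares matrix factorization: memberships Q
(rows on the probability simplex) and cluster allele frequencies F
(entries in [0, 1]) minimize the masked squared reconstruction error
between dosage/2 and QF, with missing calls excluded from the objective
rather than imputed. The Q-step solves each row's simplex-constrained
least-squares problem exactly by an active-set method; the F-step is
exact coordinate descent under box constraints; the objective is
therefore non-increasing, which the tests assert. Initialization is
k-means (k-means++ seeding) on PCA scores, deterministic given the
seed. This is an explicit, documented stand-in for spatial Bayesian
admixture machinery: the pipeline downstream needs memberships and a
cluster count, not posterior samples, so the Monte Carlo machinery (and
its spatial interaction prior) is intentionally not reimplemented.

The number of clusters is chosen by masked-entry cross-validation: a
fraction (default 5%) of the non-missing calls is hidden, the model is
fitted to the rest, and the mean squared prediction error on the hidden
calls is averaged over seeds; the chosen K is the smallest within one
standard error of the minimum.

### A known limitation of K selection under high selfing

On synthetic invasions with selfing rate 0.9 and serial founder
colonization, held-out prediction error keeps improving beyond the true
number of introductions, so cross-validated K selection settles on the
top of the candidate range rather than on 3. This is not an artifact:
selfing propagates whole multilocus genotypes, and serial founding
differentiates sites within a cluster, so "lines" and site groups are
genuine, predictable structure. Even fits initialized at the true
labels converge to solutions that split the largest cluster, with the
same objective value. On random-mating data the same procedure shows a
clean elbow and picks the correct K (and K = 1 for panmictic data), so
the limitation is a property of the data-generating biology, not of the
implementation. Practitioners analysing highly selfing species should
treat automatic K selection with suspicion and lean on PCA, the
stability of small divergent clusters, and biological context.

## Introduction-site inference

Rare variants are loci with 0 < MAF < 0.10 (strict: a locus at exactly
10% is not rare; monomorphic loci are not rare). A rare variant
"segregates at a site" if any of the site's non-missing calls carries
the globally rarer allele. The per-site *density* divides the count by
the number of loci assessed (≥1 non-missing call) at that site, so
sites with different missingness are comparable; raw counts are kept
alongside.

Spatial interpolation is ordinary kriging without a trend surface: an
exponential variogram γ(h) = nugget + psill(1 − e^{−h/range}) is fitted
to binned empirical semivariances by weighted least squares (weights
N_bin/γ²), and the kriging system is solved in semivariogram form with
a Lagrange multiplier enforcing that weights sum to one at every grid
node (asserted during the solve; with a zero nugget the surface
interpolates the data exactly). Distances are haversine great-circle
kilometres with an Earth radius of 6,371 km; the default grid spacing
is 0.05° over the padded bounding box of the sites. Distance-decay
summaries use locally weighted linear regression (loess, degree 1,
tricube weights, default span 0.75) of density on distance from a
putative origin, plus a Spearman rank correlation as a scale-free
monotonicity measure.

Introductions are ordered by *iterative peeling*. Each round flags rare
variants on the current matrix, computes site densities, and takes the
peak site among sites whose majority cluster has not yet been focal —
the newest introduction carries the densest rare variation, so rounds
run newest-first. Before the next round, loci whose globally minor
allele is private to the focal cluster are removed (the default
operationalization of "removing a cluster's rare variants"; an
alternative mode removes every rare locus segregating in the focal
cluster). Removal sets are disjoint across rounds and each round must
remove at least one locus, so the procedure terminates. The procedure
stops early, with a logged reason, if a round finds no rare variants or
no removable loci.

## Range expansion and the lag phase

Occurrence records are binned into cells of a hundredth of a degree
(about 1 km² at these latitudes) by rounding half away from zero — made
explicit, with a small numeric guard, because platform rounding of
halves differs and a coordinate like 33.815 is not exactly representable
in binary. Each cell keeps its earliest year. The accumulation curve
counts newly and cumulatively occupied cells per calendar year
(zero-new years included), and the lag test regresses log10(cumulative)
on year over years with positive occupancy (the log of zero is
undefined; the choice is documented rather than silent). Exponential
spread at a constant rate is exactly log-linear, so slope b estimates
the per-year log10 expansion rate and a high R² argues against a lag.
Because "no lag" is a judgment, the fit is reported as diagnostics —
b, R², F, df, p — together with a single-breakpoint comparison model
log10(cum) ~ max(0, year − τ) profiled over candidate years and
compared by AIC (the breakpoint model is charged one extra parameter
for τ); ΔAIC = AIC(linear) − AIC(breakpoint) > 2 favours a lag.

# The synthetic-data generator

Because the study's raw data are embargoed, every stage is exercised on
simulated data with known ground truth. The generator emulates the
study's scale and structure: 3 introductions, 52 sites, ~728
individuals (14 per site), 1,525 biallelic SNPs, selfing rate 0.9
(equilibrium Fis ≈ 0.82, within the 0.78–0.85 range typical of such
surveys), per-individual missingness including a ~2% subset with very
high missingness (emulating the handful of failed libraries that the
\>75% filter removes), and occurrence records spanning 1927–2016.

Reproduction is discrete-generation with no mutation: an offspring
arises by selfing with probability S, otherwise by random outcrossing;
gametes are drawn per locus from parental dosages. Founder frequencies
at shared loci are drawn by founder sampling (20 gene copies) around a
common native-pool frequency with a U-shaped Beta(0.5, 0.5) law, so
introductions are related but founder-effect differentiated, matching
the observation that invading clusters are not deeply diverged. Each
introduction also carries planted private rare alleles (40/150/300 for
oldest/middle/newest, echoing the strongly staggered private-allele
counts seen in such invasions) at founder frequencies 0.06–0.09, just
below the rare-variant threshold and high enough to survive drift and a
14-individual site sample at detectable rates.

Two design choices do the heavy lifting:

* **Age-staggered drift.** Origin populations burn in for 40/25/8
  generations (oldest first) at size 150. Selfing halves the effective
  size and makes drift genome-correlated (whole inbred lines live or
  die), so older introductions erode their rare variation much more
  than newer ones. This, together with the staggered planting, is what
  orders origin-site densities by recency.
* **Serial founder chains.** Sites are colonized along a spatial chain:
  each new site is founded by 8 colonists from the previous site and
  grows to 30 over 3 generations, with hop distances of 15–45 km. Rare
  alleles are lost at a high rate per hop, producing the steep,
  monotone decay of rare-variant density with distance from each origin
  that the peeling procedure and the distance-decay fits rely on.
  A `wave_size` parameter generalizes the chain to front-like expansion
  with shallower genetic depth.

What the generator does **not** emulate: linkage between loci (loci are
exchangeable given the pedigree; there are no chromosomes), mutation,
seed banks, ongoing gene flow between established sites, collection
effort bias in occurrence records, and genotyping error beyond
missingness. Passing tests on this generator therefore demonstrate that
the estimators recover the signals the generator encodes — inbreeding
equilibria, hierarchical variance, rare-variant geography, log-linear
spread — not that real surveys are free of the confounders above.

Occurrence records are generated by targeting the cumulative-cell curve
10^(b·t) after an optional flat lag, placing each new cell at a uniform
angle and a radius growing with the square root of the occupied-cell
count (so cell collisions stay rare), and resampling occupied cells for
additional records. At the historical scale (~2,900 records over
1927–2016) the feasible log10 rate is about 0.0375; steeper rates like
0.08 are exercised over shorter spans so the cell count stays within
the record count.

# Numerical choices and problem sizes

Tolerances: simplex rows of Q sum to 1 within 1e−9; kriging weight sums
are asserted within 1e−6 (achieved ~1e−15); AMOVA percent variances sum
to 100 within 1e−9; the S↔Fis round trip is tested at 1e−12. Ties in
`peak_site` break lexicographically by site name. Degenerate inputs
(all-identical genotypes, He = 0, fewer than two polymorphic loci,
single-locality designs, constant cumulative curves, duplicate kriging
coordinates) return flagged results or informative errors rather than
NaNs.

The test suite runs the heavier properties at deliberately chosen sizes:
equilibrium-Fis recovery at 500 × 1,000 over 20 seeds; the r̄d null at
200 × 1,000 with 99 permutations over 20 seeds; introduction-order
recovery on the full default generator over 20 seeds; AMOVA null
calibration at 12 × 15 over 200 simulated datasets with 49 permutations.
Smaller configurations of the same generator back the unit tests so the
whole suite stays inside a desktop-scale budget; the acceptance script
(`scripts/acceptance.R`) re-runs the study-scale computations once from
scratch.

# Known limitations

* The Fis estimator is a ratio of means without small-sample
  correction; cluster estimates from ~a dozen selfing individuals have
  substantial sampling variance because heterozygosity concentrates in
  the minority of recently outcrossed individuals.
* Cross-validated K selection overestimates the number of introductions
  under high selfing (see above); it is reported, not relied upon, and
  `iterative_peeling` accepts any cluster assignment, including one
  supplied from external knowledge.
* Kriging fits a single isotropic exponential variogram; anisotropy and
  alternative models are out of scope, though parameters can be
  supplied.
* The lag test inherits the biases of occurrence data; the package
  reports fit diagnostics and leaves the verdict to the analyst.
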