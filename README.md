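# selfspread

Invasion-history inference for highly selfing plants, from a biallelic
SNP genotype matrix with georeferenced samples and a table of dated
occurrence records.

Invasive annuals that mostly self-fertilize (the motivating system is a
desert mustard that colonized the southwestern United States within a
century) leave two complementary records of their spread: population
genomic structure, and dated herbarium/field occurrences. `selfspread`
implements the full analysis chain for both:

* **Filtering** — drop individuals with > 75% missing calls (strict
  inequality), keep loci genotyped in ≥ 10% of samples.
* **Diversity and mating system** — per-cluster observed/expected
  heterozygosity (Ho, He = 2p(1 − p)), the multilocus inbreeding
  coefficient Fis = 1 − mean(Ho)/mean(He), selfing rate
  S = 2Fis/(1 + Fis), outcrossing rate T = 1 − S, and private-allele
  counts.
* **Hierarchical AMOVA** — variance components and Φ statistics for
  individuals within localities within ecoregions, with permutation
  p-values.
* **Multilocus linkage disequilibrium** — the standardized index of
  association r̄d with a per-locus shuffling permutation test.
* **Population structure** — PCA of mean-imputed dosages and a
  least-squares admixture estimator (simplex-constrained memberships Q,
  box-constrained cluster frequencies F) with cross-validated selection
  of the number of clusters.
* **Introduction-site inference** — per-site rare-variant density
  (MAF < 10%), ordinary kriging without a trend surface, distance-decay
  local regression, and iterative peeling of cluster-private variation
  to order introductions newest-first.
* **Range expansion** — occurrence records binned into ~1 km² cells
  (hundredth-degree rounding), accumulation curves, and the lag-phase
  test: OLS of log10 cumulative occupied cells on year, with a
  single-breakpoint AIC comparison.
* **Synthetic data** — a forward simulator of partially selfing
  invasions (discrete generations, serial founder chains, planted
  private rare alleles, age-staggered drift) and of exponentially
  expanding occurrence records, with ground truth serialized beside the
  data.

## Worked example

```r
library(selfspread)

# simulate a three-introduction invasion at study scale
sim <- simulate_invasion(invasion_config(seed = 42))
g   <- filter_loci_by_presence(
         filter_individuals_by_missingness(sim$genotypes, 0.75), 0.10)
#> 15 individual(s) removed for >75% missing data: ...

# mating system per true cluster
diversity_summary(g, sim$truth$clusters[g$samples])
#>      group   n       Ho      He    Fis      S       T private
#> 1 cluster1 547 0.003961 0.04025 0.9016 0.9483 0.05175      64
#> 2 cluster2 139 0.006019 0.05932 0.8985 0.9466 0.05345      92
#> 3 cluster3  27 0.056302 0.16903 0.6669 0.8002 0.19982     287

# Fis ~ 0.8-0.9 is the inbreeding-equilibrium signature of ~90% selfing:
selfing_rate(0.80)   # 0.8889

# order the introductions by iterative rare-variant peeling
inf <- iterative_peeling(g, sim$metadata, sim$truth$clusters[g$samples])
inf$order
#>   round  cluster  site   lat    lon density
#> 1     1 cluster3 I3S01 35.03 -120.5  0.3777
#> 2     2 cluster2 I2S01 33.82 -116.5  0.2625
#> 3     3 cluster1 I1S01 34.03 -118.8  0.2478
sim$truth$origins$site   # "I3S01" "I2S01" "I1S01" — recovered, newest first

# range expansion without a lag phase
occ <- simulate_occurrences(rate_b = 0.0375, seed = 1)
lag_phase_regression(accumulation_curve(bin_records(occ)))
#> log-linear range expansion: b = 0.0376, R^2 = 0.999, F(1,88) = 92658.6,
#> p = 8.41e-135 (90 years)
#>   breakpoint comparison: tau = 1928, delta AIC = -2.78 (positive favours a lag)
```

The peeling table reads newest introduction first: the cluster with the
densest rare variation (here the 27-individual `cluster3`) marks the
most recent arrival, and each round strips that cluster's private minor
alleles before looking for the next origin. The low-looking Fis of that
tiny cluster (0.67 against a generating equilibrium of 0.82) is the
small-sample variance discussed in the vignette: in a 90% selfer,
heterozygosity is concentrated in the few recently outcrossed
individuals, so a ~27-individual estimate swings widely. A slope of
b ≈ 0.0375 on the log10 scale with R² ≈ 1 is the signature of constant
exponential spread — no detectable lag phase.

`run_pipeline(pipeline_config(...))` chains every stage (filters →
diversity → AMOVA → r̄d → PCA/admixture → introduction inference →
range expansion) and writes per-stage TSV/JSON plus a manifest with
seeds, thresholds and input checksums.

A methods vignette (`vignettes/invasion-history-methods.Rmd`) documents
the estimators, the simulator's assumptions, numerical choices, and
known limitations — including why cross-validated cluster-count
selection overestimates K for highly selfing organisms.

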