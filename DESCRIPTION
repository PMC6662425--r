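Package: selfspread
Title: Invasion-History Inference for Selfing Plants from SNP Genotypes
    and Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct the invasion history of highly selfing
    plant species from a biallelic SNP genotype matrix with georeferenced
    samples and a table of dated occurrence records. Implements matrix-level
    quality filters, per-cluster diversity summaries (observed and expected
    heterozygosity, inbreeding coefficients, selfing and outcrossing rates,
    private alleles), hierarchical analysis of molecular variance with
    permutation tests, the standardized index of association (multilocus
    linkage disequilibrium), principal component analysis and a
    least-squares admixture estimator with cross-validated selection of the
    number of clusters, introduction-site inference from rare-variant
    density (ordinary kriging without trend, distance-decay local
    regression, and iterative peeling of cluster-private variation), and
    range-expansion/lag-phase analysis of occurrence records. A forward
    simulator of partially selfing invasions with serial founder effects
    generates test data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
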