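# Shared fixtures built in code.

gm <- function(..., samples = NULL, loci = NULL) {
  x <- rbind(...)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(x)))
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(x)))
  genotype_matrix(x, samples, loci)
}

# Random genotype matrix with optional missingness.
random_gm <- function(n, L, seed, miss = 0) {
  set.seed(seed)
  x <- matrix(rbinom(n * L, 2, rep(runif(L, 0.05, 0.95), each = n)), n, L)
  if (miss > 0) x[matrix(runif(n * L) < miss, n, L)] <- NA_integer_
  genotype_matrix(x)
}

# Minimal VCF text fixture: 5 records, one triallelic, 3 samples.
write_fixture_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsamA\tsamB\tsamC",
    "chr1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tsnp2\tC\tT\t.\tPASS\t.\tGT\t0|0\t1|1\t./.",
    "chr1\t300\tsnp3\tG\tA,T\t.\tPASS\t.\tGT\t0/1\t0/2\t1/1",
    "chr1\t400\tsnp4\tT\tC\t.\tPASS\t.\tGT\t./1\t0/0\t0/1",
    "chr1\t500\tsnp5\tA\tC\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0"
  )
  writeLines(lines, path)
  path
}

fixture_metadata <- function(sites, lat, lon, eco, samples_per_site = 2) {
  n <- length(sites) * samples_per_site
  data.frame(
    sample = paste0("s", seq_len(n)),
    site = rep(sites, each = samples_per_site),
    lat = rep(lat, each = samples_per_site),
    lon = rep(lon, each = samples_per_site),
    ecoregion = rep(eco, each = samples_per_site)
  )
}

# Multilocus Fis estimate from a genotype matrix.
fis_estimate <- function(g, samples = NULL) {
  freqs <- allele_frequencies(g, samples)
  ho <- observed_heterozygosity(g, samples)
  he <- expected_heterozygosity(freqs)
  suppressWarnings(inbreeding_coefficient(ho$mean, he$mean))
}
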