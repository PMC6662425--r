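test_that("selfing simulation reaches the partial-selfing equilibrium Fis", {
  pop <- simulate_selfing_population(runif(400, 0.1, 0.9), S = 0.9,
                                     g = 25, n = 400, seed = 8)
  fis <- fis_estimate(genotype_matrix(pop))
  expect_lt(abs(fis - 0.9 / 1.1), 0.05)
  # complete selfing drives heterozygosity to ~0
  pop1 <- simulate_selfing_population(runif(200, 0.2, 0.8), S = 1,
                                      g = 50, n = 100, seed = 9)
  expect_lt(mean(pop1 == 1L), 0.01)
  expect_error(simulate_selfing_population(0.5, S = 0.5, g = 1, n = 1),
               "n >= 2")
})

test_that("estimated Fis increases monotonically with the selfing rate", {
  grid <- c(0, 0.25, 0.5, 0.75, 0.95)
  res <- expand.grid(S = grid, seed = 1:10)
  res$fis <- mapply(function(S, seed) {
    pop <- simulate_selfing_population(runif(200, 0.1, 0.9), S = S,
                                       g = 15, n = 150, seed = seed)
    fis_estimate(genotype_matrix(pop))
  }, res$S, res$seed)
  rho <- cor(res$S, res$fis, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("identical seed and config give bit-identical datasets", {
  cfg <- invasion_config(seed = 5, L = 120, sites_per_introduction = c(4, 2, 1),
                         samples_per_site = 5, generations = c(8, 5, 3),
                         n_private = c(5, 10, 20))
  s1 <- simulate_invasion(cfg)
  s2 <- simulate_invasion(cfg)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$truth$origins, s2$truth$origins)
})

test_that("invasion datasets carry coherent structure and ground truth", {
  cfg <- invasion_config(seed = 6, L = 300,
                         sites_per_introduction = c(6, 3, 1),
                         samples_per_site = 8,
                         generations = c(12, 8, 4),
                         n_private = c(10, 30, 60))
  sim <- simulate_invasion(cfg)
  g <- sim$genotypes
  expect_equal(n_samples(g), 10 * 8)
  expect_equal(n_loci(g), 300)
  expect_setequal(names(sim$truth$clusters), g$samples)
  expect_equal(nrow(sim$metadata), n_samples(g))
  # origins are newest first and name real sites
  expect_equal(sim$truth$origins$year, sort(cfg$origins$year, decreasing = TRUE))
  expect_true(all(sim$truth$origins$site %in% sim$metadata$site))
  # each locality lies in exactly one ecoregion
  map <- unique(sim$metadata[, c("site", "ecoregion")])
  expect_equal(anyDuplicated(map$site), 0)
})

test_that("rare-variant density decays with hop count from the origin", {
  hits <- 0L
  for (seed in 1:10) {
    cfg <- invasion_config(seed = seed, L = 400,
                           sites_per_introduction = c(10, 1, 1),
                           samples_per_site = 8,
                           generations = c(10, 6, 3),
                           n_private = c(60, 30, 40))
    sim <- simulate_invasion(cfg)
    g <- sim$genotypes
    cl <- sim$truth$clusters[g$samples]
    g1 <- g[cl == "cluster1", ]
    dens <- site_rare_variant_density(g1, sim$metadata)
    hops <- sim$truth$site_hops[dens$site]
    rho <- suppressWarnings(cor(hops, dens$density, method = "spearman"))
    if (!is.na(rho) && rho < 0) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("written datasets round-trip through the package readers", {
  cfg <- invasion_config(seed = 7, L = 80, sites_per_introduction = c(3, 2, 1),
                         samples_per_site = 4, generations = c(6, 4, 2),
                         n_private = c(4, 8, 15))
  sim <- simulate_invasion(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulated_dataset(sim, dir)
  g2 <- read_genotypes(paths[["genotypes"]], "matrix012")
  expect_equal(g2$calls, sim$genotypes$calls)
  md2 <- read_metadata(paths[["metadata"]])
  expect_equal(md2$sample, sim$metadata$sample)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$origins$site, sim$truth$origins$site)
})

test_that("occurrence simulation respects record counts and lag structure", {
  occ <- simulate_occurrences(rate_b = 0.03, n_records = 500, seed = 3)
  expect_gte(nrow(occ), 500)
  expect_true(all(occ$year >= 1927 & occ$year <= 2016))
  one <- simulate_occurrences(rate_b = 0.03, n_records = 1, start_year = 1950,
                              end_year = 1955, seed = 4)
  curve <- accumulation_curve(bin_records(one))
  expect_equal(max(curve$cumulative), nrow(bin_records(one)))
  expect_error(simulate_occurrences(rate_b = 0.03, n_records = 0), "n_records")
  lagged <- simulate_occurrences(rate_b = 0.03, lag_years = 30, seed = 5)
  curve_l <- accumulation_curve(bin_records(lagged))
  expect_lte(max(curve_l$cumulative[curve_l$year <= 1956]), 2)
})
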