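test_that("site rare-variant density counts minor-allele carriers by hand", {
  # 2 sites x 2 samples, 10 loci; loci 1-3 rare, site A carries minor
  # alleles at all three, site B at none.
  x <- matrix(0L, 20, 10)
  x[1, 1] <- 1L; x[2, 2] <- 1L; x[1, 3] <- 1L   # site A carriers (rows 1-2)
  x[, 4] <- 1L                                   # common locus
  g <- genotype_matrix(x)
  md <- data.frame(sample = g$samples,
                   site = rep(c("A", "B"), c(2, 18)),
                   lat = rep(c(34, 35), c(2, 18)),
                   lon = rep(c(-118, -117), c(2, 18)),
                   ecoregion = "x")
  dens <- site_rare_variant_density(g, md)
  a <- dens[dens$site == "A", ]
  b <- dens[dens$site == "B", ]
  expect_equal(a$n_rare, 3)
  expect_equal(a$loci_assessed, 10)
  expect_equal(a$density, 0.3)
  expect_equal(b$n_rare, 0)
  expect_equal(b$density, 0)
})

test_that("single-site density equals the global segregating-rare fraction", {
  g <- random_gm(10, 30, seed = 19, miss = 0.1)
  md <- data.frame(sample = g$samples, site = "only", lat = 34, lon = -118,
                   ecoregion = "x")
  dens <- site_rare_variant_density(g, md)
  freqs <- allele_frequencies(g)
  rare <- flag_rare_variants(freqs)
  expect_equal(dens$n_rare, sum(rare))
  expect_equal(dens$density, sum(rare) / n_loci(g))
})

test_that("kriging preserves constant fields and interpolates exactly", {
  sites <- data.frame(lat = c(34, 34.6, 33.8, 34.2),
                      lon = c(-118, -117.4, -117, -117.8),
                      density = rep(0.42, 4))
  vg <- list(model = "exponential", nugget = 0, psill = 1, range = 80)
  ks <- ordinary_kriging(sites, grid_spacing = 0.2, variogram = vg)
  expect_lt(max(abs(ks$grid$prediction - 0.42)), 1e-8)
  expect_lt(ks$max_weight_sum_error, 1e-8)
  # exact interpolation at an observed site with zero nugget
  sites$density <- c(0.1, 0.5, 0.3, 0.2)
  ks2 <- ordinary_kriging(sites, grid_spacing = 0.2, pad = 0, variogram = vg)
  at_site <- which(abs(ks2$grid$lat - 34.2) < 1e-9 &
                     abs(ks2$grid$lon - (-117.8)) < 1e-9)
  expect_gt(length(at_site), 0)
  expect_equal(ks2$grid$prediction[at_site], 0.2, tolerance = 1e-8)
})

test_that("3-site kriging matches an independent naive solve to 1e-8", {
  sites <- data.frame(lat = c(34.0, 34.5, 33.9),
                      lon = c(-118.0, -117.5, -117.2),
                      density = c(0.30, 0.10, 0.20))
  vg <- list(model = "exponential", nugget = 0, psill = 1, range = 100)
  ks <- ordinary_kriging(sites, grid_spacing = 0.25, pad = 0.25, variogram = vg)
  gamma_fn <- function(h) vg$nugget + vg$psill * (1 - exp(-h / vg$range))
  naive <- vapply(seq_len(nrow(ks$grid)), function(i) {
    G <- matrix(0, 3, 3)
    for (a in 1:3) for (b in 1:3) if (a != b) {
      G[a, b] <- gamma_fn(haversine_km(sites$lat[a], sites$lon[a],
                                       sites$lat[b], sites$lon[b]))
    }
    A <- rbind(cbind(G, 1), c(1, 1, 1, 0))
    rhs <- c(gamma_fn(haversine_km(sites$lat, sites$lon,
                                   ks$grid$lat[i], ks$grid$lon[i])), 1)
    w <- solve(A, rhs)[1:3]
    sum(w * sites$density)
  }, 0)
  expect_equal(ks$grid$prediction, naive, tolerance = 1e-8)
})

test_that("kriging rejects duplicates unless told to jitter", {
  sites <- data.frame(lat = c(34, 34, 33.8), lon = c(-118, -118, -117),
                      density = c(0.1, 0.2, 0.3))
  vg <- list(model = "exponential", nugget = 0, psill = 1, range = 50)
  expect_error(ordinary_kriging(sites, variogram = vg), "singular|duplicate")
  set.seed(1)
  expect_s3_class(
    ordinary_kriging(sites, grid_spacing = 0.5, variogram = vg,
                     on_duplicates = "jitter"),
    "kriging_surface")
})

test_that("peak site takes the argmax with lexicographic tie-break", {
  d <- data.frame(site = c("A", "B", "C"), lat = 1:3, lon = 1:3,
                  density = c(0.1, 0.3, 0.2))
  expect_equal(peak_site(d)$site, "B")
  d2 <- data.frame(site = c("B", "A"), lat = 1:2, lon = 1:2,
                   density = c(0.3, 0.3))
  expect_equal(peak_site(d2)$site, "A")
})

test_that("distance decay reproduces a linear trend and flat fields", {
  set.seed(3)
  lat <- 34 + runif(12, 0, 2)
  lon <- -118 + runif(12, 0, 2)
  d_km <- haversine_km(34, -118, lat, lon)
  dens <- 0.5 - 0.001 * d_km
  tab <- data.frame(site = paste0("s", 1:12), lat = lat, lon = lon,
                    density = dens)
  fit <- distance_decay(tab, c(34, -118))
  ols <- lm(dens ~ d_km)
  expect_equal(fit$table$fitted, unname(fitted(ols)), tolerance = 1e-6)
  expect_equal(fit$spearman_rho, -1)
  tab$density <- 0.25
  flat <- distance_decay(tab, c(34, -118))
  expect_lt(max(abs(flat$table$fitted - 0.25)), 1e-9)
  expect_true(is.na(flat$spearman_rho) || flat$spearman_rho == 0)
  expect_error(distance_decay(tab[1:3, ], c(34, -118)), "at least 5")
  same <- tab; same$lat <- 34; same$lon <- -118
  expect_error(distance_decay(same, c(34, -118)), "identical distance")
})

test_that("iterative peeling on a hand-built 2-cluster fixture", {
  # 8 samples (4 per cluster, 2 sites per cluster), 12 loci.
  # Loci 1-3: minor allele private to cluster B (rare, carried at site B1).
  # Loci 4-5: minor allele private to cluster A (rare, carried at A1).
  # Loci 6-12: common, shared.
  x <- matrix(1L, 8, 12)
  x[, 1:5] <- 0L
  x[5, 1] <- 1L; x[5, 2] <- 1L; x[6, 3] <- 1L   # B1 carries loci 1-3
  x[1, 4] <- 1L; x[2, 5] <- 1L                  # A1 carries loci 4-5
  g <- genotype_matrix(x)
  md <- data.frame(sample = g$samples,
                   site = c("A1", "A1", "A2", "A2", "B1", "B1", "B2", "B2"),
                   lat = c(34, 34, 34.5, 34.5, 36, 36, 36.5, 36.5),
                   lon = rep(-118, 8), ecoregion = "x")
  cl <- rep(c("A", "B"), each = 4)
  inf <- iterative_peeling(g, md, cl, compute_decay = FALSE)
  # oracle: densities -> B1 = 3/12, A1 = 2/12, others 0 -> round 1 peaks at
  # B1 (cluster B), removes loci 1-3 (minor private to B); round 2 peaks at A1.
  expect_equal(length(inf$rounds), 2)
  expect_equal(inf$order$site, c("B1", "A1"))
  expect_equal(inf$order$cluster, c("B", "A"))
  expect_equal(sort(inf$rounds[[1]]$loci_removed),
               c("locus1", "locus2", "locus3"))
  expect_equal(inf$order$density[1], 3 / 12)
  # loci removed across rounds are disjoint
  expect_equal(anyDuplicated(unlist(lapply(inf$rounds, `[[`, "loci_removed"))), 0)
})

test_that("single-cluster dataset gives exactly one round", {
  g <- random_gm(8, 20, seed = 29)
  md <- data.frame(sample = g$samples,
                   site = rep(c("S1", "S2"), each = 4),
                   lat = rep(c(34, 35), each = 4), lon = rep(-118, 8),
                   ecoregion = "x")
  inf <- iterative_peeling(g, md, rep("only", 8), compute_decay = FALSE)
  expect_equal(length(inf$rounds), 1)
  dens <- site_rare_variant_density(g, md)
  expect_equal(inf$order$site, peak_site(dens)$site)
})

test_that("density table is invariant to sample order", {
  g <- random_gm(12, 25, seed = 37, miss = 0.1)
  md <- data.frame(sample = g$samples,
                   site = rep(c("S1", "S2", "S3"), each = 4),
                   lat = rep(c(34, 35, 36), each = 4), lon = rep(-118, 12),
                   ecoregion = "x")
  d1 <- site_rare_variant_density(g, md)
  set.seed(2)
  ord <- sample(12)
  d2 <- site_rare_variant_density(g[ord, ], md)
  expect_equal(d2, d1)
})
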