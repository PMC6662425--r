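test_that("allele frequencies count alleles over non-missing calls", {
  g <- gm(c(0L, 2L), c(0L, 2L), c(1L, NA), c(2L, 0L))
  fr <- allele_frequencies(g)
  expect_equal(fr$p[1], 3 / 8)        # calls 0,0,1,2 -> 3 alt of 8
  expect_equal(fr$maf[1], 0.375)
  expect_equal(fr$n_called[2], 3)
  g0 <- gm(c(0L), c(0L), c(0L))
  expect_equal(allele_frequencies(g0)$p, 0)
  g2 <- gm(c(2L), c(2L))
  fr2 <- allele_frequencies(g2)
  expect_equal(fr2$p, 1)
  expect_equal(fr2$maf, 0)
  expect_error(allele_frequencies(g, integer(0)), "empty")
})

test_that("rare-variant flag is strict on both sides", {
  fr <- data.frame(locus = c("a", "b", "c", "d"),
                   p = c(0.05, 0.10, 0, 0.95),
                   maf = c(0.05, 0.10, 0, 0.05),
                   n_called = 10)
  expect_equal(flag_rare_variants(fr, 0.10), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("observed and expected heterozygosity match closed forms", {
  g <- gm(c(0L, 1L), c(1L, 1L), c(2L, 1L))
  ho <- observed_heterozygosity(g)
  expect_equal(unname(ho$per_locus), c(1 / 3, 1))
  expect_equal(ho$mean, mean(c(1 / 3, 1)))
  # two-locus fixture with Ho 0.2 and 0.4 -> mean 0.3
  x <- cbind(c(1L, rep(0L, 4)), c(1L, 1L, 0L, 0L, 0L))
  expect_equal(observed_heterozygosity(genotype_matrix(x))$mean, 0.3)
  fr <- data.frame(locus = c("a", "b", "c"), p = c(0.5, 0.1, 0),
                   maf = c(0.5, 0.1, 0), n_called = 10)
  he <- expected_heterozygosity(fr)
  expect_equal(unname(he$per_locus), c(0.5, 0.18, 0))
  # all loci at p = 0.5 give mean He exactly 0.5
  fr5 <- data.frame(locus = letters[1:4], p = 0.5, maf = 0.5, n_called = 8)
  expect_identical(expected_heterozygosity(fr5)$mean, 0.5)
})

test_that("Fis follows 1 - Ho/He with clamping and undefined cases", {
  expect_equal(inbreeding_coefficient(0.1, 0.2), 0.5)
  expect_equal(inbreeding_coefficient(0.3, 0.3), 0)
  expect_equal(round(inbreeding_coefficient(0.0577, 0.0697), 3), 0.172)
  expect_warning(f <- inbreeding_coefficient(0.5, 0.1), "clamped")
  expect_equal(f, -1)
  expect_warning(u <- inbreeding_coefficient(0.1, 0), "undefined")
  expect_true(is.na(u))
})

test_that("selfing/outcrossing conversion matches published cluster values", {
  expect_equal(round(selfing_rate(0.8425), 4), 0.9145)
  expect_equal(round(outcrossing_rate(0.8425), 4), 0.0855)
  expect_equal(round(selfing_rate(0.7865), 4), 0.8805)
  expect_equal(round(outcrossing_rate(0.7865), 4), 0.1195)
  expect_equal(selfing_rate(0), 0)
  expect_equal(outcrossing_rate(0), 1)
  expect_warning(s <- selfing_rate(-0.5), "negative")
  expect_true(s < 0)
  expect_error(selfing_rate(-1), "Fis <= -1")
})

test_that("Fis = S/(2-S) inverts the selfing conversion to 1e-12", {
  s_grid <- seq(0, 0.99, by = 0.01)
  expect_equal(selfing_rate(fis_at_equilibrium(s_grid)), s_grid,
               tolerance = 1e-12)
})

test_that("private alleles match a brute-force double loop on random fixtures", {
  brute <- function(g, clusters) {
    labs <- sort(unique(clusters))
    counts <- setNames(integer(length(labs)), labs)
    for (j in seq_len(n_loci(g))) {
      for (allele in c("ref", "alt")) {
        seen <- character(0)
        for (lab in labs) {
          x <- g$calls[clusters == lab, j]
          x <- x[!is.na(x)]
          obs <- if (allele == "alt") any(x > 0) else any(x < 2)
          if (obs) seen <- c(seen, lab)
        }
        if (length(seen) == 1) counts[seen] <- counts[seen] + 1L
      }
    }
    counts
  }
  for (seed in 1:5) {
    g <- random_gm(8, 10, seed = seed, miss = 0.2)
    set.seed(seed + 100)
    cl <- sample(c("A", "B"), 8, replace = TRUE)
    if (length(unique(cl)) < 2) next
    expect_equal(private_alleles(g, cl), brute(g, cl))
  }
})

test_that("private alleles: directed examples", {
  # alt allele only in cluster A at locus 1; shared at locus 2
  g <- gm(c(1L, 1L), c(0L, 1L), c(0L, 1L), c(0L, 1L))
  cl <- c("A", "A", "B", "B")
  expect_equal(private_alleles(g, cl), c(A = 1L, B = 0L))
  # single cluster: every observed allele is private
  g1 <- gm(c(0L, 1L), c(1L, 1L))
  expect_equal(unname(private_alleles(g1, c("A", "A"))), 4L)
  expect_error(private_alleles(g, setNames(c("A", "B"), c("s1", "s2"))),
               "unassigned")
})

test_that("diversity summary assembles the cluster table consistently", {
  g <- random_gm(30, 60, seed = 11)
  cl <- rep(c("g1", "g2"), each = 15)
  ds <- suppressWarnings(diversity_summary(g, cl))
  expect_equal(ds$group, c("g1", "g2"))
  expect_equal(ds$n, c(15L, 15L))
  expect_equal(ds$S, 2 * ds$Fis / (1 + ds$Fis))
  expect_equal(ds$T, 1 - ds$S)
  expect_equal(ds$private, unname(private_alleles(g, cl)))
  expect_equal(ds$Fis[1], fis_estimate(g, which(cl == "g1")))
})

test_that("random-mating simulations estimate Fis near zero", {
  hits <- 0L
  for (seed in 1:20) {
    pop <- simulate_selfing_population(runif(300, 0.1, 0.9), S = 0,
                                       g = 8, n = 250, seed = seed)
    if (abs(fis_estimate(genotype_matrix(pop))) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19)
})
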