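#' Forward simulation of a partially selfing diploid population
#'
#' Discrete non-overlapping generations, no mutation. Founders are drawn
#' in Hardy-Weinberg proportions from `founder_freqs`; each generation,
#' an offspring arises by selfing a random parent with probability `S`
#' (two independent gametes from the same parent) or by random
#' outcrossing with probability `1 - S`. Under constant partial selfing
#' the inbreeding coefficient approaches the equilibrium
#' `Fis* = S / (2 - S)` geometrically (rate S/2 per generation), so
#' 15-30 generations suffice for equilibrium at any S.
#'
#' @param founder_freqs Per-locus alternate-allele frequencies of the
#'   founding gene pool.
#' @param S Selfing rate in [0, 1].
#' @param g Number of generations.
#' @param n Population size (constant); must be >= 2 when `S < 1`.
#' @param seed Optional integer seed.
#' @param founders Optional explicit founder dosage matrix (rows =
#'   individuals); overrides `founder_freqs`/`n` for the initial
#'   generation but the population size stays `n`.
#' @return Integer dosage matrix (`n` x `length(founder_freqs)`).
#' @export
simulate_selfing_population <- function(founder_freqs, S, g, n, seed = NULL,
                                        founders = NULL) {
  stopifnot(S >= 0, S <= 1, g >= 0, n >= 1)
  if (n < 2 && S < 1) stop("a population of 1 cannot outcross; need n >= 2 when S < 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(founders)) {
    L <- length(founder_freqs)
    pop <- matrix(stats::rbinom(n * L, 2, rep(founder_freqs, each = n)), n, L)
  } else {
    pop <- founders
    L <- ncol(pop)
  }
  storage.mode(pop) <- "integer"
  for (gen in seq_len(g)) {
    pop <- reproduce_generation(pop, S, n)
  }
  pop
}

# One generation of mixed selfing/outcrossing reproduction producing
# n_off offspring from `pop`. Fully vectorized: a gamete from a parent
# carries the alternate allele with probability dosage/2.
reproduce_generation <- function(pop, S, n_off) {
  n <- nrow(pop)
  L <- ncol(pop)
  p1 <- sample.int(n, n_off, replace = TRUE)
  selfed <- stats::runif(n_off) < S
  p2 <- ifelse(selfed, p1, sample.int(n, n_off, replace = TRUE))
  gamete <- function(par_idx) {
    P <- pop[par_idx, , drop = FALSE]
    (P == 2L) + (P == 1L) * (matrix(stats::runif(n_off * L), n_off, L) < 0.5)
  }
  off <- gamete(p1) + gamete(p2)
  storage.mode(off) <- "integer"
  off
}

#' Configuration for an invasion simulation
#'
#' Defaults emulate the data structure of a three-introduction invasion
#' of a highly selfing annual surveyed at 52 sites (~14 individuals per
#' site, ~728 total) genotyped at 1,525 biallelic SNPs: three genetic
#' clusters with selfing rate 0.9 (equilibrium Fis ~ 0.82, matching the
#' 0.78-0.85 range typical of such surveys), rare-variant density
#' decaying away from each introduction point through serial founder
#' effects, and staggered founder diversity (the newest introduction
#' carries the most private low-frequency alleles, the oldest the
#' fewest). A small fraction of individuals (~2%) is given very high
#' missingness, emulating library failures that the >75% missingness
#' filter removes.
#'
#' @param seed Integer seed.
#' @param K Number of introductions.
#' @param L Number of biallelic loci.
#' @param origins `data.frame` with `lat`, `lon`, `year` per introduction
#'   (oldest first).
#' @param sites_per_introduction Sites per introduction (oldest first).
#' @param samples_per_site Individuals sampled per site.
#' @param S Selfing rate.
#' @param generations Burn-in generations at the origin, per introduction
#'   (oldest first) or a scalar recycled to all. The default scales drift
#'   time with introduction age: older introductions have had many more
#'   generations to erode their rare variation, which is what orders the
#'   rare-variant densities of their origin sites.
#' @param founder_beta Beta(a, b) parameters for the native-pool allele
#'   frequencies shared by all introductions.
#' @param founder_gene_copies Effective number of gene copies sampled
#'   from the native pool by each introduction: its founder frequency at
#'   a shared locus is drawn from `Beta(m q, m (1 - q))` around the pool
#'   frequency `q` with `m = founder_gene_copies`, so introductions are
#'   correlated but founder-effect differentiated.
#' @param n_private Private rare alleles planted per introduction
#'   (oldest first; staggered, newest largest).
#' @param private_freq_range Founder frequency range for planted private
#'   alleles (below the 0.10 rare-variant threshold).
#' @param origin_pop_size Origin population size during burn-in.
#' @param site_pop_size Population size at each established site.
#' @param n_founders_per_hop Colonists founding each new site.
#' @param settle_generations Generations of growth after each founding.
#' @param wave_size Sites per colonization wave; each new site is founded
#'   from a random site of the previous wave. The default of 1 gives a
#'   serial chain (every hop is a founder bottleneck, so rare-variant
#'   density decays steeply and monotonically away from the origin);
#'   larger values give a front-like expansion with shallower genetic
#'   hop depth.
#' @param hop_km_range Distance range of each colonization hop (km).
#' @param high_missing_fraction Fraction of individuals with high
#'   missingness.
#' @param high_missing_rate Per-call dropout for those individuals.
#' @param dropout_rate Baseline per-call dropout for everyone else.
#' @return A list of class `invasion_config`.
#' @export
invasion_config <- function(seed = 1L,
                            K = 3,
                            L = 1525,
                            origins = data.frame(
                              lat = c(34.03, 33.82, 35.03),
                              lon = c(-118.78, -116.55, -120.48),
                              year = c(1927, 1965, 2005)),
                            sites_per_introduction = c(40, 10, 2),
                            samples_per_site = 14,
                            S = 0.9,
                            generations = c(40, 25, 8),
                            founder_beta = c(0.5, 0.5),
                            founder_gene_copies = 20,
                            n_private = c(40, 150, 300),
                            private_freq_range = c(0.06, 0.09),
                            origin_pop_size = 150,
                            site_pop_size = 30,
                            n_founders_per_hop = 8,
                            settle_generations = 3,
                            wave_size = 1,
                            hop_km_range = c(15, 45),
                            high_missing_fraction = 16 / 760,
                            high_missing_rate = 0.85,
                            dropout_rate = 0.10) {
  cfg <- list(seed = seed, K = K, L = L, origins = origins,
              sites_per_introduction = sites_per_introduction,
              samples_per_site = samples_per_site, S = S,
              generations = generations, founder_beta = founder_beta,
              founder_gene_copies = founder_gene_copies,
              n_private = n_private, private_freq_range = private_freq_range,
              origin_pop_size = origin_pop_size,
              site_pop_size = site_pop_size,
              n_founders_per_hop = n_founders_per_hop,
              settle_generations = settle_generations,
              wave_size = wave_size,
              hop_km_range = hop_km_range,
              high_missing_fraction = high_missing_fraction,
              high_missing_rate = high_missing_rate,
              dropout_rate = dropout_rate)
  cfg$generations <- rep(cfg$generations, length.out = cfg$K)
  stopifnot(cfg$K >= 1, cfg$L >= 1,
            nrow(cfg$origins) == cfg$K,
            length(cfg$sites_per_introduction) == cfg$K,
            length(cfg$n_private) == cfg$K,
            cfg$S >= 0, cfg$S <= 1,
            all(cfg$sites_per_introduction >= 1))
  class(cfg) <- "invasion_config"
  cfg
}

#' Simulate a multi-introduction invasion with ground truth
#'
#' Per introduction: founder allele frequencies are drawn (shared loci by
#' founder sampling around a common native-pool frequency; the
#' introduction's reserved private loci from `private_freq_range`, zero
#' elsewhere), the origin population evolves
#' under partial selfing, and sites are colonized outward along a
#' spatial chain with a bounded number of founders per hop (serial
#' founder effect), so rare-variant density decays with hop count and
#' hence distance from the origin. Introductions are merged, per-call
#' dropout and a high-missingness subset of individuals are injected,
#' and the ground truth is returned alongside the data.
#'
#' @param config An [invasion_config()].
#' @return List of class `simulated_invasion`: `genotypes`
#'   ([genotype_matrix]), `metadata` (sample metadata `data.frame`),
#'   `truth` (list: `clusters` named by sample, `origins` `data.frame`
#'   newest-first with `cluster`, `site`, `lat`, `lon`,
#'   `n_private_planted`, `site_hops` named hop counts, `fis` realized
#'   per cluster, `config`).
#' @export
simulate_invasion <- function(config = invasion_config()) {
  cfg <- config
  set.seed(cfg$seed)
  K <- cfg$K
  L <- cfg$L
  n_priv_total <- sum(cfg$n_private)
  if (n_priv_total >= L) stop("more private loci requested than loci available")
  priv_idx <- split(seq_len(n_priv_total),
                    rep(seq_len(K), times = cfg$n_private))
  shared_idx <- (n_priv_total + 1):L

  pool <- stats::rbeta(length(shared_idx),
                       cfg$founder_beta[1], cfg$founder_beta[2])
  m <- cfg$founder_gene_copies
  geno <- list(); meta <- list(); hops <- list()
  for (k in seq_len(K)) {
    f <- numeric(L)
    f[shared_idx] <- stats::rbeta(length(shared_idx), m * pool,
                                  m * (1 - pool))
    if (cfg$n_private[k] > 0) {
      f[priv_idx[[k]]] <- stats::runif(cfg$n_private[k],
                                       cfg$private_freq_range[1],
                                       cfg$private_freq_range[2])
    }
    res <- simulate_one_introduction(cfg, k, f)
    geno[[k]] <- res$calls
    meta[[k]] <- res$meta
    hops[[k]] <- res$hops
  }
  calls <- do.call(rbind, geno)
  md <- do.call(rbind, meta)
  rownames(md) <- NULL
  samples <- sprintf("ind%04d", seq_len(nrow(calls)))
  md$sample <- samples
  rownames(calls) <- samples
  colnames(calls) <- sprintf("snp%04d", seq_len(L))

  # missingness: a small high-missingness subset plus baseline dropout
  n <- nrow(calls)
  n_high <- round(cfg$high_missing_fraction * n)
  high <- sample.int(n, n_high)
  drop_rate <- rep(cfg$dropout_rate, n)
  drop_rate[high] <- cfg$high_missing_rate
  miss <- matrix(stats::runif(n * L), n, L) < drop_rate
  calls[miss] <- NA_integer_

  g <- genotype_matrix(calls)
  clusters <- stats::setNames(md$cluster, samples)
  fis <- vapply(sort(unique(clusters)), function(cl) {
    idx <- which(clusters == cl)
    freqs <- allele_frequencies(g, idx)
    ho <- observed_heterozygosity(g, idx)
    he <- expected_heterozygosity(freqs)
    suppressWarnings(inbreeding_coefficient(ho$mean, he$mean))
  }, numeric(1))

  origins <- data.frame(
    cluster = paste0("cluster", seq_len(K)),
    site = vapply(seq_len(K), function(k) site_name(k, 1), character(1)),
    lat = cfg$origins$lat, lon = cfg$origins$lon,
    year = cfg$origins$year,
    n_private_planted = cfg$n_private
  )
  origins <- origins[order(-origins$year), ]  # newest first
  rownames(origins) <- NULL

  md$cluster <- NULL
  structure(list(genotypes = g,
                 metadata = md[, c("sample", "site", "lat", "lon", "ecoregion")],
                 truth = list(clusters = clusters, origins = origins,
                              site_hops = unlist(hops), fis = fis,
                              config = cfg)),
            class = "simulated_invasion")
}

site_name <- function(k, j) sprintf("I%dS%02d", k, j)

# Chain colonization for one introduction; returns sampled genotypes,
# per-sample metadata rows, and hop counts per site.
simulate_one_introduction <- function(cfg, k, founder_freqs) {
  n_sites <- cfg$sites_per_introduction[k]
  origin_pop <- simulate_selfing_population(
    founder_freqs, cfg$S, cfg$generations[k], cfg$origin_pop_size)
  # settle the origin site itself at site_pop_size
  pops <- vector("list", n_sites)
  pops[[1]] <- origin_pop[sample.int(nrow(origin_pop), cfg$site_pop_size,
                                     replace = cfg$site_pop_size > nrow(origin_pop)), ,
                          drop = FALSE]
  coords <- matrix(NA_real_, n_sites, 2)
  coords[1, ] <- c(cfg$origins$lat[k], cfg$origins$lon[k])
  bearing <- stats::runif(1, 0, 2 * pi)
  wave <- c(0L, ceiling(seq_len(n_sites - 1) / cfg$wave_size))
  for (j in seq_len(n_sites)[-1]) {
    prev_wave <- which(wave == wave[j] - 1L)
    src <- pops[[prev_wave[sample.int(length(prev_wave), 1)]]]
    founders <- src[sample.int(nrow(src), min(cfg$n_founders_per_hop, nrow(src))), ,
                    drop = FALSE]
    pop <- founders
    for (gen in seq_len(cfg$settle_generations)) {
      pop <- reproduce_generation(pop, cfg$S, cfg$site_pop_size)
    }
    pops[[j]] <- pop
    step_km <- stats::runif(1, cfg$hop_km_range[1], cfg$hop_km_range[2])
    theta <- bearing + stats::rnorm(1, 0, pi / 6)
    dlat <- step_km * cos(theta) / 111.32
    dlon <- step_km * sin(theta) / (111.32 * cos(coords[j - 1, 1] * pi / 180))
    coords[j, ] <- coords[j - 1, ] + c(dlat, dlon)
  }
  samples <- lapply(seq_len(n_sites), function(j) {
    pop <- pops[[j]]
    take <- sample.int(nrow(pop), min(cfg$samples_per_site, nrow(pop)))
    pop[take, , drop = FALSE]
  })
  calls <- do.call(rbind, samples)
  site_ids <- rep(vapply(seq_len(n_sites), function(j) site_name(k, j),
                         character(1)),
                  times = vapply(samples, nrow, integer(1)))
  site_row <- match(site_ids, vapply(seq_len(n_sites), function(j) site_name(k, j),
                                     character(1)))
  meta <- data.frame(
    sample = NA_character_,
    site = site_ids,
    lat = coords[site_row, 1],
    lon = coords[site_row, 2],
    ecoregion = ecoregion_of(coords[site_row, 1], coords[site_row, 2]),
    cluster = paste0("cluster", k)
  )
  hops <- stats::setNames(wave,
                          vapply(seq_len(n_sites), function(j) site_name(k, j),
                                 character(1)))
  list(calls = calls, meta = meta, hops = hops)
}

# Coarse ecoregion labels by longitude band (coastal Mediterranean vs
# inland vs desert), giving a locality-in-region hierarchy for AMOVA.
ecoregion_of <- function(lat, lon) {
  ifelse(lon <= -118, "coastal",
         ifelse(lon <= -116, "inland", "desert"))
}

#' Write a simulated dataset to disk
#'
#' Writes the genotypes as a tab-delimited 0/1/2 matrix, the metadata
#' and (optionally) occurrence records as CSV, and the ground truth as
#' JSON, in the same formats the readers of this package accept.
#'
#' @param sim A [simulate_invasion()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_genotypes(sim$genotypes, paths["genotypes"])
  utils::write.csv(sim$metadata, paths["metadata"], row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}

#' Simulate dated occurrence records of an expanding range
#'
#' The cumulative number of occupied ~1 km^2 cells follows
#' `10^(rate_b * t_eff)` where `t_eff` is years since the start minus an
#' optional flat lag of `lag_years` (during the lag the range stays at
#' its initial cell). New cells appear at growing distances from the
#' origin (uniform direction; radial scale grows with the square root of
#' the occupied-cell count so cell collisions stay rare), and additional
#' records resample already-occupied cells so the total record count
#' reaches `n_records` when the cell count allows.
#'
#' @param rate_b Log10 growth rate per year (> 0).
#' @param lag_years Flat lag before growth starts; default 0.
#' @param start_year,end_year Calendar span of the records.
#' @param n_records Total records to emit (at least one per cell).
#' @param origin `c(lat, lon)` of the introduction.
#' @param dispersal_scale Radial placement scale (km per sqrt(cell)).
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `year`, `lat`, `lon`.
#' @export
simulate_occurrences <- function(rate_b, lag_years = 0, start_year = 1927,
                                 end_year = 2016, n_records = 2900,
                                 origin = c(33.83, -116.55),
                                 dispersal_scale = 2, seed = NULL) {
  stopifnot(rate_b > 0, end_year > start_year, lag_years >= 0)
  if (n_records < 1) stop("n_records must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  years <- start_year:end_year
  t_eff <- pmax(0, (years - start_year) - lag_years)
  target <- pmax(1, round(10^(rate_b * t_eff)))
  target <- cummax(target)

  occupied <- character(0)
  recs <- list()
  total <- 0
  for (i in seq_along(years)) {
    need <- target[i] - total
    tries <- 0
    while (need > 0 && tries < 60) {
      radius <- dispersal_scale * sqrt(target[i] + 1)
      m <- max(need * 2, 8)
      r <- radius * sqrt(stats::runif(m))
      theta <- stats::runif(m, 0, 2 * pi)
      lat <- origin[1] + r * cos(theta) / 111.32
      lon <- origin[2] + r * sin(theta) / (111.32 * cos(origin[1] * pi / 180))
      key <- paste(sprintf("%.2f", round_half_away(lat, 2)),
                   sprintf("%.2f", round_half_away(lon, 2)))
      fresh <- !duplicated(key) & !(key %in% occupied)
      take <- which(fresh)[seq_len(min(need, sum(fresh)))]
      if (length(take) > 0) {
        occupied <- c(occupied, key[take])
        recs[[length(recs) + 1]] <- data.frame(year = years[i],
                                               lat = lat[take],
                                               lon = lon[take])
        total <- total + length(take)
        need <- need - length(take)
      }
      tries <- tries + 1
    }
  }
  out <- do.call(rbind, recs)
  extra <- n_records - nrow(out)
  if (extra > 0) {
    idx <- sample.int(nrow(out), extra, replace = TRUE)
    resampled <- out[idx, , drop = FALSE]
    resampled$year <- vapply(resampled$year, function(y) {
      if (y >= end_year) end_year else sample(y:end_year, 1)
    }, numeric(1))
    out <- rbind(out, resampled)
  }
  rownames(out) <- NULL
  out$year <- as.integer(out$year)
  out
}
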