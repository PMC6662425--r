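#' Great-circle distance (haversine)
#'
#' Haversine distance in kilometres with Earth radius 6,371 km;
#' coordinates in WGS84 decimal degrees.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Per-site rare-variant density
#'
#' A rare variant segregates at a site iff at least one copy of its
#' minor allele (the globally rarer allele on the current matrix) is
#' observed among the site's non-missing calls. The density is the count
#' of segregating rare variants divided by the number of loci with at
#' least one non-missing call at the site, so sites with different
#' missingness are comparable; the raw count is also returned.
#'
#' @param g A [genotype_matrix].
#' @param metadata Sample metadata (as from [read_metadata()]); must
#'   cover every sample in `g`.
#' @param rare Logical per-locus rare flags; computed with
#'   [flag_rare_variants()] at `maf_threshold` when omitted.
#' @param freqs Allele frequencies matching `g` (used to identify the
#'   minor allele); computed when omitted.
#' @param maf_threshold MAF threshold for the default rare flags.
#' @return `data.frame` with columns `site`, `lat`, `lon`, `n_samples`,
#'   `n_rare`, `loci_assessed`, `density`, `flag` (sites with zero
#'   non-missing calls are flagged `"no calls"` and carry `NA` density).
#' @export
site_rare_variant_density <- function(g, metadata, rare = NULL, freqs = NULL,
                                      maf_threshold = 0.10) {
  g <- as_gm(g)
  md <- metadata[match(g$samples, metadata$sample), , drop = FALSE]
  if (anyNA(md$site)) {
    stop("metadata missing for sample(s): ",
         paste(utils::head(g$samples[is.na(md$site)], 5), collapse = ", "))
  }
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  if (is.null(rare)) rare <- flag_rare_variants(freqs, maf_threshold)
  minor_is_alt <- !is.na(freqs$p) & freqs$p <= 0.5
  x <- g$calls
  sites <- sort(unique(md$site))
  rows <- lapply(sites, function(s) {
    idx <- which(md$site == s)
    xs <- x[idx, , drop = FALSE]
    called <- colSums(!is.na(xs)) > 0
    carries_alt <- colSums(xs > 0L, na.rm = TRUE) > 0
    carries_ref <- colSums(xs < 2L, na.rm = TRUE) > 0
    carries_minor <- ifelse(minor_is_alt, carries_alt, carries_ref)
    assessed <- sum(called)
    n_rare <- sum(rare & called & carries_minor)
    data.frame(site = s, lat = md$lat[idx[1]], lon = md$lon[idx[1]],
               n_samples = length(idx), n_rare = n_rare,
               loci_assessed = assessed,
               density = if (assessed > 0) n_rare / assessed else NA_real_,
               flag = if (assessed > 0) "" else "no calls")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit an exponential variogram to empirical semivariances
#'
#' Semivariances `(z_i - z_j)^2 / 2` are binned by great-circle distance
#' and the exponential model
#' `gamma(h) = nugget + psill * (1 - exp(-h / range))` is fitted by
#' weighted least squares (weights `N_bin / gamma_model^2`).
#'
#' @param sites `data.frame` with `lat`, `lon` and the value column.
#' @param value_col Column holding the interpolated quantity.
#' @param n_bins Number of distance bins; default 12.
#' @return List with `model = "exponential"`, `nugget`, `psill`, `range`
#'   (km), `sill` (= nugget + psill), and the `empirical` bin table.
#' @export
fit_variogram <- function(sites, value_col = "density", n_bins = 12) {
  z <- sites[[value_col]]
  n <- nrow(sites)
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  h <- haversine_km(sites$lat[pair[, 1]], sites$lon[pair[, 1]],
                    sites$lat[pair[, 2]], sites$lon[pair[, 2]])
  sv <- (z[pair[, 1]] - z[pair[, 2]])^2 / 2
  hmax <- max(h) * 0.75
  use <- h <= hmax & h > 0
  br <- seq(0, hmax, length.out = n_bins + 1)
  bin <- cut(h[use], br, include.lowest = TRUE)
  emp <- data.frame(
    h = tapply(h[use], bin, mean),
    gamma = tapply(sv[use], bin, mean),
    n = as.vector(table(bin))
  )
  emp <- emp[emp$n > 0 & !is.na(emp$gamma), , drop = FALSE]
  vz <- stats::var(z)
  start <- c(nugget = 0.05 * vz + 1e-12, psill = max(vz, 1e-12),
             range = max(stats::median(h), 1))
  if (nrow(emp) >= 3 && vz > 0) {
    obj <- function(par) {
      par <- exp(par)
      mod <- par[1] + par[2] * (1 - exp(-emp$h / par[3]))
      sum(emp$n * (emp$gamma - mod)^2 / pmax(mod, 1e-12)^2)
    }
    fit <- stats::optim(log(start), obj, method = "Nelder-Mead",
                        control = list(maxit = 500))
    par <- exp(fit$par)
  } else {
    par <- start
  }
  list(model = "exponential", nugget = unname(par[1]), psill = unname(par[2]),
       range = unname(par[3]), sill = unname(par[1] + par[2]),
       empirical = emp)
}

variogram_gamma <- function(vg, h) {
  vg$nugget + vg$psill * (1 - exp(-h / vg$range))
}

#' Ordinary kriging of site values without a trend surface
#'
#' Solves the ordinary-kriging system in semivariogram form at every node
#' of a regular lat/lon grid: weights satisfy `Gamma w + mu 1 = gamma_0`
#' with `sum(w) = 1` (the unbiasedness constraint), where `Gamma` holds
#' pairwise semivariances between sites and `gamma_0` semivariances from
#' sites to the target node. With `gamma(0) = 0` the predictor is an
#' exact interpolator at observed sites. The weight-sum condition is
#' asserted at every node.
#'
#' @param sites `data.frame` with columns `lat`, `lon` and `value_col`.
#' @param value_col Column with the values to interpolate; default
#'   `"density"`.
#' @param grid_spacing Grid resolution in degrees; default 0.05.
#' @param pad Bounding-box padding in degrees; default 0.25.
#' @param variogram Optional variogram (as from [fit_variogram()], or a
#'   list with `nugget`, `psill`, `range`); fitted from the data when
#'   omitted.
#' @param on_duplicates `"error"` or `"jitter"` (adds ~1e-5 degrees) for
#'   coincident site coordinates.
#' @return Object of class `kriging_surface`: list with `grid`
#'   (`data.frame` `lat`, `lon`, `prediction`), `variogram`, `sites`,
#'   `max_weight_sum_error`.
#' @export
ordinary_kriging <- function(sites, value_col = "density",
                             grid_spacing = 0.05, pad = 0.25,
                             variogram = NULL,
                             on_duplicates = c("error", "jitter")) {
  on_duplicates <- match.arg(on_duplicates)
  sites <- sites[!is.na(sites[[value_col]]), , drop = FALSE]
  n <- nrow(sites)
  if (n < 3) stop("ordinary kriging needs at least 3 sites with values")
  if (anyDuplicated(sites[, c("lat", "lon")])) {
    if (on_duplicates == "error") {
      stop("duplicate site coordinates make the kriging system singular; ",
           "use on_duplicates = \"jitter\" or aggregate sites")
    }
    dup <- duplicated(sites[, c("lat", "lon")])
    sites$lat[dup] <- sites$lat[dup] + stats::runif(sum(dup), -1e-5, 1e-5)
    sites$lon[dup] <- sites$lon[dup] + stats::runif(sum(dup), -1e-5, 1e-5)
  }
  if (is.null(variogram)) variogram <- fit_variogram(sites, value_col)
  z <- sites[[value_col]]

  lat_r <- range(sites$lat) + c(-pad, pad)
  lon_r <- range(sites$lon) + c(-pad, pad)
  grid <- expand.grid(
    lat = seq(lat_r[1], lat_r[2], by = grid_spacing),
    lon = seq(lon_r[1], lon_r[2], by = grid_spacing)
  )

  h_sites <- outer(seq_len(n), seq_len(n), function(i, j) {
    haversine_km(sites$lat[i], sites$lon[i], sites$lat[j], sites$lon[j])
  })
  G <- variogram_gamma(variogram, h_sites)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop("kriging system is singular: ", conditionMessage(e))
  })

  h0 <- outer(seq_len(n), seq_len(nrow(grid)), function(i, j) {
    haversine_km(sites$lat[i], sites$lon[i], grid$lat[j], grid$lon[j])
  })
  g0 <- variogram_gamma(variogram, h0)
  g0[h0 == 0] <- 0
  rhs <- rbind(g0, 1)
  Wfull <- Ainv %*% rhs
  W <- Wfull[seq_len(n), , drop = FALSE]
  wsum_err <- max(abs(colSums(W) - 1))
  stopifnot(wsum_err < 1e-6)
  grid$prediction <- drop(crossprod(W, z))

  structure(list(grid = grid, variogram = variogram, sites = sites,
                 value_col = value_col, max_weight_sum_error = wsum_err),
            class = "kriging_surface")
}

#' @export
print.kriging_surface <- function(x, ...) {
  cat(sprintf("kriging surface: %d nodes from %d sites (%s variogram: nugget %.3g, psill %.3g, range %.1f km)\n",
              nrow(x$grid), nrow(x$sites), x$variogram$model,
              x$variogram$nugget, x$variogram$psill, x$variogram$range))
  invisible(x)
}

#' Site (or surface node) of maximum density
#'
#' Returns the argmax of the per-site density (default) or of a kriged
#' surface. Ties are broken lexicographically by site name (or by grid
#' order for surfaces) so results are deterministic.
#'
#' @param density Per-site table from [site_rare_variant_density()].
#' @param surface Optional [ordinary_kriging()] result; used when
#'   `use = "surface"`.
#' @param use `"sites"` (default) or `"surface"`.
#' @return One-row `data.frame` with `site` (NA for surface maxima),
#'   `lat`, `lon`, `density`.
#' @export
peak_site <- function(density, surface = NULL, use = c("sites", "surface")) {
  use <- match.arg(use)
  if (use == "surface") {
    if (is.null(surface)) stop("surface maximum requested but no surface given")
    i <- which.max(surface$grid$prediction)
    return(data.frame(site = NA_character_, lat = surface$grid$lat[i],
                      lon = surface$grid$lon[i],
                      density = surface$grid$prediction[i]))
  }
  d <- density[!is.na(density$density), , drop = FALSE]
  if (nrow(d) == 0) stop("empty density table")
  d <- d[order(-d$density, d$site), , drop = FALSE]
  data.frame(site = d$site[1], lat = d$lat[1], lon = d$lon[1],
             density = d$density[1])
}

#' Rare-variant density as a function of distance from an origin
#'
#' Great-circle distances from the putative origin are computed for every
#' site and the density is smoothed by locally weighted linear regression
#' (tricube weights, [stats::loess()] with `degree = 1`). The Spearman
#' rank correlation between distance and density summarizes monotonic
#' decay.
#'
#' @param density Per-site table from [site_rare_variant_density()].
#' @param origin Numeric `c(lat, lon)` (or a one-row data.frame with
#'   `lat`/`lon`).
#' @param span Loess span; default 0.75.
#' @return Object of class `distance_decay_fit`: list with `table`
#'   (`site`, `distance_km`, `density`, `fitted`), `origin`, `span`,
#'   `spearman_rho`, `loess`.
#' @export
distance_decay <- function(density, origin, span = 0.75) {
  if (is.data.frame(origin)) origin <- c(origin$lat[1], origin$lon[1])
  d <- density[!is.na(density$density), , drop = FALSE]
  if (nrow(d) < 5) stop("distance decay needs at least 5 sites with densities")
  dist_km <- haversine_km(origin[1], origin[2], d$lat, d$lon)
  if (stats::var(dist_km) == 0) stop("all sites at identical distance from origin")
  fit <- stats::loess(d$density ~ dist_km, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  rho <- suppressWarnings(
    stats::cor(dist_km, d$density, method = "spearman"))
  structure(list(table = data.frame(site = d$site, distance_km = dist_km,
                                    density = d$density,
                                    fitted = stats::predict(fit)),
                 origin = c(lat = origin[1], lon = origin[2]),
                 span = span, spearman_rho = rho, loess = fit),
            class = "distance_decay_fit")
}

#' @export
print.distance_decay_fit <- function(x, ...) {
  cat(sprintf("distance decay from (%.3f, %.3f): %d sites, Spearman rho = %.3f\n",
              x$origin[1], x$origin[2], nrow(x$table), x$spearman_rho))
  invisible(x)
}

#' Iterative peeling of introductions
#'
#' Orders introductions from most recent to oldest by repeatedly locating
#' the site with the highest rare-variant density and stripping the
#' focal cluster's signal. Each round: (1) rare variants are re-flagged
#' on the current matrix; (2) per-site densities are computed; (3) the
#' peak site among sites whose majority cluster has not yet been peeled
#' is recorded together with its majority cluster and (optionally) a
#' distance-decay fit and kriged surface; (4) loci whose minor allele is
#' private to the focal cluster (default) or all rare loci segregating in
#' it (`removal = "cluster_rare"`) are removed before the next round.
#' The procedure stops when every cluster has been focal once, when
#' `max_rounds` is reached, or when a round finds no rare variants or no
#' removable loci (logged). Because the newest introduction carries the
#' densest rare variation, the round order estimates true recency order.
#'
#' @param g A [genotype_matrix].
#' @param metadata Sample metadata covering every sample.
#' @param clusters Cluster labels (vector parallel to samples or named
#'   by sample id), e.g. hard assignments from [estimate_admixture()].
#' @param max_rounds Cap on rounds; default the number of clusters.
#' @param maf_threshold Rare-variant MAF threshold; default 0.10.
#' @param removal Locus-removal rule between rounds; see Details.
#' @param compute_decay Fit [distance_decay()] per round (needs >= 5
#'   sites); default `TRUE`.
#' @param compute_surface Krige the density per round; default `FALSE`
#'   (the surface is cartographic output, not needed for ordering).
#' @param span,grid_spacing Passed to the per-round fits.
#' @return Object of class `introduction_inference`: list with `rounds`
#'   (each holding `round`, `cluster`, `peak`, `density`, `decay`,
#'   `surface`, `loci_removed`), `order` (`data.frame`: round, cluster,
#'   site, lat, lon, density), and `stopped_because`.
#' @export
iterative_peeling <- function(g, metadata, clusters, max_rounds = NULL,
                              maf_threshold = 0.10,
                              removal = c("private_minor", "cluster_rare"),
                              compute_decay = TRUE, compute_surface = FALSE,
                              span = 0.75, grid_spacing = 0.05) {
  removal <- match.arg(removal)
  g <- as_gm(g)
  clusters <- align_labels(clusters, g$samples, "clusters")
  md <- metadata[match(g$samples, metadata$sample), , drop = FALSE]
  all_clusters <- sort(unique(clusters))
  if (is.null(max_rounds)) max_rounds <- length(all_clusters)
  site_cluster <- vapply(split(clusters, md$site), majority_label, character(1))

  cur <- g
  peeled <- character(0)
  rounds <- list()
  stopped <- "all clusters peeled"
  for (r in seq_len(max_rounds)) {
    freqs <- allele_frequencies(cur)
    rare <- flag_rare_variants(freqs, maf_threshold)
    if (!any(rare)) {
      stopped <- paste0("no rare variants in round ", r)
      message(stopped)
      break
    }
    dens <- site_rare_variant_density(cur, md, rare, freqs)
    eligible <- dens[site_cluster[dens$site] %in%
                       setdiff(all_clusters, peeled), , drop = FALSE]
    if (nrow(eligible) == 0 || all(is.na(eligible$density))) {
      stopped <- paste0("no eligible sites in round ", r)
      message(stopped)
      break
    }
    peak <- peak_site(eligible)
    focal <- unname(site_cluster[peak$site])
    decay <- NULL
    if (compute_decay && sum(!is.na(dens$density)) >= 5) {
      decay <- distance_decay(dens, c(peak$lat, peak$lon), span = span)
    }
    surface <- NULL
    if (compute_surface && sum(!is.na(dens$density)) >= 3) {
      surface <- ordinary_kriging(dens, grid_spacing = grid_spacing)
    }
    loci_removed <- character(0)
    remaining <- setdiff(all_clusters, c(peeled, focal))
    if (length(remaining) > 0) {
      drop_loci <- if (removal == "private_minor") {
        minor_private_loci(cur, clusters, focal, freqs)
      } else {
        cluster_rare_loci(cur, clusters, focal, rare, freqs)
      }
      if (length(drop_loci) == 0) {
        rounds[[r]] <- list(round = r, cluster = focal, peak = peak,
                            density = dens, decay = decay, surface = surface,
                            loci_removed = character(0))
        stopped <- paste0("no removable loci for cluster ", focal,
                          " in round ", r)
        message(stopped)
        break
      }
      loci_removed <- drop_loci
      cur <- cur[, setdiff(cur$loci, drop_loci)]
    }
    rounds[[r]] <- list(round = r, cluster = focal, peak = peak,
                        density = dens, decay = decay, surface = surface,
                        loci_removed = loci_removed)
    peeled <- c(peeled, focal)
    if (length(setdiff(all_clusters, peeled)) == 0) break
  }
  rounds <- Filter(Negate(is.null), rounds)
  ord <- do.call(rbind, lapply(rounds, function(rd) {
    data.frame(round = rd$round, cluster = rd$cluster, site = rd$peak$site,
               lat = rd$peak$lat, lon = rd$peak$lon,
               density = rd$peak$density)
  }))
  structure(list(rounds = rounds, order = ord, stopped_because = stopped,
                 removal = removal),
            class = "introduction_inference")
}

#' @export
print.introduction_inference <- function(x, ...) {
  cat("introduction inference (", length(x$rounds), " round(s), newest first):\n",
      sep = "")
  print(x$order, digits = 4)
  invisible(x)
}

majority_label <- function(v) {
  tab <- sort(table(v), decreasing = TRUE)
  top <- names(tab)[tab == tab[1]]
  sort(top)[1]
}

# Loci whose (global) minor allele is observed only in the focal cluster.
minor_private_loci <- function(g, clusters, focal, freqs) {
  x <- g$calls
  minor_is_alt <- !is.na(freqs$p) & freqs$p <= 0.5
  in_focal <- clusters == focal
  carries <- function(rows, alt) {
    xs <- x[rows, , drop = FALSE]
    if (alt) colSums(xs > 0L, na.rm = TRUE) > 0 else colSums(xs < 2L, na.rm = TRUE) > 0
  }
  focal_alt <- carries(in_focal, TRUE)
  focal_ref <- carries(in_focal, FALSE)
  other_alt <- carries(!in_focal, TRUE)
  other_ref <- carries(!in_focal, FALSE)
  focal_minor <- ifelse(minor_is_alt, focal_alt, focal_ref)
  other_minor <- ifelse(minor_is_alt, other_alt, other_ref)
  g$loci[focal_minor & !other_minor]
}

# All rare loci whose minor allele segregates in the focal cluster.
cluster_rare_loci <- function(g, clusters, focal, rare, freqs) {
  x <- g$calls[clusters == focal, , drop = FALSE]
  minor_is_alt <- !is.na(freqs$p) & freqs$p <= 0.5
  carries_minor <- ifelse(minor_is_alt,
                          colSums(x > 0L, na.rm = TRUE) > 0,
                          colSums(x < 2L, na.rm = TRUE) > 0)
  g$loci[rare & carries_minor]
}
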