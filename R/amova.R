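#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions genetic variance among individuals within localities,
#' among localities (within ecoregions when `regions` is supplied), and
#' among ecoregions, following the sums-of-squares decomposition of
#' Excoffier, Smouse & Quattro (1992) applied to squared Euclidean
#' distances on 0/1/2 dosage vectors. Missing data are handled by
#' pairwise-complete loci with the squared distance rescaled by
#' L / L_complete. Significance is assessed by permutation:
#' \itemize{
#'   \item overall (within-localities row, Phi_ST): individuals permuted
#'     across all localities;
#'   \item locality level (Phi_SC): individuals permuted among localities
#'     within their region;
#'   \item region level (Phi_CT): whole localities permuted among regions.
#' }
#' Each p-value is `(#\{Phi_perm >= Phi_obs\} + 1) / (n_permutations + 1)`.
#'
#' @param g A [genotype_matrix].
#' @param localities Locality labels (vector parallel to samples, or
#'   named by sample id).
#' @param regions Optional region (ecoregion) labels, same conventions.
#'   Every locality must map to exactly one region.
#' @param n_permutations Number of permutations per level; default 999.
#' @param seed Integer seed for the permutations (required when
#'   `n_permutations > 0`).
#' @return Object of class `amova_result`: list with `table` (rows
#'   "Within localities", "Between localities", and, when hierarchical,
#'   "Between regions"; columns `sigma`, `percent`, `phi`, `p`), `df`,
#'   `ss`, `n_permutations`, `seed`. Negative variance components are
#'   reported as-is and flagged in `table$flag`.
#' @export
amova <- function(g, localities, regions = NULL, n_permutations = 999,
                  seed = NULL) {
  g <- as_gm(g)
  loc <- align_labels(localities, g$samples, "localities")
  reg <- if (is.null(regions)) NULL else align_labels(regions, g$samples, "regions")
  if (length(unique(loc)) < 2) stop("AMOVA needs at least 2 localities")
  if (!is.null(reg)) {
    map <- unique(data.frame(loc = loc, reg = reg))
    if (anyDuplicated(map$loc)) {
      stop("each locality must map to exactly one region")
    }
    if (length(unique(reg)) < 2) reg <- NULL  # degenerate hierarchy
  }
  if (n_permutations > 0 && is.null(seed)) {
    stop("a seed is required for the permutation test")
  }

  d2 <- amova_squared_distances(g)
  keep <- attr(d2, "kept")
  loc <- loc[keep]
  if (!is.null(reg)) reg <- reg[keep]

  obs <- amova_decompose(d2, loc, reg)
  tot <- sum(obs$sigma)
  if (tot <= 0) {
    warning("zero total variance; Phi statistics undefined")
  }

  p <- rep(NA_real_, length(obs$phi))
  if (n_permutations > 0 && tot > 0) {
    set.seed(seed)
    n <- length(loc)
    count <- numeric(length(obs$phi))
    for (b in seq_len(n_permutations)) {
      # overall: permute individuals across everything
      perm_all <- sample.int(n)
      phi_all <- amova_decompose(d2, loc[perm_all],
                                 if (is.null(reg)) NULL else reg[perm_all])$phi
      count[1] <- count[1] + (!is.na(phi_all[1]) && phi_all[1] >= obs$phi[1])
      if (!is.null(reg)) {
        # locality level: permute individuals among localities within region
        perm_wr <- seq_len(n)
        for (r in unique(reg)) {
          idx <- which(reg == r)
          perm_wr[idx] <- idx[sample.int(length(idx))]
        }
        phi_sc <- amova_decompose(d2, loc[perm_wr], reg)$phi
        count[2] <- count[2] + (!is.na(phi_sc[2]) && phi_sc[2] >= obs$phi[2])
        # region level: permute whole localities among regions
        map <- unique(data.frame(loc = loc, reg = reg))
        map$reg <- map$reg[sample.int(nrow(map))]
        reg_perm <- map$reg[match(loc, map$loc)]
        phi_ct <- amova_decompose(d2, loc, reg_perm)$phi
        count[3] <- count[3] + (!is.na(phi_ct[3]) && phi_ct[3] >= obs$phi[3])
      } else {
        count[2] <- count[2] + (!is.na(phi_all[2]) && phi_all[2] >= obs$phi[2])
      }
    }
    p <- (count + 1) / (n_permutations + 1)
  }

  percent <- if (tot > 0) 100 * obs$sigma / tot else rep(0, length(obs$sigma))
  rows <- if (is.null(reg)) {
    c("Within localities", "Between localities")
  } else {
    c("Within localities", "Between localities", "Between regions")
  }
  tab <- data.frame(
    level = rows,
    sigma = obs$sigma,
    percent = percent,
    phi = obs$phi,
    p = p,
    flag = ifelse(obs$sigma < 0, "negative component",
                  ifelse(tot <= 0, "undefined", "")),
    row.names = NULL
  )
  structure(list(table = tab, df = obs$df, ss = obs$ss,
                 n_permutations = n_permutations, seed = seed),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$n_permutations, " permutations)\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

# Pairwise squared Euclidean distances on dosages, pairwise-complete
# loci rescaled to the full locus count. Samples sharing no called locus
# with some other sample are removed with a warning.
amova_squared_distances <- function(g) {
  x <- g$calls
  n <- nrow(x)
  L <- ncol(x)
  m <- !is.na(x)
  x0 <- x
  x0[!m] <- 0L
  x0 <- matrix(as.numeric(x0), n, L)
  mm <- matrix(as.numeric(m), n, L)
  common <- tcrossprod(mm)
  sq <- x0^2
  raw <- tcrossprod(sq, mm) + tcrossprod(mm, sq) - 2 * tcrossprod(x0)
  kept <- seq_len(n)
  while (TRUE) {
    off <- common[kept, kept, drop = FALSE]
    diag(off) <- 1
    if (all(off > 0)) break
    worst <- kept[which.max(rowSums(common[kept, kept, drop = FALSE] == 0))]
    warning("sample ", g$samples[worst],
            " shares no called locus with another sample; excluded from AMOVA")
    kept <- setdiff(kept, worst)
    if (length(kept) < 2) stop("too few samples with computable distances")
  }
  d2 <- raw * L / pmax(common, 1)
  d2 <- d2[kept, kept, drop = FALSE]
  attr(d2, "kept") <- kept
  d2
}

# Core decomposition: squared-distance matrix + labels -> sigma, phi, df.
# With `reg = NULL` a one-level (localities only) AMOVA is returned with
# phi = c(Phi_ST, Phi_ST, NA) collapsed to two levels.
amova_decompose <- function(d2, loc, reg = NULL) {
  n <- length(loc)
  loc <- as.character(loc)
  # block sums of squared distances by locality
  bl <- rowsum(t(rowsum(d2, loc)), loc)  # locality x locality sums
  n_p <- as.vector(table(loc)[rownames(bl)])
  ss_total <- sum(d2) / (2 * n)
  ss_wp <- sum(diag(bl) / (2 * n_p))
  df_wp <- n - length(n_p)
  sigma_c <- ss_wp / df_wp
  if (is.null(reg)) {
    p_n <- length(n_p)
    ss_ap <- ss_total - ss_wp
    df_ap <- p_n - 1
    n_coef <- (n - sum(n_p^2) / n) / df_ap
    sigma_b <- (ss_ap / df_ap - sigma_c) / n_coef
    tot <- sigma_b + sigma_c
    phi_st <- if (tot > 0) sigma_b / tot else NA_real_
    return(list(sigma = c(within = sigma_c, between_localities = sigma_b),
                phi = c(phi_st = phi_st, phi_sc = phi_st),
                df = c(within = df_wp, between_localities = df_ap),
                ss = c(within = ss_wp, between_localities = ss_ap,
                       total = ss_total)))
  }
  reg <- as.character(reg)
  loc_reg <- tapply(reg, loc, function(r) r[1])[rownames(bl)]
  g_n <- length(unique(reg))
  p_n <- length(n_p)
  # within-group (region) sums
  n_g <- as.vector(tapply(n_p, loc_reg, sum))
  names(n_g) <- names(tapply(n_p, loc_reg, sum))
  br <- rowsum(t(rowsum(d2, reg)), reg)
  ss_wg <- sum(diag(br)[names(n_g)] / (2 * n_g))
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_total - ss_wg
  df_ap <- p_n - g_n
  df_ag <- g_n - 1
  sum_np2_by_g <- tapply(n_p^2, loc_reg, sum)
  a_term <- sum(sum_np2_by_g / n_g[names(sum_np2_by_g)])
  n_coef <- (n - a_term) / df_ap
  np_coef <- (a_term - sum(n_p^2) / n) / df_ag
  npp_coef <- (n - sum(n_g^2) / n) / df_ag
  sigma_b <- (ss_ap / df_ap - sigma_c) / n_coef
  sigma_a <- (ss_ag / df_ag - sigma_c - np_coef * sigma_b) / npp_coef
  tot <- sigma_a + sigma_b + sigma_c
  phi_st <- if (tot > 0) (sigma_a + sigma_b) / tot else NA_real_
  phi_sc <- if ((sigma_b + sigma_c) > 0) sigma_b / (sigma_b + sigma_c) else NA_real_
  phi_ct <- if (tot > 0) sigma_a / tot else NA_real_
  list(sigma = c(within = sigma_c, between_localities = sigma_b,
                 between_regions = sigma_a),
       phi = c(phi_st = phi_st, phi_sc = phi_sc, phi_ct = phi_ct),
       df = c(within = df_wp, between_localities = df_ap,
              between_regions = df_ag),
       ss = c(within = ss_wp, between_localities = ss_ap,
              between_regions = ss_ag, total = ss_total))
}
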