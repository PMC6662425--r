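#' Standardized index of association (r-bar-d)
#'
#' Multilocus linkage disequilibrium summary of Agapow & Burt (2001).
#' The per-locus distance between two individuals is
#' `|dosage_i - dosage_j| / 2`, defined over pairs where both calls are
#' present. Writing `V_O` for the variance over individual pairs of the
#' distance summed across loci, `var_j` for the variance of the locus-j
#' distances, and `V_E = sum_j var_j`, the statistic is
#' \deqn{\bar r_d = \frac{V_O - V_E}{2 \sum_{j<k} \sqrt{var_j var_k}}.}
#' Under free recombination and random mating r-bar-d is near 0; selfing
#' and clonality inflate it. Significance is from a one-sided upper-tail
#' permutation test that shuffles each locus's calls independently among
#' samples, `p = (#\{r_perm >= r_obs\} + 1) / (n_permutations + 1)`.
#'
#' @param g A [genotype_matrix].
#' @param n_permutations Permutations for the test; default 999. Use 0 to
#'   skip the test.
#' @param seed Integer seed (required when `n_permutations > 0`).
#' @param groups Optional grouping (vector parallel to samples or named
#'   by sample id): the statistic is then computed within each group and
#'   a `data.frame` is returned.
#' @return Object of class `index_of_association`: list with `rbar_d`,
#'   `Ia` (the unstandardized index `V_O / V_E - 1`), `V_O`, `V_E`,
#'   `p_value`, `n_permutations`, `seed`, `n_samples`, `n_loci`. With
#'   `groups`, a `data.frame` with one row per group.
#' @export
rbar_d <- function(g, n_permutations = 999, seed = NULL, groups = NULL) {
  g <- as_gm(g)
  if (!is.null(groups)) {
    groups <- align_labels(groups, g$samples, "groups")
    out <- lapply(sort(unique(groups)), function(grp) {
      res <- rbar_d(g[groups == grp, ], n_permutations = n_permutations,
                    seed = seed)
      data.frame(group = grp, rbar_d = res$rbar_d, Ia = res$Ia,
                 V_O = res$V_O, V_E = res$V_E, p_value = res$p_value,
                 n_samples = res$n_samples, n_loci = res$n_loci)
    })
    return(do.call(rbind, out))
  }
  x <- g$calls
  n <- nrow(x)
  if (n < 3) stop("r-bar-d needs at least 3 samples")
  n_called <- colSums(!is.na(x))
  p <- colSums(x, na.rm = TRUE) / (2 * pmax(n_called, 1))
  poly <- n_called > 0 & p > 0 & p < 1
  if (sum(poly) < 2) stop("r-bar-d needs at least 2 polymorphic loci")
  if (n_permutations > 0 && is.null(seed)) {
    stop("a seed is required for the permutation test")
  }

  per_locus <- locus_pair_variances(x)
  v_e <- sum(per_locus$var)
  denom <- sum(sqrt(per_locus$var))^2 - sum(per_locus$var)
  if (denom <= 0) stop("denominator of r-bar-d is zero (no locus-pair variance)")

  v_o <- observed_pair_variance(x)
  rbar <- (v_o - v_e) / denom
  ia <- if (v_e > 0) v_o / v_e - 1 else NA_real_

  p_value <- NA_real_
  if (n_permutations > 0) {
    set.seed(seed)
    count <- 0L
    for (b in seq_len(n_permutations)) {
      xp <- x
      for (j in seq_len(ncol(x))) xp[, j] <- x[sample.int(n), j]
      v_o_p <- observed_pair_variance(xp)
      rb_p <- (v_o_p - v_e) / denom
      if (rb_p >= rbar) count <- count + 1L
    }
    p_value <- (count + 1) / (n_permutations + 1)
  }

  structure(list(rbar_d = rbar, Ia = ia, V_O = v_o, V_E = v_e,
                 p_value = p_value, n_permutations = n_permutations,
                 seed = seed, n_samples = n, n_loci = ncol(x)),
            class = "index_of_association")
}

#' @export
print.index_of_association <- function(x, ...) {
  cat(sprintf("rbar_d = %.4f (Ia = %.4f), p = %s [%d samples, %d loci]\n",
              x$rbar_d, x$Ia,
              ifelse(is.na(x$p_value), "NA", format(x$p_value)),
              x$n_samples, x$n_loci))
  invisible(x)
}

# Per-locus variance (over individual pairs) of |d_i - d_j|/2, computed
# from genotype counts among non-missing calls. Sample variance with
# denominator (#pairs - 1).
locus_pair_variances <- function(x) {
  n0 <- colSums(x == 0L, na.rm = TRUE)
  n1 <- colSums(x == 1L, na.rm = TRUE)
  n2 <- colSums(x == 2L, na.rm = TRUE)
  nt <- n0 + n1 + n2
  np <- nt * (nt - 1) / 2
  c_half <- n1 * (n0 + n2)        # pairs at distance 1/2
  c_one <- n0 * n2                # pairs at distance 1
  s1 <- 0.5 * c_half + c_one
  s2 <- 0.25 * c_half + c_one
  v <- ifelse(np > 1, (s2 - s1^2 / np) / (np - 1), 0)
  v[v < 0] <- 0                   # guard tiny negatives
  list(var = v, n_pairs = np)
}

# Variance over pairs of the distance summed across loci. Complete data
# use a fast binary-expansion matrix product (|a-b| for dosages equals the
# Hamming distance of the indicators a>=1, a>=2); with missing data the
# same products are masked so a locus contributes only to pairs where
# both calls are present. Pairs sharing no called locus are dropped with
# a warning.
observed_pair_variance <- function(x) {
  n <- nrow(x)
  if (!anyNA(x)) {
    b <- cbind(x >= 1L, x >= 2L) + 0
    h <- tcrossprod(b, 1 - b)
    man <- h + t(h)
    d <- man[upper.tri(man)] / 2
    return(stats::var(d))
  }
  m <- !is.na(x)
  b1 <- (x >= 1L) & m
  b2 <- (x >= 2L) & m
  c1 <- (x < 1L) & m
  c2 <- (x < 2L) & m
  mm <- matrix(as.numeric(m), n, ncol(x))
  h <- tcrossprod(b1 + 0, c1 + 0) + tcrossprod(b2 + 0, c2 + 0)
  man <- h + t(h)
  avail <- tcrossprod(mm)
  d <- man[upper.tri(man)] / 2
  a <- avail[upper.tri(avail)]
  if (any(a == 0)) {
    warning(sum(a == 0), " sample pair(s) share no called locus; dropped")
    d <- d[a > 0]
  }
  stats::var(d)
}
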