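#' Per-locus allele frequencies
#'
#' Alternate-allele frequency p = (sum of dosages) / (2 x number of
#' non-missing calls), computed only over non-missing calls.
#'
#' @param g A [genotype_matrix].
#' @param samples Optional subset of sample ids (or indices).
#' @return `data.frame` with columns `locus`, `p` (alternate-allele
#'   frequency), `maf` (minor-allele frequency, `min(p, 1 - p)`), and
#'   `n_called` (non-missing calls). Loci with no calls in the subset get
#'   `NA` frequencies.
#' @export
allele_frequencies <- function(g, samples = NULL) {
  g <- as_gm(g)
  x <- g$calls
  if (!is.null(samples)) {
    if (length(samples) == 0) stop("empty sample subset")
    x <- x[samples, , drop = FALSE]
  }
  n_called <- colSums(!is.na(x))
  p <- colSums(x, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0] <- NA_real_
  if (any(n_called == 0)) {
    message(sum(n_called == 0), " locus/loci with no non-missing calls; ",
            "frequency undefined")
  }
  data.frame(locus = g$loci, p = p, maf = pmin(p, 1 - p),
             n_called = n_called, row.names = NULL)
}

#' Flag rare variants
#'
#' A locus is a rare variant iff `0 < MAF < threshold` (strict on both
#' sides: monomorphic loci are not rare variants, and a locus at exactly
#' the threshold is not rare).
#'
#' @param freqs Output of [allele_frequencies()].
#' @param threshold MAF threshold in (0, 0.5]; default 0.10.
#' @return Logical vector per locus (`FALSE` where MAF is undefined).
#' @export
flag_rare_variants <- function(freqs, threshold = 0.10) {
  stopifnot(threshold > 0, threshold <= 0.5)
  rare <- !is.na(freqs$maf) & freqs$maf > 0 & freqs$maf < threshold
  rare
}

#' Observed heterozygosity
#'
#' Per-locus Ho is the fraction of non-missing calls that are
#' heterozygous (dosage 1); the mean and its standard error are taken
#' over loci (SE = sd over loci / sqrt(number of loci)).
#'
#' @inheritParams allele_frequencies
#' @param exclude_monomorphic Drop loci monomorphic in the subset from the
#'   mean/SE; default `FALSE` (monomorphic loci included).
#' @return List with `per_locus`, `mean`, `se`, `n_loci`.
#' @export
observed_heterozygosity <- function(g, samples = NULL, exclude_monomorphic = FALSE) {
  g <- as_gm(g)
  x <- g$calls
  if (!is.null(samples)) {
    if (length(samples) == 0) stop("empty sample subset")
    x <- x[samples, , drop = FALSE]
  }
  ho <- colMeans(x == 1L, na.rm = TRUE)
  ho[colSums(!is.na(x)) == 0] <- NA_real_
  keep <- !is.na(ho)
  if (exclude_monomorphic) {
    p <- colSums(x, na.rm = TRUE) / (2 * colSums(!is.na(x)))
    keep <- keep & !is.na(p) & p > 0 & p < 1
  }
  vals <- ho[keep]
  list(per_locus = stats::setNames(ho, g$loci),
       mean = mean(vals),
       se = stats::sd(vals) / sqrt(length(vals)),
       n_loci = length(vals))
}

#' Expected heterozygosity
#'
#' Per-locus He = 2 p (1 - p) (no small-sample correction by default);
#' mean and SE over loci as in [observed_heterozygosity()].
#'
#' @param freqs Output of [allele_frequencies()].
#' @param unbiased Apply the n/(n-1) small-sample correction (Nei's
#'   unbiased He) per locus; default `FALSE`.
#' @param exclude_monomorphic Drop monomorphic loci from the mean/SE.
#' @return List with `per_locus`, `mean`, `se`, `n_loci`.
#' @export
expected_heterozygosity <- function(freqs, unbiased = FALSE,
                                    exclude_monomorphic = FALSE) {
  he <- 2 * freqs$p * (1 - freqs$p)
  if (unbiased) {
    n <- freqs$n_called
    he <- ifelse(n > 1, he * n / (n - 1), NA_real_)
  }
  keep <- !is.na(he)
  if (exclude_monomorphic) keep <- keep & !is.na(freqs$maf) & freqs$maf > 0
  vals <- he[keep]
  list(per_locus = stats::setNames(he, freqs$locus),
       mean = mean(vals),
       se = stats::sd(vals) / sqrt(length(vals)),
       n_loci = length(vals))
}

#' Multilocus inbreeding coefficient
#'
#' Fis = 1 - mean(Ho) / mean(He), the multilocus heterozygote-deficit
#' estimator. Values outside [-1, 1] are clamped with a warning. If
#' mean He is 0 the coefficient is undefined and `NA` is returned with a
#' warning.
#'
#' @param ho_mean Mean observed heterozygosity over loci.
#' @param he_mean Mean expected heterozygosity over loci.
#' @return Fis in [-1, 1], or `NA` when undefined.
#' @export
inbreeding_coefficient <- function(ho_mean, he_mean) {
  if (is.na(he_mean) || he_mean == 0) {
    warning("mean expected heterozygosity is 0; Fis undefined")
    return(NA_real_)
  }
  fis <- 1 - ho_mean / he_mean
  if (fis < -1 || fis > 1) {
    warning("Fis = ", signif(fis, 4), " clamped to [-1, 1]")
    fis <- max(-1, min(1, fis))
  }
  fis
}

#' Selfing and outcrossing rates from Fis
#'
#' Under inbreeding equilibrium for a partially selfing population,
#' S = 2 Fis / (1 + Fis) and T = 1 - S = (1 - Fis) / (1 + Fis).
#' Negative Fis yields a negative S, which is returned with a warning.
#'
#' @param fis Inbreeding coefficient, strictly greater than -1.
#' @return Selfing rate S (resp. outcrossing rate T).
#' @export
selfing_rate <- function(fis) {
  if (any(fis <= -1)) stop("selfing rate undefined for Fis <= -1")
  s <- 2 * fis / (1 + fis)
  if (any(s < 0)) warning("negative Fis yields a negative selfing rate")
  s
}

#' @rdname selfing_rate
#' @export
outcrossing_rate <- function(fis) 1 - selfing_rate(fis)

#' Equilibrium Fis implied by a selfing rate
#'
#' Inverse of [selfing_rate()]: Fis* = S / (2 - S), the inbreeding
#' equilibrium reached under constant partial selfing.
#'
#' @param s Selfing rate in [0, 1).
#' @return Equilibrium Fis.
#' @export
fis_at_equilibrium <- function(s) s / (2 - s)

#' Private allele counts per cluster
#'
#' An allele (reference or alternate, at any locus) is private to cluster
#' `c` iff it is observed among the non-missing calls of `c` and
#' unobserved in every other cluster. The alternate allele is observed in
#' a cluster when any dosage > 0; the reference allele when any
#' dosage < 2.
#'
#' @param g A [genotype_matrix].
#' @param clusters Cluster labels: either a vector parallel to
#'   `g$samples` or a named vector keyed by sample id. All samples must
#'   be assigned.
#' @return Named integer vector of private-allele counts per cluster.
#' @export
private_alleles <- function(g, clusters) {
  g <- as_gm(g)
  clusters <- align_labels(clusters, g$samples, "clusters")
  x <- g$calls
  alt_obs <- !is.na(x) & x > 0L
  ref_obs <- !is.na(x) & x < 2L
  # cluster x locus presence matrices
  alt_pres <- rowsum(alt_obs + 0, clusters) > 0
  ref_pres <- rowsum(ref_obs + 0, clusters) > 0
  priv_count <- function(pres) {
    n_with <- colSums(pres)
    pres_only <- pres & rep(n_with == 1, each = nrow(pres))
    rowSums(pres_only)
  }
  counts <- priv_count(alt_pres) + priv_count(ref_pres)
  counts <- counts[sort(rownames(alt_pres))]
  stats::setNames(as.integer(counts), sort(rownames(alt_pres)))
}

# Internal: align a per-sample label vector (possibly named) with samples.
align_labels <- function(labels, samples, what = "labels") {
  if (!is.null(names(labels))) {
    missing <- setdiff(samples, names(labels))
    if (length(missing)) {
      stop("unassigned sample(s) in ", what, ": ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    labels <- labels[samples]
  } else if (length(labels) != length(samples)) {
    stop(what, " must have one entry per sample")
  }
  if (any(is.na(labels))) stop("NA ", what, " not allowed")
  as.character(labels)
}

#' Per-group diversity and mating-system summary
#'
#' One row per group with the quantities of a cluster summary table:
#' sample size, mean observed and expected heterozygosity with standard
#' errors over loci, the multilocus inbreeding coefficient, the selfing
#' and outcrossing rates implied by it, and the private-allele count.
#'
#' @param g A [genotype_matrix].
#' @param groups Group labels (vector parallel to samples, or named by
#'   sample id).
#' @param exclude_monomorphic Exclude group-monomorphic loci from Ho/He
#'   means; default `FALSE`.
#' @param unbiased_he Apply the n/(n-1) correction to He; default `FALSE`.
#' @return `data.frame` with columns `group`, `n`, `Ho`, `Ho_se`, `He`,
#'   `He_se`, `Fis`, `S`, `T`, `private`.
#' @export
diversity_summary <- function(g, groups, exclude_monomorphic = FALSE,
                              unbiased_he = FALSE) {
  g <- as_gm(g)
  groups <- align_labels(groups, g$samples, "groups")
  priv <- private_alleles(g, groups)
  rows <- lapply(sort(unique(groups)), function(grp) {
    idx <- which(groups == grp)
    freqs <- allele_frequencies(g, idx)
    ho <- observed_heterozygosity(g, idx, exclude_monomorphic = exclude_monomorphic)
    he <- expected_heterozygosity(freqs, unbiased = unbiased_he,
                                  exclude_monomorphic = exclude_monomorphic)
    fis <- inbreeding_coefficient(ho$mean, he$mean)
    s <- if (is.na(fis)) NA_real_ else selfing_rate(fis)
    data.frame(group = grp, n = length(idx),
               Ho = ho$mean, Ho_se = ho$se, He = he$mean, He_se = he$se,
               Fis = fis, S = s, T = 1 - s,
               private = unname(priv[grp]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
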