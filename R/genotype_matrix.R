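#' Biallelic genotype matrix
#'
#' Container for diploid biallelic SNP genotypes coded as alternate-allele
#' dosage: 0 (homozygous reference), 1 (heterozygous), 2 (homozygous
#' alternate), or `NA` for a missing call. Rows are individuals, columns
#' are loci.
#'
#' @param calls Integer (or coercible) matrix of dosages in \{0, 1, 2, NA\}.
#'   Row names are taken as sample ids and column names as locus ids when
#'   `samples`/`loci` are not given.
#' @param samples Character vector of unique sample ids.
#' @param loci Character vector of unique locus ids.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls` (integer matrix), `samples`, and `loci`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, NA), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("L1", "L2"))))
#' n_samples(g)
#' @export
genotype_matrix <- function(calls, samples = rownames(calls), loci = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(calls)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(calls)))
  samples <- as.character(samples)
  loci <- as.character(loci)
  if (length(samples) != nrow(calls)) stop("length(samples) must equal nrow(calls)")
  if (length(loci) != ncol(calls)) stop("length(loci) must equal ncol(calls)")
  if (anyDuplicated(samples)) stop("duplicate sample ids: ",
    paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(loci)) stop("duplicate locus ids: ",
    paste(unique(loci[duplicated(loci)]), collapse = ", "))
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("calls must be 0, 1, 2 or NA; found ",
    paste(unique(calls[bad]), collapse = ", "))
  dimnames(calls) <- list(samples, loci)
  structure(list(calls = calls, samples = samples, loci = loci),
            class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param g A `genotype_matrix`.
#' @export
n_samples <- function(g) length(g$samples)

#' @rdname genotype_matrix
#' @export
n_loci <- function(g) length(g$loci)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param i Sample index (integer, logical, or sample ids).
#' @param j Locus index (integer, logical, or locus ids).
#' @param ... Ignored.
#' @return A `genotype_matrix` restricted to the selected samples/loci.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_along(x$loci)
  genotype_matrix(x$calls[i, j, drop = FALSE])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.1f%% missing)\n",
              n_samples(x), n_loci(x), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# Internal: accept either a genotype_matrix or a bare dosage matrix.
as_gm <- function(g) {
  if (inherits(g, "genotype_matrix")) g else genotype_matrix(g)
}
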