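#' Read genotypes from VCF or a 0/1/2 matrix file
#'
#' Supported formats:
#' \describe{
#'   \item{`vcf`}{VCF v4.x. Only the GT field is used; phased and unphased
#'     calls are treated identically; half-calls (e.g. `./1`) and missing
#'     genotypes become `NA`. Records that are not biallelic SNP sites
#'     (multiallelic ALT, or missing ALT) are dropped and the count is
#'     reported via [message()].}
#'   \item{`matrix012`}{Tab-delimited matrix: header row of locus ids,
#'     first column of sample ids, entries in \{0, 1, 2\} or a missing
#'     token. Accepted missing tokens: `NA`, `.`, `-9`.}
#' }
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"matrix012"`.
#' @param missing_tokens Tokens interpreted as missing in `matrix012` input.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix012"),
                           missing_tokens = c("NA", ".", "-9")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "matrix012"
  }
  if (format == "vcf") read_genotypes_vcf(path) else
    read_genotypes_matrix012(path, missing_tokens)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) stop("no variant records in VCF: ", path)
  alt <- vcf@fix[, "ALT"]
  biallelic <- !is.na(alt) & alt != "." & !grepl(",", alt, fixed = TRUE)
  n_dropped <- sum(!biallelic)
  if (n_dropped > 0) {
    message(n_dropped, " non-biallelic VCF record(s) dropped")
    vcf <- vcf[biallelic, ]
  }
  if (nrow(vcf@fix) == 0) stop("no biallelic records remain in VCF: ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- vcf@fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(vcf@fix[no_id, "CHROM"], "_", vcf@fix[no_id, "POS"])
  alleles <- gsub("\\|", "/", gt)
  parts <- strsplit(alleles, "/", fixed = TRUE)
  n_alleles <- lengths(parts)
  if (any(n_alleles > 2, na.rm = TRUE)) {
    stop("non-diploid genotype call in VCF (", max(n_alleles), " alleles)")
  }
  dos <- vapply(parts, function(a) {
    if (length(a) != 2 || any(a == ".") || any(is.na(a))) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  calls <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt))
  # vcfR's gt matrix is loci x samples; transpose to samples x loci
  calls <- t(calls)
  genotype_matrix(calls, samples = colnames(gt), loci = ids)
}

read_genotypes_matrix012 <- function(path, missing_tokens) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           row.names = 1, na.strings = character(0))
  if (ncol(tab) == 0) stop("no loci columns in matrix012 file: ", path)
  m <- as.matrix(tab)
  is_missing <- m %in% missing_tokens
  known <- m %in% c("0", "1", "2")
  if (any(!is_missing & !known)) {
    bad <- unique(m[!is_missing & !known])
    stop("unknown genotype token(s) in matrix012 file: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  calls <- suppressWarnings(matrix(as.integer(m), nrow(m), ncol(m)))
  calls[matrix(is_missing, nrow(m), ncol(m))] <- NA_integer_
  genotype_matrix(calls, samples = rownames(tab), loci = colnames(tab))
}

#' Write genotypes as a tab-delimited 0/1/2 matrix
#'
#' Missing calls are written as `NA`. The file round-trips through
#' [read_genotypes()] to an equal matrix.
#'
#' @param g A [genotype_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  g <- as_gm(g)
  out <- as.data.frame(g$calls, check.names = FALSE)
  utils::write.table(cbind(sample = g$samples, out), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove individuals with excessive missing data
#'
#' Drops samples whose fraction of missing calls is strictly greater than
#' `max_missing_fraction` (an individual with exactly the threshold
#' fraction is retained). Survivor order is preserved; removed ids are
#' reported via [message()] and attached as attribute `"removed"`.
#'
#' @param g A [genotype_matrix].
#' @param max_missing_fraction Threshold in (0, 1]; default 0.75.
#' @return Filtered [genotype_matrix].
#' @export
filter_individuals_by_missingness <- function(g, max_missing_fraction = 0.75) {
  g <- as_gm(g)
  stopifnot(max_missing_fraction > 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(g$calls))
  drop <- frac > max_missing_fraction
  if (all(drop)) {
    stop("all samples exceed the missingness threshold (",
         max_missing_fraction, ")")
  }
  if (any(drop)) {
    message(sum(drop), " individual(s) removed for >",
            round(100 * max_missing_fraction, 1), "% missing data: ",
            paste(g$samples[drop], collapse = ", "))
  }
  out <- g[!drop, ]
  attr(out, "removed") <- g$samples[drop]
  out
}

#' Retain loci genotyped in a minimum fraction of samples
#'
#' Keeps loci with non-missing calls in at least (`>=`)
#' `min_presence_fraction` of samples.
#'
#' @param g A [genotype_matrix].
#' @param min_presence_fraction Threshold in (0, 1]; default 0.10.
#' @return Filtered [genotype_matrix] with attribute `"removed"` naming
#'   dropped loci.
#' @export
filter_loci_by_presence <- function(g, min_presence_fraction = 0.10) {
  g <- as_gm(g)
  stopifnot(min_presence_fraction > 0, min_presence_fraction <= 1)
  pres <- colMeans(!is.na(g$calls))
  keep <- pres >= min_presence_fraction
  if (!any(keep)) {
    stop("all loci fall below the presence threshold (",
         min_presence_fraction, ")")
  }
  if (any(!keep)) {
    message(sum(!keep), " locus/loci removed for presence < ",
            min_presence_fraction)
  }
  out <- g[, keep]
  attr(out, "removed") <- g$loci[!keep]
  out
}

#' Read sample metadata
#'
#' CSV with headers `sample,site,lat,lon,ecoregion`. Rows with unparseable
#' coordinates are rejected and their line numbers reported.
#'
#' @param path CSV path.
#' @return `data.frame` with columns `sample`, `site`, `lat`, `lon`,
#'   `ecoregion`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample", "site", "lat", "lon", "ecoregion")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  md$lat <- suppressWarnings(as.numeric(md$lat))
  md$lon <- suppressWarnings(as.numeric(md$lon))
  bad <- is.na(md$lat) | is.na(md$lon) |
    md$lat < -90 | md$lat > 90 | md$lon < -180 | md$lon > 180
  if (any(bad)) {
    message(sum(bad), " metadata row(s) rejected (invalid coordinates), lines: ",
            paste(which(bad) + 1L, collapse = ", "))
    md <- md[!bad, , drop = FALSE]
  }
  if (anyDuplicated(md$sample)) {
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(md$sample[duplicated(md$sample)]), collapse = ", "))
  }
  rownames(md) <- NULL
  md[required]
}

#' Read dated occurrence records
#'
#' CSV with headers `year,lat,lon`. Rows with unparseable or out-of-range
#' years/coordinates are rejected with their line numbers reported.
#'
#' @param path CSV path.
#' @param year_range Acceptable year interval; default 1800 to the current
#'   calendar year.
#' @return `data.frame` with columns `year`, `lat`, `lon`.
#' @export
read_occurrences <- function(path,
                             year_range = c(1800, as.integer(format(Sys.Date(), "%Y")))) {
  if (!file.exists(path)) stop("file not found: ", path)
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("year", "lat", "lon")
  missing_cols <- setdiff(required, names(occ))
  if (length(missing_cols)) {
    stop("occurrence file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  occ$year <- suppressWarnings(as.integer(occ$year))
  occ$lat <- suppressWarnings(as.numeric(occ$lat))
  occ$lon <- suppressWarnings(as.numeric(occ$lon))
  bad <- is.na(occ$year) | is.na(occ$lat) | is.na(occ$lon) |
    occ$year < year_range[1] | occ$year > year_range[2] |
    occ$lat < -90 | occ$lat > 90 | occ$lon < -180 | occ$lon > 180
  if (any(bad)) {
    message(sum(bad), " occurrence row(s) rejected, lines: ",
            paste(which(bad) + 1L, collapse = ", "))
    occ <- occ[!bad, , drop = FALSE]
  }
  rownames(occ) <- NULL
  occ[required]
}
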