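test_that("matrix012 files parse with all accepted missing tokens", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample\tL1\tL2",
    "s1\t0\tNA",
    "s2\t1\t.",
    "s3\t2\t-9"
  ), path)
  g <- read_genotypes(path, "matrix012")
  expect_equal(g$samples, c("s1", "s2", "s3"))
  expect_equal(unname(g$calls[, "L1"]), 0:2)
  expect_true(all(is.na(g$calls[, "L2"])))
})

test_that("unknown genotype tokens and empty files are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tL1", "s1\t7"), path)
  expect_error(read_genotypes(path, "matrix012"), "unknown genotype token")
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(read_genotypes(empty), "empty file")
  expect_error(read_genotypes(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("VCF parsing drops multiallelic records and handles half-calls", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(path)
  expect_message(g <- read_genotypes(path), "1 non-biallelic")
  expect_equal(n_loci(g), 4)
  expect_equal(g$loci, c("snp1", "snp2", "snp4", "snp5"))
  expect_equal(unname(g$calls["samA", ]), c(0, 0, NA, 2))
  expect_equal(unname(g$calls["samB", ]), c(1, 2, 0, 1))
  expect_equal(unname(g$calls["samC", "snp2"]), NA_integer_)
})

test_that("write/read round trip preserves the matrix", {
  g <- random_gm(6, 8, seed = 4, miss = 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, "matrix012")
  expect_equal(g2$calls, g$calls)
})

test_that("individual missingness filter uses a strict inequality", {
  x <- matrix(0L, 3, 10)
  x[1, 1:8] <- NA    # 80% missing -> removed
  x[2, 1:6] <- NA    # 60% -> kept
  g <- genotype_matrix(x)
  suppressMessages(out <- filter_individuals_by_missingness(g, 0.75))
  expect_equal(out$samples, c("sample2", "sample3"))
  # exactly at the threshold is retained
  x2 <- matrix(0L, 2, 4)
  x2[1, 1:3] <- NA   # 75% missing exactly
  out2 <- filter_individuals_by_missingness(genotype_matrix(x2), 0.75)
  expect_equal(n_samples(out2), 2)
  # no missing calls: identity
  g3 <- random_gm(4, 5, seed = 1)
  expect_equal(filter_individuals_by_missingness(g3)$calls, g3$calls)
  # all removed: error
  x4 <- matrix(NA_integer_, 2, 4)
  expect_error(filter_individuals_by_missingness(genotype_matrix(x4)), "0.75")
})

test_that("locus presence filter keeps loci at the threshold (>=)", {
  x <- matrix(0L, 20, 3)
  x[2:20, 1] <- NA          # called in 1/20 = 0.05 -> dropped
  x[3:20, 2] <- NA          # called in 2/20 = 0.10 -> retained
  g <- genotype_matrix(x)
  suppressMessages(out <- filter_loci_by_presence(g, 0.10))
  expect_equal(out$loci, c("locus2", "locus3"))
  g2 <- random_gm(5, 4, seed = 2)
  expect_equal(filter_loci_by_presence(g2)$calls, g2$calls)
})

test_that("filters are idempotent and compose as documented on a 6x6 fixture", {
  x <- matrix(NA_integer_, 6, 6)
  # hand-built: rows 1-4 mostly called, row 5 has 5/6 missing (>75%),
  # row 6 fully called; after row-5 removal, locus presence changes.
  x[1, ] <- c(0L, 1L, NA, 2L, 0L, NA)
  x[2, ] <- c(1L, 1L, NA, 0L, 0L, NA)
  x[3, ] <- c(2L, 0L, NA, 1L, 1L, NA)
  x[4, ] <- c(0L, 2L, NA, 2L, 1L, NA)
  x[5, ] <- c(NA, NA, 2L, NA, NA, NA)
  x[6, ] <- c(1L, 0L, NA, 1L, 2L, 2L)
  g <- genotype_matrix(x)
  out <- suppressMessages(
    filter_loci_by_presence(filter_individuals_by_missingness(g, 0.75), 0.10))
  # oracle by hand: row 5 removed (5/6 > 0.75). Of the remaining 5 rows,
  # locus3 has 0 calls (<10%) -> dropped; locus6 has 1/5 = 20% -> kept.
  expect_equal(out$samples, paste0("sample", c(1:4, 6)))
  expect_equal(out$loci, paste0("locus", c(1, 2, 4, 5, 6)))
  # idempotence
  again <- suppressMessages(
    filter_loci_by_presence(filter_individuals_by_missingness(out, 0.75), 0.10))
  expect_equal(again$calls, out$calls)
})

test_that("metadata reader validates columns, coordinates, duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,site,lat,lon,ecoregion",
               "s1,Malibu,34.03,-118.78,coastal",
               "s2,Bad,999,-118,coastal",
               "s3,Anza,33.5,-116.6,desert"), path)
  expect_message(md <- read_metadata(path), "1 metadata row\\(s\\) rejected")
  expect_equal(md$sample, c("s1", "s3"))
  expect_equal(md$lat[1], 34.03)
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,site,lat,lon,ecoregion",
               "s1,A,34,-118,x", "s1,B,35,-117,y"), dup)
  expect_error(read_metadata(dup), "duplicate sample id")
  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,site,lat,lon", "s1,A,34,-118"), nocol)
  expect_error(read_metadata(nocol), "ecoregion")
})

test_that("occurrence reader parses years and rejects invalid rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,lat,lon",
               "1927,33.81,-116.54",
               "notayear,33.0,-116.0",
               "2016,34.5,-117.2"), path)
  expect_message(occ <- read_occurrences(path), "1 occurrence row")
  expect_equal(occ$year, c(1927L, 2016L))
})
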