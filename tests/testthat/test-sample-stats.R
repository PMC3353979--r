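test_that("the monomorphic-sample bound solves p^k = alpha", {
  b <- minCompatibleFrequency(17, 0.05)
  expect_equal(pMin(b), 0.8384, tolerance = 5e-5)
  expect_gte(pMin(b), 0.83)                      # the printed lower bound
  expect_equal(pMin(b)^17, 0.05, tolerance = 1e-12)
  # chromosome-counting variant and trivial case
  expect_equal(pMin(minCompatibleFrequency(34, 0.05)), 0.9157, tolerance = 5e-5)
  expect_equal(pMin(minCompatibleFrequency(1, 0.05)), 0.05)
  expect_error(minCompatibleFrequency(0, 0.05), "k")
  expect_error(minCompatibleFrequency(5, 0), "alpha")
  expect_error(minCompatibleFrequency(5, 1), "alpha")
})

test_that("the bound increases in k and alpha and matches a grid search", {
  ks <- c(1, 2, 5, 17, 34, 100)
  expect_true(all(diff(vapply(ks, function(k)
    pMin(minCompatibleFrequency(k, 0.05)), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(0.01, 0.05, 0.2, 0.5), function(a)
    pMin(minCompatibleFrequency(17, a)), numeric(1))) > 0))
  # brute-force grid oracle: smallest p on a fine grid with p^k >= alpha
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  for (k in c(3, 17, 34)) {
    for (a in c(0.05, 0.01)) {
      oracle <- grid[which(grid^k >= a)[1]]
      expect_lt(abs(pMin(minCompatibleFrequency(k, a)) - oracle), 1.01e-4)
    }
  }
})

test_that("the packaged prehistoric table matches its published layout", {
  tab <- casp12AncientTable()
  s <- summarizeGenotypeTable(tab)
  expect_identical(s$total, 24L)
  expect_identical(s$perSite[["SJAPL"]], 17L)
  expect_identical(s$perSite[["Longar"]], 3L)
  singles <- setdiff(names(s$perSite), c("SJAPL", "Longar"))
  expect_identical(length(singles), 4L)
  expect_true(all(s$perSite[singles] == 1L))
  expect_identical(sum(s$perSite), s$total)
  expect_identical(sum(s$perPeriod), s$total)
  expect_identical(s$genotypeCounts[["TT"]], 24L)
  f <- observedAlleleFrequency(tab, "T")
  expect_identical(f$frequency, 1)
  expect_identical(f$frequencyIndividuals, 1)
  expect_identical(f$individuals, 24L)
})

test_that("allele frequencies handle heterozygotes, missing data and edge cases", {
  mk <- function(gt) ancientGenotypeTable(data.frame(
    sample = paste0("s", seq_along(gt)), site = "x", period = "y",
    c14_bp = NA, genotype = gt, replicates = ""))
  expect_equal(observedAlleleFrequency(mk("CT"), "T")$frequency, 0.5)
  f <- observedAlleleFrequency(mk(c("CC", NA)), "T")
  expect_identical(f$frequency, 0)
  expect_identical(f$individuals, 1L)
  expect_error(observedAlleleFrequency(mk(c(NA, NA)), "T"), "missing")
  empty <- ancientGenotypeTable(data.frame(
    sample = character(), site = character(), period = character(),
    c14_bp = numeric(), genotype = character(), replicates = character()))
  s <- summarizeGenotypeTable(empty)
  expect_identical(s$total, 0L)
  expect_true(all(s$genotypeCounts == 0L))
})

test_that("table validation rejects duplicates and inconsistent replicates", {
  d <- data.frame(sample = c("a", "a"), site = "x", period = "y",
                  c14_bp = NA, genotype = "TT", replicates = "")
  expect_error(ancientGenotypeTable(d), "duplicate")
  d2 <- data.frame(sample = "a", site = "x", period = "y", c14_bp = NA,
                   genotype = "TT", replicates = "CC;CC")
  expect_error(ancientGenotypeTable(d2), "disagrees")
  d3 <- data.frame(sample = "a", site = "x", period = "y", c14_bp = NA,
                   genotype = "XX", replicates = "")
  expect_error(ancientGenotypeTable(d3), "genotypes")
})

test_that("genotype tables round-trip through TSV", {
  tab <- casp12AncientTable()
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab@data, f, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  tab2 <- readGenotypeTable(f)
  expect_equal(summarizeGenotypeTable(tab2), summarizeGenotypeTable(tab))
})
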