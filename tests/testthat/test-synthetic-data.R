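test_that("every generator is deterministic under a fixed seed", {
  sp <- syntheticSpec(seed = 99, contaminationRate = 0.2)
  expect_identical(genGenotypeTable(sp), genGenotypeTable(sp))
  c1 <- genCloneSets(sp, "mtdna")
  c2 <- genCloneSets(sp, "mtdna")
  expect_identical(lapply(c1, function(x) as.character(x@clones)),
                   lapply(c2, function(x) as.character(x@clones)))
  expect_identical(genHaplotypeSurvey(sp), genHaplotypeSurvey(sp))
  expect_identical(genDilutionSeries(sp), genDilutionSeries(sp))
  # and a different seed changes the draw
  expect_false(identical(genDilutionSeries(sp),
                         genDilutionSeries(syntheticSpec(seed = 100))))
})

test_that("genotype tables honor the layout, distribution and dropout boundaries", {
  noDrop <- genGenotypeTable(syntheticSpec(seed = 1, dropoutRate = 0))
  s <- summarizeGenotypeTable(noDrop$table)
  expect_identical(s$total, 24L)                       # published layout
  expect_identical(s$perSite[["SJAPL"]], 17L)
  expect_true(all(noDrop$table@data$genotype == "TT")) # P(TT) = 1, no dropout
  expect_identical(genotypeConcordance(
    strsplit(noDrop$table@data$replicates[1], ";")[[1]])$status,
    "authenticated")
  allDrop <- genGenotypeTable(syntheticSpec(seed = 2, dropoutRate = 1))
  expect_true(all(is.na(allDrop$table@data$genotype)))
  # genotype frequencies are recovered at scale
  big <- genGenotypeTable(syntheticSpec(seed = 3,
    siteLayout = c(s = 400L), dropoutRate = 0,
    genotypeProbs = c(CC = 0.25, CT = 0.5, TT = 0.25)))
  counts <- summarizeGenotypeTable(big$table)$genotypeCounts
  expect_lt(abs(counts[["CT"]] / 400 - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("heterozygote dropout produces false homozygotes at the expected rate", {
  g <- genGenotypeTable(syntheticSpec(seed = 4, siteLayout = c(s = 500L),
    genotypeProbs = c(CC = 0, CT = 1, TT = 0), dropoutRate = 0.3), nAssays = 1L)
  calls <- g$table@data$genotype
  # a heterozygote appears homozygous when exactly one allele drops:
  # 2 * d * (1 - d) = 0.42, split evenly between CC and TT
  obsHom <- mean(calls %in% c("CC", "TT"), na.rm = FALSE)
  propNA <- mean(is.na(calls))
  expect_lt(abs(propNA - 0.09), 3 * sqrt(0.09 * 0.91 / 500))
  expect_lt(abs(obsHom - 0.42), 3 * sqrt(0.42 * 0.58 / 500))
})

test_that("clone-set generation respects zero rates and recovers the printed rates", {
  clean <- genCloneSets(syntheticSpec(seed = 5, siteLayout = c(s = 10L),
    damageRates = list(casp12 = c("A>G" = 0), mtdna = c("A>G" = 0))), "mtdna")
  expect_true(all(vapply(clean, function(cs)
    all(as.character(cs@clones) == as.character(cs@consensus)), logical(1))))
  expect_equal(damageProfile(clean)@meanTotal, 0)
  # parameter recovery at the default per-type rates, 200 samples
  sp <- syntheticSpec(seed = 6, siteLayout = c(s = 200L))
  dpMt <- damageProfile(genCloneSets(sp, "mtdna"))
  target <- c("A>G" = 1.8, "G>A" = 2.2, "insA" = 1.5, "insG" = 0.04,
              "C>T" = 0.2, "T>C" = 0.08)
  for (ty in names(target)) {
    se <- max(sqrt(target[[ty]] / 200), 0.005)
    expect_lt(abs(dpMt@meanPerType[[ty]] - target[[ty]]), 3 * se + 0.05)
  }
  dpCasp <- damageProfile(genCloneSets(sp, "casp12"))
  expect_lt(abs(dpCasp@meanTotal - 1.8), 3 * sqrt(1.8 / 200) + 0.06)
})

test_that("impossible damage rates are rejected as specification errors", {
  sp <- syntheticSpec(seed = 7, siteLayout = c(s = 5L),
    damageRates = list(casp12 = c("N>A" = 3), mtdna = c("A>G" = 1)),
    damageModel = "fixed")
  expect_error(genCloneSets(sp, "casp12"), "no")
})

test_that("haplotype surveys plant contamination exactly as recorded", {
  none <- genHaplotypeSurvey(syntheticSpec(seed = 8, siteLayout = c(s = 30L),
                                           contaminationRate = 0))
  scr <- contaminationScreen(none$samples, none$researchers)
  expect_true(scr$passed)
  expect_identical(nrow(none$truth), 0L)
  all <- genHaplotypeSurvey(syntheticSpec(seed = 9, siteLayout = c(s = 30L),
                                          contaminationRate = 1))
  scrAll <- contaminationScreen(all$samples, all$researchers)
  expect_identical(sort(unique(scrAll$matches$sample)),
                   sort(unique(all$truth$sample)))
  expect_identical(nrow(all$truth), 30L)
  # partial contamination: the screen report equals the planted truth
  part <- genHaplotypeSurvey(syntheticSpec(seed = 10, siteLayout = c(s = 50L),
                                           contaminationRate = 0.2))
  scrPart <- contaminationScreen(part$samples, part$researchers)
  expect_setequal(do.call(paste, scrPart$matches), do.call(paste, part$truth))
  expect_gt(nrow(part$truth), 0L)
  # pool-size contract
  expect_error(genHaplotypeSurvey(syntheticSpec(seed = 11), poolSize = 5,
                                  nResearchers = 10), "poolSize")
})

test_that("dilution series reproduce the assay layout and the noiseless identity", {
  d <- genDilutionSeries(syntheticSpec(seed = 12,
    qpcrTruth = list(efficiency = 1, intercept = 38, ctSd = 0)))
  expect_identical(nrow(d), 12L)                       # 3 points x 4 replicates
  expect_identical(sort(unique(d$copies_per_ul)), c(1.4e4, 1.4e5, 1.4e6))
  cv <- suppressWarnings(fitStandardCurve(d))
  expect_equal(cv@slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(cv@rSquared, 1, tolerance = 1e-12)
  expect_error(genDilutionSeries(syntheticSpec(seed = 13), points = c(-1, 1, 10)),
               "positive")
})
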