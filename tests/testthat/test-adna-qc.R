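test_that("the damage profiler equals an independent hand count", {
  # hand-built case: one unique clone with 2 A>G and 1 C>T
  cs <- suppressWarnings(cloneSet("h1", "AACCGGTT",
    c("AACCGGTT", "GGCCGGTT", "AACTGGTT", "GGCCGGTT")))
  dp <- damageProfile(list(cs))
  ps <- dp@perSample
  expect_identical(ps[["A>G"]], 2L)
  expect_identical(ps[["C>T"]], 1L)
  expect_identical(ps$total, 3L)                  # duplicate clone counted once
  expect_equal(dp@meanTotal, 3)
  # identical clone only: all-zero profile
  z <- damageProfile(suppressWarnings(cloneSet("z", "ACGTACGT", "ACGTACGT")))
  expect_equal(z@meanTotal, 0)
  # randomized equal-length clone sets against the brute-force oracle
  for (seed in 1:5) {
    rc <- randomCloneSet(seed)
    got <- damageProfile(suppressWarnings(
      cloneSet("r", rc$consensus, rc$clones)))@perSample
    want <- oracleDamageCounts(rc$consensus, rc$clones)
    for (ty in names(want))
      expect_identical(as.numeric(got[[ty]]), as.numeric(want[[ty]]))
  }
})

test_that("single-base insertions are classified by the inserted base", {
  cs <- suppressWarnings(cloneSet("i1", "AACCGGTT",
    c("AACCGAGTT",    # insertion of A inside
      "GAACCGGTT",    # insertion of G at the start
      "AACCGGTTA")))  # insertion of A at the end
  ps <- damageProfile(list(cs))@perSample
  expect_identical(ps[["insA"]], 2L)
  expect_identical(ps[["insG"]], 1L)
  expect_identical(ps$total, 3L)
  # total mean equals the sum of per-type means by construction
  dp <- damageProfile(list(cs))
  expect_equal(dp@meanTotal, sum(dp@meanPerType))
})

test_that("unalignable clones are excluded with a warning, not an error", {
  cs <- suppressWarnings(cloneSet("u", "AACCGGTTAACCGGTT",
    c("AACCGGTTAACCGGTT", paste(rep("A", 40), collapse = ""))))
  expect_warning(dp <- damageProfile(list(cs)), "unalignable")
  expect_equal(dp@meanTotal, 0)
})

test_that("contamination screening flags exactly the investigator matches", {
  hap <- function(id, pos, ref, alt)
    data.frame(id = id, position = pos, ref = ref, alt = alt)
  res <- rbind(hap("R1", c(16024, 16100), c("A", "A"), c("G", "T")),
               hap("R2", 16300, "A", "C"))
  # sample S1 identical to R1; S2 and S3 share a haplotype matching no one
  sam <- rbind(hap("S1", c(16024, 16100), c("A", "A"), c("G", "T")),
               hap("S2", 16111, "T", "C"),
               hap("S3", 16111, "T", "C"))
  scr <- contaminationScreen(sam, res)
  expect_identical(scr$matches$sample, "S1")
  expect_identical(scr$matches$researcher, "R1")
  expect_false(scr$passed)
  expect_identical(scr$sharedSampleHaplotypes, list(c("S2", "S3")))
  # all-distinct haplotypes pass
  clean <- contaminationScreen(hap("S9", 16050, "G", "A"), res)
  expect_true(clean$passed)
  expect_identical(nrow(clean$matches), 0L)
  # malformed variants are rejected
  expect_error(contaminationScreen(hap("S1", 15000, "A", "G"), res), "positions")
  expect_error(contaminationScreen(
    rbind(hap("S1", 16050, "A", "G"), hap("S1", 16050, "A", "T")), res),
    "duplicate")
})

test_that("replicate concordance follows the two-assay authentication rule", {
  expect_identical(genotypeConcordance(c("TT", "TT")),
                   list(status = "authenticated", genotype = "TT"))
  expect_identical(genotypeConcordance(c("TT", NA))$status, "unconfirmed")
  expect_identical(genotypeConcordance(c("CT", "TT"))$status, "discordant")
  expect_identical(genotypeConcordance(c("TT", "TT", "TT", NA))$status,
                   "authenticated")
  expect_error(genotypeConcordance(character()), "at least one")
  # order invariance
  calls <- c("TT", NA, "CT", "TT")
  for (i in 1:5) {
    perm <- withr::with_seed(i, sample(calls))
    expect_identical(genotypeConcordance(perm)$status,
                     genotypeConcordance(calls)$status)
  }
})

test_that("the clone majority check passes on strict majorities and fails ties", {
  mk <- function(n_match, n_total) suppressWarnings(cloneSet("m", "ACGT",
    c(rep("ACGT", n_match), rep("AGGT", n_total - n_match))))
  r1 <- cloneMajorityCheck(mk(10, 10), 2)
  expect_true(r1$pass)
  expect_equal(r1$majorityFraction, 1)
  r2 <- cloneMajorityCheck(mk(6, 10), 2)
  expect_true(r2$pass)
  expect_equal(r2$majorityFraction, 0.6)
  r3 <- cloneMajorityCheck(mk(5, 10), 2)
  expect_false(r3$pass)
  expect_true(r3$tie)
  expect_error(cloneMajorityCheck(mk(2, 2), 1), "at least 3")
  expect_error(cloneMajorityCheck(mk(3, 3), 99), "position")
})

test_that("noiseless standard curves are recovered exactly", {
  s <- expand.grid(replicate = 1:4, copies_per_ul = c(1.4e4, 1.4e5, 1.4e6))
  s$ct <- 38 - log10(s$copies_per_ul) / log10(2)   # perfect doubling
  cv <- suppressWarnings(fitStandardCurve(s))
  expect_equal(cv@slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(cv@efficiency, 1, tolerance = 1e-9)
  expect_equal(cv@rSquared, 1, tolerance = 1e-9)
  # inversion identities
  expect_equal(quantifyExtract(cv@intercept, cv), 1, tolerance = 1e-9)
  expect_equal(quantifyExtract(predictCt(cv, 1.4e5), cv), 1.4e5,
               tolerance = 1e-9)
  mid <- s$ct[s$copies_per_ul == 1.4e5][1]
  expect_equal(quantifyExtract(mid, cv), 1.4e5, tolerance = 1e-6)
  # contract errors
  expect_error(fitStandardCurve(s[s$copies_per_ul < 1e5, ]), "3 distinct")
  expect_error(fitStandardCurve(data.frame(copies_per_ul = 1, ct = 1)),
               "3 distinct|positive")
})

test_that("efficiency estimates recover the generating truth across noise", {
  effs <- vapply(1:40, function(i) {
    sp <- syntheticSpec(seed = 1000 + i,
                        qpcrTruth = list(efficiency = 0.9, intercept = 40,
                                         ctSd = 0.1))
    fitStandardCurve(genDilutionSeries(sp))@efficiency
  }, numeric(1))
  se <- sd(effs) / sqrt(length(effs))
  expect_lt(abs(mean(effs) - 0.9), 3 * se + 0.01)
})

test_that("clone sets round-trip through FASTA", {
  cs <- list(suppressWarnings(cloneSet("a", "ACGTACGT",
                                       c("ACGTACGT", "ACTTACGT"))),
             suppressWarnings(cloneSet("b", "GGCCAATT", "GGCCAATT")))
  f <- withr::local_tempfile(fileext = ".fasta")
  writeCloneSets(cs, f)
  back <- suppressWarnings(readCloneSets(f))   # < 10 clones per sample
  expect_identical(length(back), 2L)
  expect_identical(as.character(back[[1]]@consensus), "ACGTACGT")
  expect_identical(unname(as.character(back[[1]]@clones)),
                   c("ACGTACGT", "ACTTACGT"))
  expect_equal(damageProfile(back)@meanTotal, damageProfile(cs)@meanTotal)
})
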