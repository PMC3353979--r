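test_that("the packaged scaled Out-of-Africa fixture reproduces the derived sizes", {
  m <- ooaScaledModel()
  expect_identical(m@populations, c("AFR", "EUR", "ASN"))
  expect_identical(m@N0, 500L)
  expect_equal(m@tEnd, 0.607)
  # African reduction, re-expansion, growth: 500 * 0.1 * 10 * 1.68202 = 841
  expect_identical(populationSizeAt(m, "AFR", 0.005), 841L)
  expect_identical(populationSizeAt(m, "AFR", 0.6), 841L)     # constant after
  # European founding bottleneck: 841 * 0.170737565
  expect_identical(populationSizeAt(m, "EUR", 0.211074), 144L)
  # Asian split: EUR reduced to 104, ASN founded at 23, before growth
  expect_identical(populationSizeAt(m, "EUR", 0.534772), 104L)
  expect_identical(populationSizeAt(m, "ASN", 0.534772), 23L)
  # exponential growth to the end of the timeline
  expect_identical(populationSizeAt(m, "EUR", 0.607), 1211L)
  expect_gt(populationSizeAt(m, "ASN", 0.607), 1000L)
})

test_that("scaled times convert to generation indices by rounding", {
  m <- ooaScaledModel()
  expect_identical(scaledToGenerations(m, 0.607), 607L)
  expect_identical(scaledToGenerations(m, 0), 0L)
  expect_identical(scaledToGenerations(m, 0.211074), 211L)
  expect_error(scaledToGenerations(m, 0.7), "tEnd")
  # monotone in t
  ts <- seq(0, 0.607, length.out = 50)
  expect_true(!is.unsorted(scaledToGenerations(m, ts)))
  # the record point sits about 7,000 years before present under the
  # adopted scaling (size ratio kappa enters year conversions only)
  expect_equal(scaledToYearsBP(m, m@recordTimes[["7kYBP"]]), 7000,
               tolerance = 0.1)
})

test_that("a minimal configuration yields a constant-size model", {
  m <- constantModel(500, 0.1)
  expect_identical(populationSizeAt(m, "P", 0), 500L)
  expect_identical(populationSizeAt(m, "P", 0.1), 500L)
  expect_identical(nrow(m@events), 0L)
})

test_that("invalid configurations are rejected with informative errors", {
  base <- list(N0 = 500, t_end = 0.1, populations = list("A", "B"))
  expect_error(demographicModel(list(N0 = 500, populations = list("A"))),
               "missing field")
  bad <- base
  bad$events <- list(list(time = 0.2, kind = "size_change", pop = "A", value = 2))
  expect_error(demographicModel(bad), "beyond tEnd")
  bad <- base
  bad$events <- list(list(time = 0.01, kind = "size_change", pop = "Z", value = 2))
  expect_error(demographicModel(bad), "unknown population")
  bad <- base
  bad$events <- list(list(time = 0.05, kind = "size_change", pop = "A", value = 2),
                     list(time = 0.01, kind = "size_change", pop = "A", value = 2))
  expect_error(demographicModel(bad), "sorted")
  bad <- base
  bad$events <- list(list(time = 0.01, kind = "migration_change", pop = "A",
                          pop2 = "B", value = -1))
  expect_error(demographicModel(bad), "migration")
  # event acting on a split daughter before it exists
  bad <- base
  bad$events <- list(list(time = 0.01, kind = "size_change", pop = "B", value = 2),
                     list(time = 0.05, kind = "split", pop = "A", pop2 = "B"))
  expect_error(demographicModel(bad), "before it is founded")
})

test_that("models serialize to YAML and reload identically", {
  m <- ooaScaledModel()
  f <- withr::local_tempfile(fileext = ".yaml")
  writeDemographicModel(m, f)
  expect_equal(loadDemographicModel(f), m)
})

test_that("migrant-copy payloads imply symmetric per-generation fractions", {
  # the payloads into each side of a pair differ, but dividing by the
  # receiving population's 2N recovers the same per-generation fraction
  m <- ooaScaledModel()
  mig <- migrationRatesAt(m, 0.3)
  expect_equal(mig["AFR", "EUR"], mig["EUR", "AFR"], tolerance = 0.02)
  mig2 <- migrationRatesAt(m, 0.54)
  expect_equal(mig2["EUR", "ASN"], mig2["ASN", "EUR"], tolerance = 0.05)
  expect_equal(mig2["AFR", "ASN"], mig2["ASN", "AFR"], tolerance = 0.05)
  # migration into Europe and Asia from Africa is shut off late in the
  # timeline
  mig3 <- migrationRatesAt(m, 0.56)
  expect_identical(mig3["EUR", "AFR"], 0)
  expect_identical(mig3["AFR", "EUR"], 0)
  expect_gt(mig3["EUR", "ASN"], 0)
})
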