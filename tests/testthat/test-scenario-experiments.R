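test_that("conditioning on the same criterion gives probability one", {
  m <- ooaScaledModel()
  est <- estimateConditionalProbability(m, neutralScheme(), seed = 5,
    acceptanceWindow = c(0.3, 0.5), successThreshold = 0.3,
    acceptancePop = "AFR", successPop = "AFR",
    nAcceptedTarget = 20L, batchSize = 5000L)
  expect_identical(est@pHat, 1)
  expect_identical(est@kSuccess, est@nAccepted)
})

test_that("raising the success threshold never increases the estimate", {
  m <- ooaScaledModel()
  run <- function(thr) estimateConditionalProbability(m, neutralScheme(),
    seed = 99, successThreshold = thr, nAcceptedTarget = 60L,
    batchSize = 10000L)
  ps <- vapply(c(0.5, 0.8, 0.95, 0.999), function(t) run(t)@pHat, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("estimates from independent seeds agree within their joint precision", {
  m <- ooaScaledModel()
  e1 <- estimateConditionalProbability(m, neutralScheme(), seed = 1,
    nAcceptedTarget = 300L, batchSize = 15000L)
  e2 <- estimateConditionalProbability(m, neutralScheme(), seed = 2,
    nAcceptedTarget = 300L, batchSize = 15000L)
  hw <- (e1@ci95[2] - e1@ci95[1]) / 2 + (e2@ci95[2] - e2@ci95[1]) / 2
  expect_lt(abs(e1@pHat - e2@pHat), hw)
  # accepted replicates all sit inside the window
  expect_true(all(e1@accepted$freq_AFR >= 0.3 & e1@accepted$freq_AFR <= 0.5))
})

test_that("an empty acceptance window fails with an informative cap message", {
  m <- constantModel(50, 0.02)
  expect_error(
    estimateConditionalProbability(m, neutralScheme(), seed = 3,
      acceptanceWindow = c(0.999, 1), successThreshold = 0.5,
      acceptancePop = "P", successPop = "P", originWindow = c(0.001, 0.003),
      nAcceptedTarget = 10L, batchSize = 2000L, rawCap = 4000),
    "cap")
})

test_that("the record-time summary conditions correctly", {
  m <- ooaScaledModel()
  est <- estimateConditionalProbability(m, neutralScheme(), seed = 17,
    nAcceptedTarget = 150L, batchSize = 15000L)
  e7 <- expectedFrequencyAtTime(est, record = "EUR_at_7kYBP")
  expect_identical(e7$n, as.integer(est@nAccepted))
  expect_true(e7$ci95[1] <= e7$mean && e7$mean <= e7$ci95[2])
  # conditioning tautology: the mean accepted African final frequency lies
  # inside the acceptance window
  expect_true(mean(est@accepted$freq_AFR) >= 0.3 &&
              mean(est@accepted$freq_AFR) <= 0.5)
  expect_error(expectedFrequencyAtTime(est, record = "nope"), "record")
})

test_that("the two-step scenario delegates to the deterministic solver", {
  genic <- fitnessScheme(0.01, parameterization = "genic")
  expect_identical(twoStepNeolithic(0.995, genic, target = 0.99)$generations, 0L)
  ts <- twoStepNeolithic(0.4, genic, target = 0.99)
  expect_identical(ts$generations, 503L)
  expect_s4_class(ts$trajectory, "Trajectory")
  expect_gte(ts$trajectory@frequencies[504], 0.99)
  # under the literal viability scheme the same transition takes far longer
  tv <- twoStepNeolithic(0.4, fitnessScheme(0.01, 0.11), target = 0.99)
  expect_gt(tv$generations, 2000L)
})

test_that("sweep-time sensitivity reports all parameterizations", {
  s <- sweepTimeSensitivity(0.4, 0.8, 0.01, 0.11)
  expect_setequal(s$parameterization,
                  c("viability", "genic", "additive", "additive_closed_form"))
  expect_identical(s$generations[s$parameterization == "viability"], 457)
  expect_identical(s$generations[s$parameterization == "genic"], 181)
  closed <- s$generations[s$parameterization == "additive_closed_form"]
  additive <- s$generations[s$parameterization == "additive"]
  expect_lt(abs(additive - closed) / closed, 0.05)
})
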