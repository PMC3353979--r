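test_that("recursion has fixed points at 0 and 1 and is the identity when neutral", {
  schemes <- list(fitnessScheme(0.01, 0.11),
                  fitnessScheme(0.3, 0),
                  fitnessScheme(0.05, 1),
                  fitnessScheme(0.02, parameterization = "genic"),
                  fitnessScheme(0.01, parameterization = "additive"),
                  neutralScheme())
  ps <- withr::with_seed(1, runif(25))
  for (sc in schemes) {
    expect_identical(stepFrequency(0, sc), 0)
    expect_identical(stepFrequency(1, sc), 1)
  }
  expect_equal(stepFrequency(ps, neutralScheme()), ps, tolerance = 1e-15)
})

test_that("one selection step reproduces the direct evaluation of the recursion", {
  # frozen high-precision evaluation of p(p wAA + q wAa)/wbar at p = 0.4,
  # s = 0.01, h = 0.11
  expect_equal(stepFrequency(0.4, fitnessScheme(0.01, 0.11)), 0.4013930,
               tolerance = 1e-6)
  # algebraic identity p' * wbar = p (p wAA + q wAa), at random points
  ps <- withr::with_seed(7, runif(50))
  for (sc in list(fitnessScheme(0.02, 0.3), fitnessScheme(0.3, 0.9))) {
    w <- viabilities(sc)
    q <- 1 - ps
    wbar <- ps^2 * w[["wAA"]] + 2 * ps * q * w[["wAa"]] + q^2 * w[["waa"]]
    expect_equal(stepFrequency(ps, sc) * wbar,
                 ps * (ps * w[["wAA"]] + q * w[["wAa"]]), tolerance = 1e-14)
  }
})

test_that("trajectories are monotone, bounded and anchored at p0", {
  tr <- simulateTrajectory(0.05, fitnessScheme(0.02, 0.11), 500)
  d <- as.data.frame(tr)
  expect_identical(nrow(d), 501L)
  expect_identical(d$frequency[1], 0.05)
  expect_true(all(diff(d$frequency) > 0))         # strictly increasing
  expect_true(all(d$frequency >= 0 & d$frequency <= 1))
  # boundary and neutral trajectories are constant
  expect_true(all(simulateTrajectory(1, fitnessScheme(0.01, 0.11), 100)@frequencies == 1))
  expect_true(all(simulateTrajectory(0.4, neutralScheme(), 200)@frequencies == 0.4))
})

test_that("time to target matches the frozen recursion values per parameterization", {
  # literal viability scheme with the nominal (s = 1%, h = 0.11)
  expect_identical(generationsToReach(0.4, 0.8, fitnessScheme(0.01, 0.11)), 457L)
  # per-allele-copy (genic) variant
  genic <- fitnessScheme(0.01, parameterization = "genic")
  expect_identical(generationsToReach(0.4, 0.8, genic), 181L)
  expect_identical(generationsToReach(0.4, 0.99, genic), 503L)
  # contract cases
  expect_identical(generationsToReach(0.4, 0.4, fitnessScheme(0.01, 0.11)), 0L)
  expect_identical(generationsToReach(0.5, 0.4, fitnessScheme(0.01, 0.11)), 0L)
  expect_identical(generationsToReach(0.4, 0.8, neutralScheme(), 500L), NA_integer_)
})

test_that("semidominant recursion agrees with the closed-form sweep time within 5%", {
  cases <- expand.grid(s = c(0.002, 0.005, 0.01), p1 = c(0.1, 0.4),
                       p2 = c(0.8, 0.95))
  for (i in seq_len(nrow(cases))) {
    s <- cases$s[i]
    tClosed <- additiveSweepTime(cases$p1[i], cases$p2[i], s)
    tRec <- generationsToReach(cases$p1[i], cases$p2[i],
                               fitnessScheme(s, parameterization = "additive"),
                               maxGenerations = 50000L)
    expect_lt(abs(tRec - tClosed) / tClosed, 0.05)
  }
  # the 358-generation landmark: iterating that many generations lands at 0.8
  tr <- simulateTrajectory(0.4, fitnessScheme(0.01, 0.5), 358)
  expect_equal(tr@frequencies[359], 0.8, tolerance = 0.05)
})

test_that("domain errors are raised for invalid frequencies and counts", {
  sc <- fitnessScheme(0.01, 0.11)
  expect_error(stepFrequency(-0.1, sc), "0, 1")
  expect_error(stepFrequency(1.1, sc), "0, 1")
  expect_error(simulateTrajectory(0.4, sc, -1), ">= 0")
  expect_error(fitnessScheme(-0.1), "s")
  expect_error(fitnessScheme(0.01, 2), "h")
})
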