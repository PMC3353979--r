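## Deterministic single-locus viability-selection recursion and
## time-to-frequency solvers.

#' Construct a fitness scheme
#'
#' @param s selection coefficient, in \code{[0, 1)}.
#' @param h heterozygous effect, in \code{[0, 1]}; ignored (forced to 0.5)
#'   for \code{parameterization = "additive"}, and irrelevant under
#'   \code{"genic"}.
#' @param parameterization \code{"viability"} (default), \code{"genic"} or
#'   \code{"additive"}; see [FitnessScheme-class].
#' @return A [FitnessScheme-class] object.
#' @examples
#' fitnessScheme(s = 0.01, h = 0.11)
#' viabilities(fitnessScheme(s = 0.01, parameterization = "genic"))
#' @export
fitnessScheme <- function(s = 0, h = 0.5,
                          parameterization = c("viability", "genic", "additive")) {
  parameterization <- match.arg(parameterization)
  if (parameterization == "additive") h <- 0.5
  new("FitnessScheme", s = as.numeric(s), h = as.numeric(h),
      parameterization = parameterization)
}

#' Neutral fitness scheme
#'
#' @return A neutral [FitnessScheme-class] (\code{s = 0}).
#' @export
neutralScheme <- function() fitnessScheme(s = 0)

.viabilities <- function(scheme) {
  s <- scheme@s
  switch(scheme@parameterization,
    genic = c(wAA = (1 + s)^2, wAa = 1 + s, waa = 1),
    ## viability and additive share the w = (1, 1-hs, 1-s) form
    c(wAA = 1, wAa = 1 - scheme@h * s, waa = 1 - s))
}

#' Genotype viabilities of a fitness scheme
#'
#' @param scheme a [FitnessScheme-class].
#' @return Named numeric vector \code{c(wAA, wAa, waa)}.
#' @export
viabilities <- function(scheme) {
  stopifnot(is(scheme, "FitnessScheme"))
  .viabilities(scheme)
}

#' @describeIn fitnessScheme selection coefficient accessor
#' @param scheme a [FitnessScheme-class].
#' @export
selectionCoef <- function(scheme) scheme@s

#' @describeIn fitnessScheme heterozygous-effect accessor
#' @export
heterozygousEffect <- function(scheme) scheme@h

setMethod("show", "FitnessScheme", function(object) {
  w <- .viabilities(object)
  cat(sprintf("FitnessScheme: s = %g, h = %g (%s)\n", object@s, object@h,
              object@parameterization))
  cat(sprintf("  viabilities: wAA = %g, wAa = %g, waa = %g\n", w[1], w[2], w[3]))
})

## core recursion, vectorized over p; w = c(wAA, wAa, waa)
.stepFreq <- function(p, w) {
  q <- 1 - p
  wbar <- p * p * w[[1L]] + 2 * p * q * w[[2L]] + q * q * w[[3L]]
  p * (p * w[[1L]] + q * w[[2L]]) / wbar
}

#' One generation of deterministic viability selection
#'
#' Applies the standard single-locus recursion
#' \deqn{p' = p (p w_{AA} + q w_{Aa}) / \bar w, \quad
#'       \bar w = p^2 w_{AA} + 2 p q w_{Aa} + q^2 w_{aa}}
#' with \eqn{q = 1 - p}, under constant population size.
#'
#' @param p current frequency of the derived allele, in \code{[0, 1]}
#'   (vectorized).
#' @param scheme a [FitnessScheme-class].
#' @return The frequency after one generation of selection.
#' @examples
#' stepFrequency(0.4, fitnessScheme(s = 0.01, h = 0.11))
#' @export
stepFrequency <- function(p, scheme) {
  stopifnot(is(scheme, "FitnessScheme"))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("'p' must lie in [0, 1]")
  .stepFreq(p, .viabilities(scheme))
}

#' Iterate the selection recursion over generations
#'
#' @param p0 initial frequency.
#' @param scheme a [FitnessScheme-class].
#' @param nGenerations number of generations to iterate (>= 0).
#' @return A [Trajectory-class] with \code{nGenerations + 1} points.
#' @examples
#' tr <- simulateTrajectory(0.4, fitnessScheme(s = 0.01, h = 0.5), 358)
#' tail(as.data.frame(tr))
#' @export
simulateTrajectory <- function(p0, scheme, nGenerations) {
  stopifnot(is(scheme, "FitnessScheme"))
  if (is.na(p0) || p0 < 0 || p0 > 1) stop("'p0' must lie in [0, 1]")
  nGenerations <- as.integer(nGenerations)
  if (is.na(nGenerations) || nGenerations < 0L)
    stop("'nGenerations' must be >= 0")
  w <- .viabilities(scheme)
  freqs <- numeric(nGenerations + 1L)
  freqs[1L] <- p <- p0
  for (t in seq_len(nGenerations)) {
    p <- .stepFreq(p, w)
    freqs[t + 1L] <- p
  }
  new("Trajectory", generations = 0:nGenerations, frequencies = freqs,
      scheme = scheme, p0 = p0)
}

#' Generations needed to reach a target frequency
#'
#' Iterates the deterministic recursion from \code{p0} and returns the first
#' generation at which the frequency is at least \code{target} (closed
#' comparison; the recursion never hits a target exactly), or \code{NA} if
#' the target is not attained within \code{maxGenerations}.
#'
#' @param p0 initial frequency.
#' @param target target frequency.
#' @param scheme a [FitnessScheme-class].
#' @param maxGenerations convergence guard (default 10000).
#' @return Integer generation count, or \code{NA_integer_} if not reached.
#' @examples
#' generationsToReach(0.4, 0.8, fitnessScheme(s = 0.01, h = 0.5))
#' generationsToReach(0.4, 0.8, fitnessScheme(s = 0.01, parameterization = "genic"))
#' @export
generationsToReach <- function(p0, target, scheme, maxGenerations = 10000L) {
  stopifnot(is(scheme, "FitnessScheme"))
  if (is.na(p0) || p0 < 0 || p0 > 1) stop("'p0' must lie in [0, 1]")
  if (is.na(target) || target < 0 || target > 1) stop("'target' must lie in [0, 1]")
  maxGenerations <- as.integer(maxGenerations)
  if (maxGenerations < 0L) stop("'maxGenerations' must be >= 0")
  if (p0 >= target) return(0L)
  w <- .viabilities(scheme)
  p <- p0
  for (t in seq_len(maxGenerations)) {
    p <- .stepFreq(p, w)
    if (p >= target) return(t)
  }
  NA_integer_
}

#' Closed-form sweep time under additive (semidominant) selection
#'
#' The logistic approximation \eqn{t = (2/s) \ln(p_2 q_1 / (p_1 q_2))} for a
#' semidominant allele with homozygote advantage \code{s} (so the per-copy
#' advantage is \code{s/2}); used as the independent check of the recursion.
#'
#' @param p1,p2 start and end frequencies in (0, 1).
#' @param s selection coefficient.
#' @return Time in generations (real-valued).
#' @export
additiveSweepTime <- function(p1, p2, s) {
  stopifnot(s > 0, p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  (2 / s) * log(p2 * (1 - p1) / (p1 * (1 - p2)))
}

setMethod("show", "Trajectory", function(object) {
  n <- length(object@frequencies)
  cat(sprintf("Trajectory: %d generations, p0 = %g -> p_final = %g\n",
              n - 1L, object@p0, object@frequencies[n]))
  show(object@scheme)
})

#' @export
#' @method as.data.frame Trajectory
as.data.frame.Trajectory <- function(x, ...) {
  data.frame(generation = x@generations, frequency = x@frequencies)
}

setMethod("as.data.frame", "Trajectory", as.data.frame.Trajectory)

setMethod("length", "Trajectory", function(x) length(x@frequencies))
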