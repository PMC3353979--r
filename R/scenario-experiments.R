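## The three simulation experiments: neutral conditional probability,
## selected-since-origin conditional probability, and the two-step Neolithic
## scenario built on the deterministic recursion.

#' Conditional probability of high European frequency
#'
#' Rejection sampling: forward replicates are run in batches until
#' \code{nAcceptedTarget} of them end with the frequency in
#' \code{acceptancePop} inside \code{acceptanceWindow}; the estimate is the
#' fraction of accepted replicates whose final frequency in
#' \code{successPop} is at least \code{successThreshold}. Replicates whose
#' mutation is lost are raw failures (frequency 0 never falls in the
#' window). Batch seeds are drawn lazily from the master seed, so the result
#' is deterministic given \code{(seed, batchSize)}.
#'
#' @param model a [DemographicModel-class].
#' @param scheme a [FitnessScheme-class].
#' @param seed master integer seed.
#' @param acceptanceWindow closed frequency interval applied to
#'   \code{acceptancePop} at the final generation (default \code{c(0.3, 0.5)}).
#' @param successThreshold success frequency on \code{successPop} at the
#'   final generation (default 0.95).
#' @param nAcceptedTarget accepted replicates to collect (default 2000).
#' @param acceptancePop,successPop population labels (defaults AFR / EUR).
#' @param originWindow scaled-time origin window (default \code{c(0.001, 0.003)}).
#' @param batchSize replicates per batch (default 25000).
#' @param rawCap maximum raw replicates before giving up (default 5e6).
#' @param sampleChromosomes if non-NULL, evaluate the acceptance and success
#'   criteria on a binomial draw of this many chromosomes from each final
#'   population frequency instead of the population frequency itself
#'   (mirrors scoring on a sequenced sample).
#' @param scenario free-text tag stored in the result.
#' @return A [ConditionalEstimate-class]; its \code{accepted} slot keeps the
#'   accepted replicate rows for downstream summaries.
#' @examples
#' \dontrun{
#' est <- estimateConditionalProbability(ooaScaledModel(), neutralScheme(),
#'                                       seed = 1, nAcceptedTarget = 2000)
#' est
#' }
#' @export
estimateConditionalProbability <- function(model, scheme, seed,
                                           acceptanceWindow = c(0.3, 0.5),
                                           successThreshold = 0.95,
                                           nAcceptedTarget = 2000L,
                                           acceptancePop = "AFR",
                                           successPop = "EUR",
                                           originWindow = c(0.001, 0.003),
                                           batchSize = 25000L,
                                           rawCap = 5e6,
                                           sampleChromosomes = NULL,
                                           scenario = NA_character_) {
  stopifnot(is(model, "DemographicModel"), is(scheme, "FitnessScheme"))
  if (length(acceptanceWindow) != 2L || acceptanceWindow[1] > acceptanceWindow[2] ||
      acceptanceWindow[1] < 0 || acceptanceWindow[2] > 1)
    stop("'acceptanceWindow' must be an interval within [0, 1]")
  if (successThreshold < 0 || successThreshold > 1)
    stop("'successThreshold' must lie in [0, 1]")
  if (nAcceptedTarget < 1) stop("'nAcceptedTarget' must be >= 1")
  accCol <- paste0("freq_", acceptancePop)
  sucCol <- paste0("freq_", successPop)
  plan <- .compilePlan(model)
  w <- .viabilities(scheme)
  originIdx <- match(model@populations[1L], model@populations)
  nRaw <- 0
  keep <- list()
  nAcc <- 0
  withr::with_seed(as.integer(seed), {
    while (nAcc < nAcceptedTarget && nRaw < rawCap) {
      batchSeed <- sample.int(.Machine$integer.max - 1L, 1L)
      batch <- withr::with_seed(batchSeed,
        .simulateBatch(plan, w, as.integer(batchSize), originIdx,
                       originWindow, model@N0))
      nRaw <- nRaw + nrow(batch)
      av <- batch[[accCol]]
      sv <- batch[[sucCol]]
      if (!is.null(sampleChromosomes)) {
        n <- as.integer(sampleChromosomes)
        av <- stats::rbinom(length(av), n, av) / n
        sv <- stats::rbinom(length(sv), n, sv) / n
      }
      batch$.acc <- av
      batch$.suc <- sv
      acc <- batch[av >= acceptanceWindow[1] & av <= acceptanceWindow[2], ,
                   drop = FALSE]
      if (nrow(acc)) {
        keep[[length(keep) + 1L]] <- acc
        nAcc <- nAcc + nrow(acc)
      }
    }
  })
  if (nAcc == 0)
    stop(sprintf(paste0("no replicate entered the acceptance window [%g, %g] ",
                        "within the raw-replicate cap of %g"),
                 acceptanceWindow[1], acceptanceWindow[2], rawCap))
  if (nAcc < nAcceptedTarget)
    warning(sprintf("raw cap reached with only %d of %d accepted replicates",
                    nAcc, as.integer(nAcceptedTarget)))
  accepted <- do.call(rbind, keep)
  k <- sum(accepted$.suc >= successThreshold)
  ci <- as.numeric(stats::binom.test(k, nAcc)$conf.int)
  new("ConditionalEstimate",
      nRaw = nRaw, nAccepted = as.numeric(nAcc), kSuccess = as.numeric(k),
      pHat = k / nAcc, ci95 = ci, scenario = scenario,
      seed = as.numeric(seed), accepted = accepted)
}

setMethod("show", "ConditionalEstimate", function(object) {
  cat(sprintf("ConditionalEstimate%s\n",
              if (is.na(object@scenario)) "" else paste0(" [", object@scenario, "]")))
  cat(sprintf("  accepted %d / %g raw replicates; successes %d\n",
              as.integer(object@nAccepted), object@nRaw,
              as.integer(object@kSuccess)))
  cat(sprintf("  p_hat = %.4f  (95%% CI %.4f-%.4f)  seed %g\n",
              object@pHat, object@ci95[1], object@ci95[2], object@seed))
  if (object@nAccepted < 100)
    cat("  note: few accepted replicates; the interval is wide\n")
})

#' Mean recorded frequency over accepted replicates
#'
#' Summarizes a record-time frequency (by default the European frequency at
#' the 7,000-years-before-present record point) over the replicates accepted
#' by a conditional experiment, with a bootstrap confidence interval. Either
#' pass an existing [ConditionalEstimate-class] or the arguments needed to
#' run one.
#'
#' @param x a [ConditionalEstimate-class], or a [DemographicModel-class]
#'   (in which case the remaining arguments are forwarded to
#'   [estimateConditionalProbability()]).
#' @param record record column suffix, e.g. \code{"EUR_at_7kYBP"}.
#' @param nBoot bootstrap resamples for the CI (default 2000).
#' @param ... forwarded to [estimateConditionalProbability()] when \code{x}
#'   is a model.
#' @return List with \code{mean}, \code{ci95}, \code{n}, and
#'   \code{meanSurviving} (the same mean over accepted replicates with the
#'   record present, identical here since records exist for every
#'   replicate — both reported for transparency).
#' @export
expectedFrequencyAtTime <- function(x, record = "EUR_at_7kYBP",
                                    nBoot = 2000L, ...) {
  est <- if (is(x, "ConditionalEstimate")) x
         else estimateConditionalProbability(x, ...)
  col <- paste0("freq_", record)
  if (!col %in% names(est@accepted))
    stop("no such record column in the accepted replicates: ", col)
  v <- est@accepted[[col]]
  mu <- mean(v)
  ci <- withr::with_seed(as.integer(est@seed) + 1L, {
    bm <- vapply(seq_len(nBoot), function(i)
      mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
    stats::quantile(bm, c(0.025, 0.975), names = FALSE)
  })
  list(mean = mu, ci95 = ci, n = length(v),
       meanSurviving = mean(v[rowSums(est@accepted[grep("^freq_",
         names(est@accepted), value = TRUE)]) > 0]))
}

#' Two-step Neolithic sweep scenario
#'
#' The second step of the standing-variation workaround: starting from the
#' mid-Holocene European frequency estimated under neutrality (default 0.4),
#' how many generations of deterministic selection are needed to exceed the
#' present-day target (default 0.99), assuming population sizes already large
#' enough for drift to be negligible.
#'
#' @param pStart starting frequency (default 0.4).
#' @param scheme a [FitnessScheme-class] for the post-Neolithic regime.
#' @param target target frequency (default 0.99).
#' @param maxGenerations guard for [generationsToReach()].
#' @return List with \code{generations} (integer or \code{NA} if not
#'   reached), \code{years} (under a 25-year generation), and
#'   \code{trajectory} (a [Trajectory-class] up to the attained generation or
#'   the guard).
#' @export
twoStepNeolithic <- function(pStart = 0.4, scheme, target = 0.99,
                             maxGenerations = 10000L) {
  stopifnot(is(scheme, "FitnessScheme"))
  gen <- generationsToReach(pStart, target, scheme, maxGenerations)
  n <- if (is.na(gen)) as.integer(maxGenerations) else gen
  list(generations = gen,
       years = if (is.na(gen)) NA_real_ else gen * 25,
       trajectory = simulateTrajectory(pStart, scheme, n))
}

#' Sensitivity of deterministic sweep times to the fitness parameterization
#'
#' Computes [generationsToReach()] for a start/target pair under the three
#' parameterizations of the same nominal \code{(s, h)}: the literal viability
#' scheme, the genic (per-allele-copy) scheme and the additive
#' (semidominant) scheme, alongside the closed-form additive approximation.
#'
#' @param p0 starting frequency.
#' @param target target frequency.
#' @param s selection coefficient.
#' @param h heterozygous effect for the viability scheme.
#' @param maxGenerations guard.
#' @return data.frame with columns \code{parameterization} and
#'   \code{generations}; the closed form appears as
#'   \code{"additive_closed_form"}.
#' @export
sweepTimeSensitivity <- function(p0, target, s, h = 0.11,
                                 maxGenerations = 10000L) {
  rows <- list(
    viability = generationsToReach(p0, target, fitnessScheme(s, h), maxGenerations),
    genic = generationsToReach(p0, target,
      fitnessScheme(s, parameterization = "genic"), maxGenerations),
    additive = generationsToReach(p0, target,
      fitnessScheme(s, parameterization = "additive"), maxGenerations),
    additive_closed_form = additiveSweepTime(p0, min(target, 1 - 1e-12), s))
  data.frame(parameterization = names(rows),
             generations = as.numeric(unlist(rows)),
             row.names = NULL)
}
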