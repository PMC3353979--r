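#' @importClassesFrom Biostrings DNAString DNAStringSet
NULL

## ---------------------------------------------------------------------------
## FitnessScheme
## ---------------------------------------------------------------------------

#' Single-locus fitness scheme
#'
#' Holds the selection coefficient \code{s} and heterozygous effect \code{h}
#' of a single biallelic locus with derived advantageous allele A, together
#' with the parameterization used to derive genotype viabilities:
#' \describe{
#'   \item{\code{viability} (default)}{\eqn{w_{AA}=1}, \eqn{w_{Aa}=1-hs},
#'     \eqn{w_{aa}=1-s}.}
#'   \item{\code{genic}}{per-allele-copy fitness 1 and \eqn{1+s}, i.e.
#'     \eqn{w_{AA}=(1+s)^2}, \eqn{w_{Aa}=1+s}, \eqn{w_{aa}=1}.}
#'   \item{\code{additive}}{the viability scheme with \code{h} forced to 0.5
#'     (semidominance), for which the classic closed-form sweep-time
#'     approximation applies.}
#' }
#'
#' @slot s selection coefficient, in \code{[0, 1)}.
#' @slot h heterozygous (dominance) effect, in \code{[0, 1]}.
#' @slot parameterization one of \code{"viability"}, \code{"genic"},
#'   \code{"additive"}.
#' @seealso [fitnessScheme()], [viabilities()], [stepFrequency()]
#' @exportClass FitnessScheme
setClass("FitnessScheme",
  representation(s = "numeric", h = "numeric", parameterization = "character"),
  prototype(s = 0, h = 0.5, parameterization = "viability"))

setValidity("FitnessScheme", function(object) {
  msg <- character()
  if (length(object@s) != 1L || is.na(object@s) || object@s < 0 || object@s >= 1)
    msg <- c(msg, "'s' must be a single value in [0, 1)")
  if (length(object@h) != 1L || is.na(object@h) || object@h < 0 || object@h > 1)
    msg <- c(msg, "'h' must be a single value in [0, 1]")
  if (!object@parameterization %in% c("viability", "genic", "additive"))
    msg <- c(msg, "'parameterization' must be 'viability', 'genic' or 'additive'")
  if (length(msg)) msg else {
    w <- .viabilities(object)
    if (any(w <= 0)) "all genotype viabilities must be strictly positive" else TRUE
  }
})

## ---------------------------------------------------------------------------
## Trajectory
## ---------------------------------------------------------------------------

#' Deterministic allele-frequency trajectory
#'
#' Frequencies of the derived allele over discrete generations under the
#' deterministic viability-selection recursion.
#'
#' @slot generations integer generation times, starting at 0.
#' @slot frequencies allele frequency at each generation, in \code{[0, 1]};
#'   the first element equals \code{p0}.
#' @slot scheme the [FitnessScheme-class] used.
#' @slot p0 initial frequency.
#' @seealso [simulateTrajectory()]
#' @exportClass Trajectory
setClass("Trajectory",
  representation(generations = "integer", frequencies = "numeric",
                 scheme = "FitnessScheme", p0 = "numeric"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@generations) != length(object@frequencies))
    msg <- c(msg, "'generations' and 'frequencies' must have equal length")
  if (length(object@frequencies)) {
    if (any(object@frequencies < 0 | object@frequencies > 1))
      msg <- c(msg, "frequencies must lie in [0, 1]")
    if (abs(object@frequencies[1L] - object@p0) > 1e-12)
      msg <- c(msg, "first frequency must equal p0")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DemographicModel
## ---------------------------------------------------------------------------

#' Scaled demographic model
#'
#' A timeline of demographic events acting on a set of populations, with all
#' times in units of \eqn{2 N_0} generations measured forward from the start
#' of the simulation, and all sizes scaled to the ancestral diploid size
#' \code{N0}. Event kinds are \code{split}, \code{size_change} (payload:
#' multiplier on the current size), \code{growth_rate_change} (payload:
#' exponential rate per unit scaled time) and \code{migration_change}
#' (payload interpreted per \code{migrationConvention}).
#'
#' @slot N0 scaled ancestral diploid population size.
#' @slot populations ordered population labels; the first is ancestral.
#' @slot events data.frame with columns \code{time}, \code{kind}, \code{pop},
#'   \code{pop2}, \code{value}, sorted by time. \code{pop2} is the daughter
#'   label for splits and the source population for migration changes.
#' @slot tEnd scaled end time of the simulation.
#' @slot recordTimes named numeric vector of scaled times at which
#'   per-population frequencies are recorded.
#' @slot kappa real-to-scaled population-size ratio, used only for year
#'   conversions.
#' @slot generationTime generation time in years.
#' @slot migrationConvention one of \code{"copies"} (payload = migrant gene
#'   copies per generation into \code{pop}, divided by its current \eqn{2N}),
#'   \code{"4N0m"} (payload = \eqn{4 N_0 m}) or \code{"2N0m"} (payload =
#'   \eqn{2 N_0 m}), where \eqn{m} is the per-generation fraction of
#'   \code{pop} replaced by migrants from \code{pop2}.
#' @seealso [loadDemographicModel()], [ooaScaledModel()], [populationSizeAt()]
#' @exportClass DemographicModel
setClass("DemographicModel",
  representation(N0 = "integer", populations = "character",
                 events = "data.frame", tEnd = "numeric",
                 recordTimes = "numeric", kappa = "numeric",
                 generationTime = "numeric", migrationConvention = "character"))

setValidity("DemographicModel", function(object) {
  msg <- character()
  ev <- object@events
  needed <- c("time", "kind", "pop", "pop2", "value")
  if (!all(needed %in% names(ev)))
    return(sprintf("events must have columns %s", paste(needed, collapse = ", ")))
  if (length(object@N0) != 1L || is.na(object@N0) || object@N0 < 2L)
    msg <- c(msg, "'N0' must be a single integer >= 2")
  if (!length(object@populations) || anyDuplicated(object@populations))
    msg <- c(msg, "'populations' must be non-empty and unique")
  if (length(object@tEnd) != 1L || object@tEnd < 0)
    msg <- c(msg, "'tEnd' must be a single non-negative time")
  if (nrow(ev)) {
    if (is.unsorted(ev$time))
      msg <- c(msg, "events must be sorted by time")
    if (any(ev$time < 0))
      msg <- c(msg, "event times must be >= 0")
    if (any(ev$time > object@tEnd))
      msg <- c(msg, sprintf("event at time %g lies beyond tEnd = %g",
                            max(ev$time), object@tEnd))
    bad <- !ev$kind %in% c("split", "size_change", "growth_rate_change",
                           "migration_change")
    if (any(bad))
      msg <- c(msg, sprintf("unknown event kind '%s'", ev$kind[bad][1L]))
    if (any(ev$kind == "size_change" & ev$value <= 0))
      msg <- c(msg, "size multipliers must be > 0")
    if (any(ev$kind == "migration_change" & ev$value < 0))
      msg <- c(msg, "migration rates must be >= 0")
    unknown <- setdiff(c(ev$pop, ev$pop2[!is.na(ev$pop2)]), object@populations)
    if (length(unknown)) {
      msg <- c(msg, sprintf("event refers to unknown population '%s'", unknown[1L]))
    } else {
      ## every event must act on a population already founded at its time
      founded <- .foundingTimes(object)
      for (i in seq_len(nrow(ev))) {
        p <- ev$pop[i]
        if (ev$time[i] < founded[[p]] - 1e-12)
          msg <- c(msg, sprintf("event at time %g acts on '%s' before it is founded (%g)",
                                ev$time[i], p, founded[[p]]))
      }
    }
  }
  if (any(object@recordTimes < 0 | object@recordTimes > object@tEnd))
    msg <- c(msg, "record times must lie in [0, tEnd]")
  if (!object@migrationConvention %in% c("copies", "4N0m", "2N0m"))
    msg <- c(msg, "'migrationConvention' must be 'copies', '4N0m' or '2N0m'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## LocusState
## ---------------------------------------------------------------------------

#' Single-locus simulation state
#'
#' Derived-allele counts for one locus across populations and (vectorized)
#' simulation replicates, together with the current generation index. Counts
#' are \code{NA} for populations not yet founded.
#'
#' @slot counts integer matrix, populations x replicates.
#' @slot sizes current diploid size per population (\code{NA} if unfounded).
#' @slot generation current generation index (0 = start).
#' @seealso [newLocusState()], [injectMutation()], [advanceGeneration()]
#' @exportClass LocusState
setClass("LocusState",
  representation(counts = "matrix", sizes = "numeric", generation = "integer"))

setValidity("LocusState", function(object) {
  msg <- character()
  if (nrow(object@counts) != length(object@sizes))
    msg <- c(msg, "counts rows must match sizes length")
  ok <- !is.na(object@sizes)
  if (any(ok)) {
    cnt <- object@counts[ok, , drop = FALSE]
    lim <- 2 * object@sizes[ok]
    if (any(is.na(cnt)) || any(cnt < 0) || any(cnt > lim))
      msg <- c(msg, "allele counts must lie in [0, 2N] for founded populations")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ConditionalEstimate
## ---------------------------------------------------------------------------

#' Conditional probability estimate from rejection sampling
#'
#' Result of running forward replicates until a target number fall inside the
#' present-day African-frequency acceptance window, and scoring the fraction
#' of accepted replicates whose European frequency meets the success
#' threshold.
#'
#' @slot nRaw replicates attempted.
#' @slot nAccepted replicates passing the acceptance window.
#' @slot kSuccess accepted replicates meeting the success criterion.
#' @slot pHat \code{kSuccess / nAccepted}.
#' @slot ci95 exact binomial (Clopper-Pearson) 95\% interval for \code{pHat}.
#' @slot scenario free-text scenario tag.
#' @slot seed master seed used.
#' @slot accepted data.frame of accepted replicates (columns as returned by
#'   [simulateReplicates()]), for downstream summaries.
#' @seealso [estimateConditionalProbability()]
#' @exportClass ConditionalEstimate
setClass("ConditionalEstimate",
  representation(nRaw = "numeric", nAccepted = "numeric", kSuccess = "numeric",
                 pHat = "numeric", ci95 = "numeric", scenario = "character",
                 seed = "numeric", accepted = "data.frame"))

setValidity("ConditionalEstimate", function(object) {
  msg <- character()
  if (!(object@kSuccess <= object@nAccepted && object@nAccepted <= object@nRaw))
    msg <- c(msg, "need kSuccess <= nAccepted <= nRaw")
  if (object@nAccepted > 0 && (object@pHat < 0 || object@pHat > 1))
    msg <- c(msg, "pHat must lie in [0, 1]")
  if (length(object@ci95) == 2 && object@nAccepted > 0 &&
      !(object@ci95[1] - 1e-12 <= object@pHat && object@pHat <= object@ci95[2] + 1e-12))
    msg <- c(msg, "ci95 must contain pHat")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## FrequencyBound
## ---------------------------------------------------------------------------

#' Monomorphic-sample minimum compatible allele frequency
#'
#' The smallest allele frequency \eqn{p_{min}} under which observing only the
#' focal allele in \code{k} independent allele copies has probability at
#' least \code{alpha}; the exact binomial (Clopper-Pearson style) one-sided
#' lower bound \eqn{p_{min} = \alpha^{1/k}}.
#'
#' @slot k number of independent observed allele copies.
#' @slot alpha significance level.
#' @slot pMin the bound.
#' @seealso [minCompatibleFrequency()]
#' @exportClass FrequencyBound
setClass("FrequencyBound",
  representation(k = "integer", alpha = "numeric", pMin = "numeric"))

setValidity("FrequencyBound", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "'k' must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "'alpha' must be in (0, 1)")
  if (object@pMin <= 0 || object@pMin >= 1) msg <- c(msg, "'pMin' must be in (0, 1)")
  if (!length(msg) && abs(object@pMin^object@k - object@alpha) > 1e-12)
    msg <- c(msg, "pMin^k must equal alpha")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## AncientGenotypeTable
## ---------------------------------------------------------------------------

#' Ancient-sample genotype table
#'
#' Per-individual genotype bookkeeping for the diagnostic site: sample id,
#' archaeological site, cultural period, radiocarbon date, genotype call and
#' per-assay replicate outcomes.
#'
#' @slot data data.frame with columns \code{sample}, \code{site},
#'   \code{period}, \code{c14_bp}, \code{genotype} (one of CC, CT, TT or NA)
#'   and \code{replicates} (semicolon-separated per-assay calls, may be "").
#' @seealso [readGenotypeTable()], [summarizeGenotypeTable()],
#'   [observedAlleleFrequency()]
#' @exportClass AncientGenotypeTable
setClass("AncientGenotypeTable", representation(data = "data.frame"))

setValidity("AncientGenotypeTable", function(object) {
  d <- object@data
  needed <- c("sample", "site", "period", "c14_bp", "genotype", "replicates")
  if (!all(needed %in% names(d)))
    return(sprintf("data must have columns %s", paste(needed, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(d$sample))
    msg <- c(msg, sprintf("duplicate sample id '%s'", d$sample[duplicated(d$sample)][1L]))
  gt <- d$genotype[!is.na(d$genotype)]
  if (!all(gt %in% c("CC", "CT", "TT")))
    msg <- c(msg, "genotypes must be CC, CT, TT or NA")
  ## genotype must agree with a concordant set of replicate calls when both present
  for (i in seq_len(nrow(d))) {
    calls <- .splitCalls(d$replicates[i])
    calls <- calls[!is.na(calls)]
    if (length(calls) && !is.na(d$genotype[i]) &&
        length(unique(calls)) == 1L && unique(calls) != d$genotype[i])
      msg <- c(msg, sprintf("sample '%s': genotype disagrees with replicate calls",
                            d$sample[i]))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CloneSet
## ---------------------------------------------------------------------------

#' Cloned PCR product set
#'
#' The direct-PCR consensus sequence of one sample together with the
#' sequences of bacterial clones of the same product. Sequence variability in
#' unique clones relative to the consensus indicates post-mortem template
#' damage.
#'
#' @slot sample sample id.
#' @slot consensus the direct-PCR product sequence ([Biostrings::DNAString]).
#' @slot clones clone sequences ([Biostrings::DNAStringSet]); may differ in
#'   length from the consensus by small insertions.
#' @slot locus locus tag, e.g. \code{"casp12"} or \code{"mtdna"}.
#' @seealso [damageProfile()], [cloneMajorityCheck()], [readCloneSets()]
#' @exportClass CloneSet
setClass("CloneSet",
  representation(sample = "character", consensus = "DNAString",
                 clones = "DNAStringSet", locus = "character"))

setValidity("CloneSet", function(object) {
  if (length(object@clones) < 1L) "need at least one clone" else TRUE
})

## ---------------------------------------------------------------------------
## DamageProfile
## ---------------------------------------------------------------------------

#' Post-mortem damage profile
#'
#' Per-substitution-type counts of sequence changes observed in unique clones
#' (deduplicated within sample), aggregated to per-sample totals and
#' cross-sample means.
#'
#' @slot perSample data.frame: one row per sample, one column per event type
#'   plus \code{total}.
#' @slot meanPerType named numeric: cross-sample mean events per type.
#' @slot meanTotal cross-sample mean of per-sample totals.
#' @slot nSamples number of samples profiled.
#' @seealso [damageProfile()]
#' @exportClass DamageProfile
setClass("DamageProfile",
  representation(perSample = "data.frame", meanPerType = "numeric",
                 meanTotal = "numeric", nSamples = "integer"))

setValidity("DamageProfile", function(object) {
  if (any(object@meanPerType < 0)) return("per-type means must be >= 0")
  if (abs(sum(object@meanPerType) - object@meanTotal) > 1e-9)
    return("meanTotal must equal the sum of per-type means")
  TRUE
})

## ---------------------------------------------------------------------------
## StandardCurve
## ---------------------------------------------------------------------------

#' qPCR standard curve
#'
#' Least-squares fit of threshold cycle (Ct) on log10 template copies from a
#' serial dilution, with amplification efficiency
#' \eqn{E = 10^{-1/slope} - 1}.
#'
#' @slot slope Ct change per log10 copies (negative for amplification).
#' @slot intercept fitted Ct at 1 copy/microlitre.
#' @slot rSquared coefficient of determination.
#' @slot efficiency amplification efficiency as a fraction (1 = 100\%).
#' @slot n number of points fitted.
#' @seealso [fitStandardCurve()], [quantifyExtract()]
#' @exportClass StandardCurve
setClass("StandardCurve",
  representation(slope = "numeric", intercept = "numeric", rSquared = "numeric",
                 efficiency = "numeric", n = "integer"))

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (!is.na(object@rSquared) && (object@rSquared < 0 || object@rSquared > 1))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (object@slope == 0) msg <- c(msg, "slope must be nonzero")
  if (!length(msg) &&
      abs(object@efficiency - (10^(-1 / object@slope) - 1)) > 1e-9)
    msg <- c(msg, "efficiency must equal 10^(-1/slope) - 1")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SyntheticSpec
## ---------------------------------------------------------------------------

#' Synthetic-data generation settings
#'
#' All parameters driving the seeded generators: sample/site layout, true
#' genotype distribution, allelic dropout, per-type post-mortem damage rates,
#' contamination rate and qPCR truth.
#'
#' @slot seed integer seed; every generator is deterministic given it.
#' @slot nSamples number of samples.
#' @slot siteLayout named integer vector of per-site sample counts summing to
#'   \code{nSamples}.
#' @slot genotypeProbs named probabilities for CC, CT, TT.
#' @slot dropoutRate per-allele per-assay dropout probability.
#' @slot damageRates list with elements \code{casp12} and \code{mtdna}: named
#'   per-type mean events per sample.
#' @slot clonesPerSample clones generated per sample.
#' @slot fragmentLengths named lengths (bp) for \code{casp12} and \code{mtdna}
#'   fragments.
#' @slot contaminationRate probability a sample haplotype is replaced by a
#'   researcher haplotype.
#' @slot qpcrTruth list: \code{efficiency}, \code{intercept}, \code{ctSd}.
#' @slot damageModel \code{"poisson"} (default) or \code{"fixed"}
#'   (deterministic per-sample event counts, for exact tests).
#' @seealso [syntheticSpec()] and the \code{gen*} generators.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(seed = "integer", nSamples = "integer", siteLayout = "integer",
                 genotypeProbs = "numeric", dropoutRate = "numeric",
                 damageRates = "list", clonesPerSample = "integer",
                 fragmentLengths = "integer", contaminationRate = "numeric",
                 qpcrTruth = "list", damageModel = "character"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (sum(object@siteLayout) != object@nSamples)
    msg <- c(msg, "per-site counts must sum to nSamples")
  if (abs(sum(object@genotypeProbs) - 1) > 1e-9 || any(object@genotypeProbs < 0))
    msg <- c(msg, "genotypeProbs must be non-negative and sum to 1")
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1]")
  if (object@contaminationRate < 0 || object@contaminationRate > 1)
    msg <- c(msg, "contaminationRate must lie in [0, 1]")
  if (any(unlist(object@damageRates) < 0))
    msg <- c(msg, "damage rates must be >= 0")
  if (!object@damageModel %in% c("poisson", "fixed"))
    msg <- c(msg, "damageModel must be 'poisson' or 'fixed'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## AnalysisReport
## ---------------------------------------------------------------------------

#' Consolidated analysis report
#'
#' Results of the full pipeline run: conditional probability estimates,
#' expected mid-Holocene European frequency, two-step sweep generation counts
#' under each fitness parameterization, the monomorphic-sample frequency
#' bound, genotype-table summary and QC summaries.
#'
#' @slot results named list of stage results.
#' @slot seed master seed.
#' @slot config configuration list actually used.
#' @slot version package version string.
#' @slot runtime elapsed seconds.
#' @seealso [runFullAnalysis()], [renderReport()]
#' @exportClass AnalysisReport
setClass("AnalysisReport",
  representation(results = "list", seed = "numeric", config = "list",
                 version = "character", runtime = "numeric"))
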