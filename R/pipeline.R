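## Orchestration: one-command reproduction of the computational results on
## the packaged fixtures and synthetic data, with a consolidated report.

## benchmark values this analysis is checked against (published estimates
## for the locus: conditional probabilities, mid-Holocene European
## frequency, and the monomorphic-sample bound)
.REFERENCE_VALUES <- c(neutral_probability = 0.021,
                       selected_probability = 0.024,
                       eur_frequency_7kybp = 0.4,
                       min_compatible_frequency = 0.83)

.defaultConfig <- function() {
  list(nAccepted = 2000L,
       acceptanceWindow = c(0.3, 0.5),
       successThreshold = 0.95,
       originWindow = c(0.001, 0.003),
       batchSize = 25000L,
       rawCap = 5e6,
       s = 0.01,
       h = 0.11,
       twoStepStart = 0.4,
       twoStepTarget = 0.99,
       damageSamples = 200L,
       alpha = 0.05,
       migrationConvention = "copies")
}

#' Run the full analysis pipeline
#'
#' Sequences every stage: the deterministic-recursion sweep-time sensitivity
#' check, the neutral and selected-since-origin conditional probabilities,
#' the expected mid-Holocene European frequency, the two-step Neolithic
#' scenario, the monomorphic-sample frequency bound and genotype-table
#' summary, and QC parameter-recovery on synthetic clone sets, haplotype
#' surveys and dilution series. Deterministic given \code{(config, seed)}.
#'
#' @param config named list overriding the defaults (see Details); unnamed
#'   entries are rejected. Defaults: 2000 accepted replicates, acceptance
#'   window \code{[0.3, 0.5]}, success threshold 0.95, \code{s} = 0.01,
#'   \code{h} = 0.11, 200 synthetic damage samples, \code{alpha} = 0.05.
#' @param seed master integer seed; all stage seeds derive from it.
#' @return An [AnalysisReport-class].
#' @examples
#' \dontrun{
#' rep <- runFullAnalysis(list(nAccepted = 100, damageSamples = 20), seed = 1)
#' cat(renderReport(rep))
#' }
#' @export
runFullAnalysis <- function(config = list(), seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  defaults <- .defaultConfig()
  unknown <- setdiff(names(config), c(names(defaults), "model", "genotypeTable"))
  if (length(unknown) || (length(config) && is.null(names(config))))
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  model <- if (!is.null(config$model)) config$model
           else ooaScaledModel(cfg$migrationConvention)
  gtable <- if (!is.null(config$genotypeTable)) config$genotypeTable
            else casp12AncientTable()
  stageSeeds <- withr::with_seed(as.integer(seed),
    sample.int(.Machine$integer.max - 1L, 6L))

  message("stage 1/6: deterministic recursion sensitivity")
  sens08 <- sweepTimeSensitivity(cfg$twoStepStart, 0.8, cfg$s, cfg$h)
  sens99 <- sweepTimeSensitivity(cfg$twoStepStart, cfg$twoStepTarget,
                                 cfg$s, cfg$h)
  viability99 <- sens99$generations[sens99$parameterization == "viability"]
  tension <- is.na(viability99) || viability99 > 250

  message("stage 2/6: neutral conditional probability")
  neutral <- estimateConditionalProbability(model, neutralScheme(),
    seed = stageSeeds[1], acceptanceWindow = cfg$acceptanceWindow,
    successThreshold = cfg$successThreshold, nAcceptedTarget = cfg$nAccepted,
    originWindow = cfg$originWindow, batchSize = cfg$batchSize,
    rawCap = cfg$rawCap, scenario = "neutral")

  message("stage 3/6: expected European frequency at the 7 kYBP record point")
  eur7k <- expectedFrequencyAtTime(neutral, record = "EUR_at_7kYBP")

  message("stage 4/6: selected-since-origin conditional probability")
  selected <- estimateConditionalProbability(model,
    fitnessScheme(cfg$s, parameterization = "additive"),
    seed = stageSeeds[2], acceptanceWindow = cfg$acceptanceWindow,
    successThreshold = cfg$successThreshold, nAcceptedTarget = cfg$nAccepted,
    originWindow = cfg$originWindow, batchSize = cfg$batchSize,
    rawCap = cfg$rawCap, scenario = "selected_since_origin")

  message("stage 5/6: ancient-sample statistics")
  summ <- summarizeGenotypeTable(gtable)
  k <- max(summ$perSite)
  bound <- minCompatibleFrequency(k, cfg$alpha)
  boundChrom <- minCompatibleFrequency(2L * k, cfg$alpha)
  afreq <- observedAlleleFrequency(gtable, "T")

  message("stage 6/6: QC parameter recovery on synthetic data")
  qcSpec <- syntheticSpec(seed = stageSeeds[3],
                          siteLayout = c(synthetic_site = cfg$damageSamples))
  dmgMt <- damageProfile(genCloneSets(qcSpec, "mtdna"))
  dmgCasp <- damageProfile(genCloneSets(qcSpec, "casp12"))
  contamSpec <- syntheticSpec(seed = stageSeeds[4],
                              siteLayout = c(synthetic_site = 50L),
                              contaminationRate = 0.2)
  survey <- genHaplotypeSurvey(contamSpec)
  screen <- contaminationScreen(survey$samples, survey$researchers)
  qpcrSpec <- syntheticSpec(seed = stageSeeds[5])
  curve <- fitStandardCurve(genDilutionSeries(qpcrSpec))

  lowPrecision <- cfg$nAccepted < 500
  if (lowPrecision)
    warning("fewer than 500 accepted replicates requested; ",
            "conditional-probability intervals will be wide")

  results <- list(
    sweep_sensitivity_0.8 = sens08,
    sweep_sensitivity_target = sens99,
    recursion_tension = tension,
    neutral = neutral,
    eur7k = eur7k,
    selected = selected,
    genotype_summary = summ,
    observed_T_frequency = afreq,
    frequency_bound = bound,
    frequency_bound_chromosomes = boundChrom,
    damage_mtdna = dmgMt,
    damage_casp12 = dmgCasp,
    contamination = list(screen = screen, truth = survey$truth,
      recovered = setequal(
        do.call(paste, screen$matches),
        do.call(paste, survey$truth))),
    qpcr = curve,
    low_precision = lowPrecision)
  new("AnalysisReport", results = results, seed = as.numeric(seed),
      config = cfg, version = as.character(utils::packageVersion("paleosweep")),
      runtime = proc.time()[["elapsed"]] - t0)
}

setMethod("show", "AnalysisReport", function(object) {
  cat(sprintf("AnalysisReport (v%s, seed %g, %.1f s): %d stage result(s)\n",
              object@version, object@seed, object@runtime,
              length(object@results)))
  cat("  use renderReport() for the full summary\n")
})

#' Render an analysis report
#'
#' The text format juxtaposes each computed value with the package's
#' benchmark value for that quantity and flags the deterministic-recursion
#' tension: under the literal viability scheme with the nominal
#' \code{(s, h)}, the mid-frequency sweep takes far longer than the
#' ~200/<250-generation figures the benchmark narrative assumes; only the
#' genic or additive parameterizations approach those figures. The JSON
#' format is the machine-readable twin.
#'
#' @param report an [AnalysisReport-class].
#' @param format \code{"text"} (default) or \code{"json"}.
#' @return A character scalar (text) or a JSON string.
#' @export
renderReport <- function(report, format = c("text", "json")) {
  stopifnot(is(report, "AnalysisReport"))
  format <- match.arg(format)
  r <- report@results
  needed <- c("neutral", "selected", "eur7k", "frequency_bound")
  missing <- setdiff(needed, names(r))
  if (length(missing))
    stop("report is missing stage(s): ", paste(missing, collapse = ", "))
  if (format == "json") {
    out <- list(
      version = report@version, seed = report@seed,
      runtime_seconds = report@runtime,
      neutral = list(p_hat = r$neutral@pHat, ci95 = r$neutral@ci95,
                     n_raw = r$neutral@nRaw, n_accepted = r$neutral@nAccepted,
                     k_success = r$neutral@kSuccess,
                     reference = unname(.REFERENCE_VALUES["neutral_probability"])),
      selected = list(p_hat = r$selected@pHat, ci95 = r$selected@ci95,
                      n_raw = r$selected@nRaw, n_accepted = r$selected@nAccepted,
                      k_success = r$selected@kSuccess,
                      reference = unname(.REFERENCE_VALUES["selected_probability"])),
      eur_frequency_7kybp = list(mean = r$eur7k$mean, ci95 = r$eur7k$ci95,
        reference = unname(.REFERENCE_VALUES["eur_frequency_7kybp"])),
      frequency_bound = list(p_min = r$frequency_bound@pMin,
        k = r$frequency_bound@k, alpha = r$frequency_bound@alpha,
        reference = unname(.REFERENCE_VALUES["min_compatible_frequency"])),
      sweep_sensitivity = r$sweep_sensitivity_target,
      recursion_tension = r$recursion_tension,
      damage_mean_mtdna = r$damage_mtdna@meanTotal,
      damage_mean_casp12 = r$damage_casp12@meanTotal,
      qpcr_efficiency = r$qpcr@efficiency,
      contamination_recovered = r$contamination$recovered)
    return(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA))
  }
  fmtRow <- function(label, value, ref, extra = "") {
    sprintf("  %-34s %10.4f   (benchmark %.3g)%s", label, value, ref,
            if (nzchar(extra)) paste0("  ", extra) else "")
  }
  lines <- c(
    sprintf("paleosweep analysis report (v%s, seed %g)", report@version,
            report@seed),
    "",
    fmtRow("P(EUR >= 0.95 | neutral)", r$neutral@pHat,
           .REFERENCE_VALUES["neutral_probability"],
           sprintf("CI [%.4f, %.4f]", r$neutral@ci95[1], r$neutral@ci95[2])),
    fmtRow("P(EUR >= 0.95 | selected)", r$selected@pHat,
           .REFERENCE_VALUES["selected_probability"],
           sprintf("CI [%.4f, %.4f]", r$selected@ci95[1], r$selected@ci95[2])),
    fmtRow("mean EUR frequency at 7 kYBP", r$eur7k$mean,
           .REFERENCE_VALUES["eur_frequency_7kybp"]),
    fmtRow(sprintf("p_min (k = %d, alpha = %g)", r$frequency_bound@k,
                   r$frequency_bound@alpha), r$frequency_bound@pMin,
           .REFERENCE_VALUES["min_compatible_frequency"]),
    "",
    "  two-step sweep generations to target, by parameterization:",
    sprintf("    %-22s %s", r$sweep_sensitivity_target$parameterization,
            format(round(r$sweep_sensitivity_target$generations))),
    "")
  if (isTRUE(r$recursion_tension))
    lines <- c(lines,
      "  NOTE: under the literal viability scheme (s, h as configured) the",
      "  deterministic recursion needs far more than 250 generations to reach",
      "  the target; the ~200/<250-generation benchmark figures are attainable",
      "  only under the genic or additive parameterizations.", "")
  lines <- c(lines,
    sprintf("  damage means (mtDNA, nuclear): %.2f, %.2f events/sample",
            r$damage_mtdna@meanTotal, r$damage_casp12@meanTotal),
    sprintf("  qPCR efficiency: %.1f%% (r^2 = %.3f)", 100 * r$qpcr@efficiency,
            r$qpcr@rSquared),
    sprintf("  contamination screen recovered planted truth: %s",
            r$contamination$recovered),
    sprintf("  observed derived-allele frequency in ancient samples: %.3f",
            r$observed_T_frequency$frequency))
  paste(lines, collapse = "\n")
}
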