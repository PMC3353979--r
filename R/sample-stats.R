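## Ancient-sample genotype bookkeeping and the monomorphic-sample
## minimum-compatible-frequency bound.

#' Minimum allele frequency compatible with a monomorphic sample
#'
#' If only the focal allele is observed in \code{k} independent allele
#' copies, the smallest true frequency under which that observation has
#' probability at least \code{alpha} is the exact one-sided binomial
#' (Clopper-Pearson style) lower bound \eqn{p_{min} = \alpha^{1/k}}. With
#' one independent copy counted per individual (conservative against allelic
#' dropout in degraded DNA), 17 monomorphic individuals give
#' \eqn{0.05^{1/17} = 0.8384}.
#'
#' @param k number of independent observed allele copies (>= 1). Under the
#'   default individual-counting convention this is the number of
#'   individuals; under chromosome counting it is twice that.
#' @param alpha significance level in (0, 1).
#' @return A [FrequencyBound-class].
#' @examples
#' minCompatibleFrequency(17, 0.05)
#' minCompatibleFrequency(34, 0.05)  # chromosome-counting variant
#' @export
minCompatibleFrequency <- function(k, alpha = 0.05) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be an integer >= 1")
  if (is.na(alpha) || alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  new("FrequencyBound", k = k, alpha = alpha, pMin = alpha^(1 / k))
}

setMethod("show", "FrequencyBound", function(object) {
  cat(sprintf("FrequencyBound: p_min = %.4f  (k = %d, alpha = %g)\n",
              object@pMin, object@k, object@alpha))
})

#' @describeIn minCompatibleFrequency numeric accessor for the bound
#' @param bound a [FrequencyBound-class].
#' @export
pMin <- function(bound) bound@pMin

#' Build an ancient genotype table
#'
#' @param data data.frame with columns \code{sample}, \code{site},
#'   \code{period}, \code{c14_bp}, \code{genotype}, \code{replicates}.
#' @return A validated [AncientGenotypeTable-class].
#' @export
ancientGenotypeTable <- function(data) {
  data$sample <- as.character(data$sample)
  data$site <- as.character(data$site)
  data$period <- as.character(data$period)
  data$c14_bp <- as.numeric(data$c14_bp)
  data$genotype <- as.character(data$genotype)
  data$replicates <- as.character(data$replicates)
  data$replicates[is.na(data$replicates)] <- ""
  new("AncientGenotypeTable", data = data)
}

.splitCalls <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  calls <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  ifelse(calls %in% c("", "NA", "missing"), NA_character_, calls)
}

#' Read an ancient genotype table from TSV
#'
#' Expects a header with columns \code{sample}, \code{site}, \code{period},
#' \code{c14_bp}, \code{genotype}, \code{replicates} (semicolon-separated
#' per-assay calls; empty for none).
#'
#' @param file path to a tab-separated file.
#' @return An [AncientGenotypeTable-class].
#' @export
readGenotypeTable <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  d <- utils::read.delim(file, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  ancientGenotypeTable(d)
}

#' The packaged prehistoric genotype fixture
#'
#' Twenty-four prehistoric individuals from six sites in the north of the
#' Iberian Peninsula (Late Upper Paleolithic to Late Neolithic), all
#' homozygous for the derived (inactive) T allele at the diagnostic site.
#'
#' @return An [AncientGenotypeTable-class] with 24 rows.
#' @export
casp12AncientTable <- function() {
  readGenotypeTable(system.file("extdata", "table1_genotypes.tsv",
                                package = "paleosweep", mustWork = TRUE))
}

#' Summarize an ancient genotype table
#'
#' @param table an [AncientGenotypeTable-class].
#' @return List with \code{total}, \code{perSite}, \code{perPeriod} (named
#'   counts) and \code{genotypeCounts} over non-missing calls.
#' @export
summarizeGenotypeTable <- function(table) {
  stopifnot(is(table, "AncientGenotypeTable"))
  d <- table@data
  perSite <- if (nrow(d)) table(d$site) else table(character())
  perPeriod <- if (nrow(d)) table(d$period) else table(character())
  gt <- d$genotype[!is.na(d$genotype)]
  list(total = nrow(d),
       perSite = stats::setNames(as.integer(perSite), names(perSite)),
       perPeriod = stats::setNames(as.integer(perPeriod), names(perPeriod)),
       genotypeCounts = stats::setNames(
         as.integer(table(factor(gt, levels = c("CC", "CT", "TT")))),
         c("CC", "CT", "TT")))
}

#' Observed frequency of an allele in a genotype table
#'
#' Counts allele copies over non-missing genotypes. Two conventions are
#' reported: chromosome counting (copies over \eqn{2 \times} individuals)
#' and the dropout-conservative individual counting (at most one independent
#' copy credited per individual: an individual carrying the allele counts 1).
#'
#' @param table an [AncientGenotypeTable-class].
#' @param allele \code{"T"} (default) or \code{"C"}.
#' @return List with \code{frequency} (chromosome counting), \code{copies},
#'   \code{chromosomes}, \code{frequencyIndividuals},
#'   \code{individualsCarrying} and \code{individuals}.
#' @export
observedAlleleFrequency <- function(table, allele = c("T", "C")) {
  stopifnot(is(table, "AncientGenotypeTable"))
  allele <- match.arg(allele)
  gt <- table@data$genotype
  gt <- gt[!is.na(gt)]
  if (!length(gt)) stop("all genotypes are missing; frequency undefined")
  copies <- sum(vapply(strsplit(gt, ""), function(a) sum(a == allele), numeric(1)))
  carrying <- sum(vapply(strsplit(gt, ""), function(a) any(a == allele), logical(1)))
  list(frequency = copies / (2 * length(gt)),
       copies = copies, chromosomes = 2L * length(gt),
       frequencyIndividuals = carrying / length(gt),
       individualsCarrying = carrying, individuals = length(gt))
}

setMethod("show", "AncientGenotypeTable", function(object) {
  s <- summarizeGenotypeTable(object)
  cat(sprintf("AncientGenotypeTable: %d individual(s), %d site(s)\n",
              s$total, length(s$perSite)))
  cat("  genotypes:",
      paste(sprintf("%s = %d", names(s$genotypeCounts), s$genotypeCounts),
            collapse = ", "), "\n")
})
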