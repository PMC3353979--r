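## Seeded generators for every input the pipeline consumes: genotype tables
## with allelic dropout, clone sets with per-type post-mortem damage,
## haplotype surveys with planted contamination, and qPCR dilution series.

## fixed synthetic amplicon fragments (balanced base composition; only the
## composition matters, for damage-event eligibility)
.CASP12_FRAG <- paste0(
  "ACTGGATCCA", "GTTACGGAAT", "CGATTACAGG", "TACGTAGCTA",
  "GGATCATTCG", "ACGTTAGCAT", "CGGATATCGA", "TTACGCAGTA")      # 80 bp
.MTDNA_FRAG <- paste0(
  "CATTAGCACC", "CAAAGCTAAG", "ATTCTAATTT", "AAACTATTCT",
  "CTGTTCTTTC", "ATGGGGAAGC", "AGATTTGGGT", "ACCACCCAAG",
  "TATTGACTCA", "CCCATCAACA")                                  # 100 bp

#' Construct synthetic-data generation settings
#'
#' Defaults mirror the study conditions: 24 samples laid out over the six
#' archaeological sites (17 at SJAPL), every true genotype TT, ten clones per
#' sample, per-type damage-event means of 1.2 A>G and 0.6 G>A on the 80 bp
#' nuclear fragment and 1.8 A>G, 2.2 G>A, 1.5 insA, 0.04 insG, 0.2 C>T and
#' 0.08 T>C on the 100 bp mtDNA fragment, and a qPCR truth of 102\%
#' efficiency.
#'
#' @param seed integer seed.
#' @param nSamples number of samples (default the sum of \code{siteLayout}).
#' @param siteLayout named per-site counts.
#' @param genotypeProbs named probabilities for CC, CT, TT.
#' @param dropoutRate per-allele per-assay dropout probability (default 0.1).
#' @param damageRates list with named per-type mean events per sample for
#'   \code{casp12} and \code{mtdna}.
#' @param clonesPerSample clones per sample (default 10).
#' @param fragmentLengths named fragment lengths; must not exceed the
#'   packaged fragment lengths (80 and 100 bp).
#' @param contaminationRate probability a sample haplotype is replaced by a
#'   researcher haplotype (default 0).
#' @param qpcrTruth list with \code{efficiency}, \code{intercept},
#'   \code{ctSd}.
#' @param damageModel \code{"poisson"} (default) or \code{"fixed"}.
#' @return A validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(seed = 1L,
                          nSamples = NULL,
                          siteLayout = c("La Pasiega" = 1L, "La Chora" = 1L,
                                         "Erralla" = 1L, "Marizulo" = 1L,
                                         "SJAPL" = 17L, "Longar" = 3L),
                          genotypeProbs = c(CC = 0, CT = 0, TT = 1),
                          dropoutRate = 0.1,
                          damageRates = list(
                            casp12 = c("A>G" = 1.2, "G>A" = 0.6),
                            mtdna = c("A>G" = 1.8, "G>A" = 2.2, "insA" = 1.5,
                                      "insG" = 0.04, "C>T" = 0.2,
                                      "T>C" = 0.08)),
                          clonesPerSample = 10L,
                          fragmentLengths = c(casp12 = 80L, mtdna = 100L),
                          contaminationRate = 0,
                          qpcrTruth = list(efficiency = 1.02, intercept = 38,
                                           ctSd = 0.1),
                          damageModel = c("poisson", "fixed")) {
  damageModel <- match.arg(damageModel)
  siteLayout <- stats::setNames(as.integer(siteLayout), names(siteLayout))
  if (is.null(nSamples)) nSamples <- sum(siteLayout)
  if (sum(siteLayout) != nSamples) {
    ## a bare sample count without layout: one generic site
    siteLayout <- c(synthetic_site = as.integer(nSamples))
  }
  new("SyntheticSpec", seed = as.integer(seed), nSamples = as.integer(nSamples),
      siteLayout = siteLayout,
      genotypeProbs = genotypeProbs[c("CC", "CT", "TT")],
      dropoutRate = dropoutRate, damageRates = damageRates,
      clonesPerSample = as.integer(clonesPerSample),
      fragmentLengths = stats::setNames(as.integer(fragmentLengths),
                                        names(fragmentLengths)),
      contaminationRate = contaminationRate, qpcrTruth = qpcrTruth,
      damageModel = damageModel)
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d sample(s) over %d site(s); seed %d\n",
              object@nSamples, length(object@siteLayout), object@seed))
  cat(sprintf("  dropout %.2g, contamination %.2g, %d clones/sample (%s damage)\n",
              object@dropoutRate, object@contaminationRate,
              object@clonesPerSample, object@damageModel))
})

#' Generate a synthetic ancient genotype table
#'
#' Draws a true genotype per sample from the configured distribution, then
#' derives per-assay observed calls with independent per-allele dropout
#' (heterozygotes may appear homozygous; full dropout gives a missing call).
#' The recorded genotype is the first non-missing call, as with direct
#' sequencing.
#'
#' @param spec a [SyntheticSpec-class].
#' @param nAssays per-sample assays (default 2: duplication protocol).
#' @return List with \code{table} (an [AncientGenotypeTable-class]) and
#'   \code{truth} (named character vector of true genotypes).
#' @export
genGenotypeTable <- function(spec, nAssays = 2L) {
  stopifnot(is(spec, "SyntheticSpec"))
  withr::with_seed(spec@seed, {
    sites <- rep(names(spec@siteLayout), spec@siteLayout)
    ids <- make.unique(paste0(abbreviate(gsub("[^A-Za-z]", "", sites), 5),
                              seq_along(sites)), sep = "_")
    truth <- sample(c("CC", "CT", "TT"), spec@nSamples, replace = TRUE,
                    prob = spec@genotypeProbs)
    callOne <- function(gt) {
      alleles <- strsplit(gt, "")[[1L]]
      kept <- alleles[stats::runif(2) >= spec@dropoutRate]
      if (!length(kept)) return(NA_character_)
      u <- sort(unique(kept))
      if (length(u) == 2L) "CT" else paste0(u, u)
    }
    calls <- vapply(truth, function(gt)
      paste(vapply(seq_len(nAssays), function(i) {
        cl <- callOne(gt)
        if (is.na(cl)) "NA" else cl
      }, character(1)), collapse = ";"), character(1))
    observed <- vapply(strsplit(calls, ";"), function(cs) {
      cs <- cs[cs != "NA"]
      if (length(cs)) cs[1L] else NA_character_
    }, character(1))
    tab <- ancientGenotypeTable(data.frame(
      sample = ids, site = sites, period = "synthetic", c14_bp = NA_real_,
      genotype = observed, replicates = calls, stringsAsFactors = FALSE))
    list(table = tab, truth = stats::setNames(truth, ids))
  })
}

## apply one substitution event of a given type to a clone character vector
.applySubstitution <- function(chars, type) {
  from <- substr(type, 1L, 1L)
  to <- substr(type, 3L, 3L)
  elig <- which(chars == from)
  if (!length(elig)) return(NULL)
  i <- if (length(elig) == 1L) elig else sample(elig, 1L)
  chars[i] <- to
  chars
}

#' Generate synthetic clone sets with post-mortem damage
#'
#' Clones start identical to the fixed consensus fragment; damage events are
#' allocated so that the expected per-sample total of each type equals the
#' configured rate (Poisson per clone with mean rate/clones under the
#' default model, exactly \code{round(rate)} events per sample under
#' \code{"fixed"}). Substitution events pick a uniform eligible base;
#' insertion events insert the named base at a uniform position.
#'
#' @param spec a [SyntheticSpec-class].
#' @param locus \code{"mtdna"} or \code{"casp12"}.
#' @return List of [CloneSet-class] objects, one per sample.
#' @export
genCloneSets <- function(spec, locus = c("mtdna", "casp12")) {
  stopifnot(is(spec, "SyntheticSpec"))
  locus <- match.arg(locus)
  frag <- if (locus == "mtdna") .MTDNA_FRAG else .CASP12_FRAG
  len <- spec@fragmentLengths[[locus]]
  if (len > nchar(frag))
    stop(sprintf("fragment length %d exceeds the packaged %s fragment (%d bp)",
                 len, locus, nchar(frag)))
  frag <- substr(frag, 1L, len)
  rates <- spec@damageRates[[locus]]
  consChars <- strsplit(frag, "")[[1L]]
  for (ty in names(rates)[rates > 0 & !startsWith(names(rates), "ins")]) {
    if (!substr(ty, 1L, 1L) %in% consChars)
      stop(sprintf("rate for %s is positive but the fragment has no %s",
                   ty, substr(ty, 1L, 1L)))
  }
  nc <- spec@clonesPerSample
  withr::with_seed(spec@seed + ifelse(locus == "mtdna", 101L, 202L), {
    lapply(seq_len(spec@nSamples), function(si) {
      clones <- character(nc)
      ## per-sample per-type event counts split over clones
      for (ci in seq_len(nc)) {
        chars <- consChars
        inserts <- character()
        insPos <- integer()
        for (ty in names(rates)) {
          nEv <- if (spec@damageModel == "poisson") {
            stats::rpois(1L, rates[[ty]] / nc)
          } else {
            ## fixed: events land on the first clones, round(rate) per sample
            tot <- as.integer(round(rates[[ty]]))
            sum(((seq_len(tot) - 1L) %% nc) + 1L == ci)
          }
          if (nEv == 0L) next
          if (startsWith(ty, "ins")) {
            base <- substr(ty, 4L, 4L)
            for (e in seq_len(nEv)) {
              insPos <- c(insPos, sample.int(length(chars) + 1L, 1L))
              inserts <- c(inserts, base)
            }
          } else {
            for (e in seq_len(nEv)) {
              res <- .applySubstitution(chars, ty)
              if (is.null(res))
                stop(sprintf("no eligible base left for %s in sample %d", ty, si))
              chars <- res
            }
          }
        }
        if (length(insPos)) {
          for (k in order(insPos, decreasing = TRUE))
            chars <- append(chars, inserts[k], after = insPos[k] - 1L)
        }
        clones[ci] <- paste(chars, collapse = "")
      }
      suppressWarnings(cloneSet(sprintf("synth%03d", si), frag, clones,
                                locus = locus))
    })
  })
}

## deterministic synthetic mtDNA "reference" base at a position
.refBaseAt <- function(pos) c("A", "C", "G", "T")[(pos %% 4L) + 1L]

.randomHaplotype <- function(minVar = 1L, maxVar = 5L) {
  n <- sample(minVar:maxVar, 1L)
  pos <- sort(sample(16024:16383, n))
  ref <- vapply(pos, .refBaseAt, character(1))
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1))
  data.frame(position = pos, ref = ref, alt = unname(alt),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic haplotype survey with planted contamination
#'
#' Builds a pool of distinct HVR-I variant-set haplotypes, assigns
#' researchers distinct haplotypes, draws sample haplotypes from the
#' remaining pool, and replaces each sample's haplotype by a random
#' researcher haplotype with the configured contamination rate, recording the
#' planted truth.
#'
#' @param spec a [SyntheticSpec-class].
#' @param nResearchers researcher pool size (default 10).
#' @param poolSize distinct haplotypes to generate in total (default
#'   \code{nResearchers + 20}); must exceed \code{nResearchers}.
#' @return List with \code{samples} and \code{researchers} (variant
#'   data.frames: \code{id}, \code{position}, \code{ref}, \code{alt}) and
#'   \code{truth} (data.frame \code{sample}, \code{researcher} of planted
#'   contaminations).
#' @export
genHaplotypeSurvey <- function(spec, nResearchers = 10L, poolSize = NULL) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (is.null(poolSize)) poolSize <- nResearchers + 20L
  if (poolSize <= nResearchers)
    stop("'poolSize' too small: need more distinct haplotypes than researchers")
  withr::with_seed(spec@seed + 303L, {
    pool <- list()
    keys <- character()
    guard <- 0L
    while (length(pool) < poolSize) {
      guard <- guard + 1L
      if (guard > 100L * poolSize)
        stop("could not generate enough distinct haplotypes for the pool")
      h <- .randomHaplotype()
      key <- paste(sprintf("%d%s>%s", h$position, h$ref, h$alt), collapse = ";")
      if (key %in% keys) next
      pool[[length(pool) + 1L]] <- h
      keys <- c(keys, key)
    }
    resIdx <- seq_len(nResearchers)
    resIds <- sprintf("R%02d", resIdx)
    sampleIds <- sprintf("S%03d", seq_len(spec@nSamples))
    assigned <- sample((nResearchers + 1L):poolSize, spec@nSamples,
                       replace = TRUE)
    contam <- stats::runif(spec@nSamples) < spec@contaminationRate
    source <- ifelse(contam, sample(resIdx, spec@nSamples, replace = TRUE),
                     assigned)
    bind <- function(ids, idx) {
      do.call(rbind, lapply(seq_along(ids), function(i)
        cbind(id = ids[i], pool[[idx[i]]], stringsAsFactors = FALSE)))
    }
    list(samples = bind(sampleIds, source),
         researchers = bind(resIds, resIdx),
         truth = data.frame(sample = sampleIds[contam],
                            researcher = resIds[match(source[contam], resIdx)],
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic qPCR dilution series
#'
#' Threshold cycles follow
#' \eqn{Ct = intercept - \log_{10}(copies)/\log_{10}(1 + E) + \epsilon}
#' with Gaussian noise of the configured standard deviation.
#'
#' @param spec a [SyntheticSpec-class]; the truth lives in
#'   \code{spec@qpcrTruth}.
#' @param points known copies per microlitre (default the high-concentration
#'   layout \code{c(1.4e4, 1.4e5, 1.4e6)}).
#' @param replicates replicates per point (default 4).
#' @return data.frame with columns \code{copies_per_ul}, \code{ct},
#'   \code{replicate}, suitable for [fitStandardCurve()].
#' @export
genDilutionSeries <- function(spec, points = c(1.4e4, 1.4e5, 1.4e6),
                              replicates = 4L) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (any(points <= 0)) stop("copy numbers must be positive")
  E <- spec@qpcrTruth$efficiency
  if (is.null(E) || E <= 0) stop("qPCR efficiency must be positive")
  withr::with_seed(spec@seed + 404L, {
    d <- expand.grid(replicate = seq_len(replicates), copies_per_ul = points)
    d <- d[c("copies_per_ul", "replicate")]
    d$ct <- spec@qpcrTruth$intercept -
      log10(d$copies_per_ul) / log10(1 + E) +
      stats::rnorm(nrow(d), 0, spec@qpcrTruth$ctSd)
    d
  })
}
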