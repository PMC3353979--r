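## Ancient-DNA authentication computations: post-mortem damage profiling of
## cloned PCR products, mtDNA HVR-I contamination screening, replicate
## concordance and qPCR standard-curve quantitation.

.DAMAGE_TYPES <- c("A>G", "G>A", "C>T", "T>C", "insA", "insG", "other")
.HVR1_RANGE <- c(15998L, 16400L)

#' Construct a clone set
#'
#' @param sample sample id.
#' @param consensus consensus (direct-PCR) sequence; character or
#'   [Biostrings::DNAString].
#' @param clones clone sequences; character vector or
#'   [Biostrings::DNAStringSet].
#' @param locus locus tag (default \code{"casp12"}).
#' @return A [CloneSet-class]. Fewer than 10 clones triggers a warning (the
#'   cloning protocol picks at least 10 colonies), not an error.
#' @export
cloneSet <- function(sample, consensus, clones, locus = "casp12") {
  if (is.character(consensus)) consensus <- Biostrings::DNAString(consensus)
  if (is.character(clones)) clones <- Biostrings::DNAStringSet(clones)
  if (length(clones) < 10L)
    warning(sprintf("sample '%s': only %d clone(s); protocol expects >= 10",
                    sample, length(clones)))
  new("CloneSet", sample = as.character(sample), consensus = consensus,
      clones = clones, locus = as.character(locus))
}

setMethod("show", "CloneSet", function(object) {
  cat(sprintf("CloneSet '%s' (%s): consensus %d bp, %d clone(s), %d unique\n",
              object@sample, object@locus, length(object@consensus),
              length(object@clones),
              length(unique(as.character(object@clones)))))
})

## End-anchored alignment of a short clone fragment against its consensus,
## tolerant of isolated single-base gaps (the indel mode expected from
## cloned PCR products of the same locus). Greedy scan with a short
## lookahead decides substitution vs gap at each mismatch. Returns list
## (a = consensus chars, b = clone chars, both gapped with "-"), or NULL if
## unalignable (length difference beyond 10 or alignment dominated by
## mismatches).
.alignClone <- function(consChars, cloneChars, lookahead = 8L) {
  la <- length(consChars)
  lb <- length(cloneChars)
  d <- lb - la
  if (abs(d) > 10L) return(NULL)
  A <- character(la + abs(d))
  B <- character(la + abs(d))
  n <- 0L
  i <- 1L
  j <- 1L
  scoreAt <- function(ii, jj) {
    w <- min(lookahead, la - ii + 1L, lb - jj + 1L)
    if (w <= 0L) return(0)
    sum(consChars[ii:(ii + w - 1L)] == cloneChars[jj:(jj + w - 1L)])
  }
  while (i <= la && j <= lb) {
    n <- n + 1L
    if (consChars[i] == cloneChars[j]) {
      A[n] <- consChars[i]; B[n] <- cloneChars[j]; i <- i + 1L; j <- j + 1L
      next
    }
    sSub <- scoreAt(i + 1L, j + 1L)
    sIns <- if (d > 0L) scoreAt(i, j + 1L) else -1
    sDel <- if (d < 0L) scoreAt(i + 1L, j) else -1
    best <- max(sSub, sIns, sDel)
    if (d > 0L && sIns == best && sIns > sSub) {
      A[n] <- "-"; B[n] <- cloneChars[j]; j <- j + 1L; d <- d - 1L
    } else if (d < 0L && sDel == best && sDel > sSub) {
      A[n] <- consChars[i]; B[n] <- "-"; i <- i + 1L; d <- d + 1L
    } else {
      A[n] <- consChars[i]; B[n] <- cloneChars[j]; i <- i + 1L; j <- j + 1L
    }
  }
  while (j <= lb) { n <- n + 1L; A[n] <- "-"; B[n] <- cloneChars[j]; j <- j + 1L }
  while (i <= la) { n <- n + 1L; A[n] <- consChars[i]; B[n] <- "-"; i <- i + 1L }
  A <- A[seq_len(n)]
  B <- B[seq_len(n)]
  if (sum(A != B) > 0.3 * la) return(NULL)
  list(a = A, b = B)
}

## classify the differences of one clone against the consensus.
## Returns a named count vector over .DAMAGE_TYPES, or NULL if unalignable.
.cloneEvents <- function(consensus, clone) {
  counts <- stats::setNames(integer(length(.DAMAGE_TYPES)), .DAMAGE_TYPES)
  cs <- as.character(consensus)
  cl <- as.character(clone)
  if (nchar(cs) == nchar(cl)) {
    a <- strsplit(cs, "")[[1L]]
    b <- strsplit(cl, "")[[1L]]
  } else {
    al <- .alignClone(strsplit(cs, "")[[1L]], strsplit(cl, "")[[1L]])
    if (is.null(al)) return(NULL)
    a <- al$a
    b <- al$b
  }
  diff <- which(a != b)
  for (i in diff) {
    key <- if (a[i] == "-") {           # insertion in the clone
      if (b[i] == "A") "insA" else if (b[i] == "G") "insG" else "other"
    } else if (b[i] == "-") {           # deletion in the clone
      "other"
    } else {
      k <- paste0(a[i], ">", b[i])
      if (k %in% .DAMAGE_TYPES) k else "other"
    }
    counts[key] <- counts[key] + 1L
  }
  counts
}

#' Profile post-mortem damage across clone sets
#'
#' Counts sequence changes of each type (\code{A>G}, \code{G>A}, \code{C>T},
#' \code{T>C}, single-base insertions of A or G, and \code{other}) in the
#' unique clones of each sample relative to its consensus, then aggregates to
#' per-sample totals and cross-sample means. Duplicate clone sequences within
#' a sample are counted once. Clones that cannot be aligned to the consensus
#' (length difference beyond small indels) are excluded with a warning.
#'
#' @param cloneSets list of [CloneSet-class] objects (or a single one).
#' @return A [DamageProfile-class].
#' @examples
#' cs <- cloneSet("s1", "ACGTACGT", c("ACGTACGT", "GCGTACGT"), locus = "mtdna")
#' damageProfile(list(cs))
#' @export
damageProfile <- function(cloneSets) {
  if (is(cloneSets, "CloneSet")) cloneSets <- list(cloneSets)
  stopifnot(length(cloneSets) >= 1L,
            all(vapply(cloneSets, is, logical(1), "CloneSet")))
  rows <- lapply(cloneSets, function(cs) {
    uniq <- unique(as.character(cs@clones))
    tot <- stats::setNames(integer(length(.DAMAGE_TYPES)), .DAMAGE_TYPES)
    for (cl in uniq) {
      ev <- .cloneEvents(cs@consensus, cl)
      if (is.null(ev)) {
        warning(sprintf("sample '%s': unalignable clone excluded", cs@sample))
        next
      }
      tot <- tot + ev
    }
    tot
  })
  perSample <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  perSample <- cbind(sample = vapply(cloneSets, function(x) x@sample, character(1)),
                     perSample, total = as.integer(rowSums(perSample)))
  meanPerType <- colMeans(perSample[.DAMAGE_TYPES])
  new("DamageProfile", perSample = perSample, meanPerType = meanPerType,
      meanTotal = sum(meanPerType), nSamples = length(cloneSets))
}

setMethod("show", "DamageProfile", function(object) {
  cat(sprintf("DamageProfile over %d sample(s): mean %.2f event(s)/sample\n",
              object@nSamples, object@meanTotal))
  nz <- object@meanPerType[object@meanPerType > 0]
  if (length(nz))
    cat("  per type:",
        paste(sprintf("%s = %.2f", names(nz), nz), collapse = ", "), "\n")
})

#' @describeIn damageProfile cross-sample mean of per-sample totals
#' @param profile a [DamageProfile-class].
#' @export
meanDamagePerSample <- function(profile) profile@meanTotal

#' Read clone sets from FASTA
#'
#' Record ids follow \code{<sample>|consensus} and \code{<sample>|clone<N>};
#' the consensus record of each sample must be present.
#'
#' @param file FASTA path.
#' @param locus locus tag attached to every set.
#' @return List of [CloneSet-class] objects.
#' @export
readCloneSets <- function(file, locus = "casp12") {
  seqs <- Biostrings::readDNAStringSet(file)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  samples <- vapply(parts, `[`, character(1), 1L)
  roles <- vapply(parts, `[`, character(1), 2L)
  lapply(unique(samples), function(s) {
    sel <- samples == s
    cons <- seqs[sel & roles == "consensus"]
    if (length(cons) != 1L)
      stop(sprintf("sample '%s': expected exactly one consensus record", s))
    cloneSet(s, Biostrings::DNAString(as.character(cons[[1L]])),
             seqs[sel & roles != "consensus"], locus = locus)
  })
}

#' Write clone sets to FASTA
#'
#' @param cloneSets list of [CloneSet-class].
#' @param file output FASTA path.
#' @return \code{file}, invisibly.
#' @export
writeCloneSets <- function(cloneSets, file) {
  all <- lapply(cloneSets, function(cs) {
    x <- c(Biostrings::DNAStringSet(cs@consensus), cs@clones)
    names(x) <- c(paste0(cs@sample, "|consensus"),
                  paste0(cs@sample, "|clone", seq_along(cs@clones)))
    x
  })
  Biostrings::writeXStringSet(do.call(c, all), file)
  invisible(file)
}

## ---------------------------------------------------------------------------
## haplotypes and contamination
## ---------------------------------------------------------------------------

.validateHaplotypes <- function(h, what) {
  needed <- c("id", "position", "ref", "alt")
  if (!all(needed %in% names(h)))
    stop(sprintf("%s must have columns %s", what, paste(needed, collapse = ", ")))
  if (any(h$position < .HVR1_RANGE[1] | h$position > .HVR1_RANGE[2]))
    stop(sprintf("%s: positions must lie in %d-%d", what,
                 .HVR1_RANGE[1], .HVR1_RANGE[2]))
  dup <- stats::aggregate(position ~ id, h, function(p) anyDuplicated(p) > 0)
  if (any(dup$position))
    stop(sprintf("%s: duplicate variant positions for id '%s'", what,
                 dup$id[dup$position][1L]))
  invisible(h)
}

.haplotypeKeys <- function(h) {
  ids <- unique(h$id)
  stats::setNames(vapply(ids, function(i) {
    v <- h[h$id == i, , drop = FALSE]
    v <- v[order(v$position), , drop = FALSE]
    paste(sprintf("%d%s>%s", v$position, v$ref, v$alt), collapse = ";")
  }, character(1)), ids)
}

#' Screen sample haplotypes against researcher haplotypes
#'
#' A sample is flagged as potentially contaminated when its full HVR-I
#' variant set is identical to a researcher's. Haplotypes shared between
#' samples (but matching no researcher) are reported as a note, not flagged:
#' the criterion is investigator-haplotype identity.
#'
#' @param sampleHaplotypes,researcherHaplotypes data.frames with columns
#'   \code{id}, \code{position}, \code{ref}, \code{alt}; one row per variant
#'   relative to the mtDNA reference over HVR-I (positions 15,998-16,400).
#'   Ids with no rows can be supplied via the \code{ids} arguments to
#'   represent reference-identical haplotypes.
#' @param sampleIds,researcherIds optional full id sets (defaults to the ids
#'   present in the variant tables).
#' @return List with \code{matches} (data.frame \code{sample},
#'   \code{researcher}), \code{passed} (no matches), and
#'   \code{sharedSampleHaplotypes} (list of sample-id groups sharing a
#'   haplotype).
#' @export
contaminationScreen <- function(sampleHaplotypes, researcherHaplotypes,
                                sampleIds = NULL, researcherIds = NULL) {
  .validateHaplotypes(sampleHaplotypes, "sampleHaplotypes")
  .validateHaplotypes(researcherHaplotypes, "researcherHaplotypes")
  sk <- .haplotypeKeys(sampleHaplotypes)
  rk <- .haplotypeKeys(researcherHaplotypes)
  if (!is.null(sampleIds))
    sk <- c(sk, stats::setNames(rep("", length(setdiff(sampleIds, names(sk)))),
                                setdiff(sampleIds, names(sk))))
  if (!is.null(researcherIds))
    rk <- c(rk, stats::setNames(rep("", length(setdiff(researcherIds, names(rk)))),
                                setdiff(researcherIds, names(rk))))
  hits <- which(outer(sk, rk, `==`), arr.ind = TRUE)
  matches <- data.frame(sample = names(sk)[hits[, 1L]],
                        researcher = names(rk)[hits[, 2L]],
                        stringsAsFactors = FALSE)
  shared <- split(names(sk), sk)
  shared <- unname(shared[vapply(shared, length, integer(1)) > 1L])
  list(matches = matches, passed = nrow(matches) == 0L,
       sharedSampleHaplotypes = shared)
}

#' Read haplotype variant tables from TSV
#'
#' @param file TSV with header \code{id}, \code{position}, \code{ref},
#'   \code{alt}.
#' @return data.frame in the haplotype format of [contaminationScreen()].
#' @export
readHaplotypes <- function(file) {
  h <- utils::read.delim(file, stringsAsFactors = FALSE)
  .validateHaplotypes(h, basename(file))
}

## ---------------------------------------------------------------------------
## replicate concordance and clone majority
## ---------------------------------------------------------------------------

#' Concordance of per-assay genotype calls
#'
#' A genotype is authenticated when at least two non-missing calls agree and
#' none disagree; discordant when any two non-missing calls differ;
#' unconfirmed when fewer than two non-missing calls are available (for
#' example when no PCR product could be obtained in one laboratory).
#'
#' @param calls character vector of genotype calls, \code{NA} for failed
#'   assays. At least one call (missing or not) must be supplied.
#' @return List with \code{status} (\code{"authenticated"},
#'   \code{"discordant"} or \code{"unconfirmed"}) and \code{genotype} (the
#'   agreed call, or \code{NA}).
#' @examples
#' genotypeConcordance(c("TT", "TT"))
#' genotypeConcordance(c("TT", NA))
#' genotypeConcordance(c("CT", "TT"))
#' @export
genotypeConcordance <- function(calls) {
  if (length(calls) == 0L) stop("need at least one call")
  ok <- calls[!is.na(calls)]
  if (length(unique(ok)) > 1L)
    return(list(status = "discordant", genotype = NA_character_))
  if (length(ok) >= 2L)
    return(list(status = "authenticated", genotype = unique(ok)))
  list(status = "unconfirmed",
       genotype = if (length(ok)) ok else NA_character_)
}

#' Majority check of clones at a site
#'
#' Passes when a strict majority of clones carries the consensus allele at
#' the given position; an exact tie fails with the tie flag set.
#'
#' @param cloneSetObj a [CloneSet-class] with at least 3 clones.
#' @param position 1-based position in the consensus sequence.
#' @return List with \code{pass}, \code{majorityFraction},
#'   \code{consensusAllele} and \code{tie}.
#' @export
cloneMajorityCheck <- function(cloneSetObj, position) {
  stopifnot(is(cloneSetObj, "CloneSet"))
  if (length(cloneSetObj@clones) < 3L) stop("need at least 3 clones")
  consLen <- length(cloneSetObj@consensus)
  if (position < 1L || position > consLen)
    stop("'position' outside the consensus sequence")
  consAllele <- as.character(cloneSetObj@consensus[position])
  consChars <- strsplit(as.character(cloneSetObj@consensus), "")[[1L]]
  cloneBase <- vapply(seq_along(cloneSetObj@clones), function(i) {
    cl <- as.character(cloneSetObj@clones[[i]])
    if (nchar(cl) == consLen) return(substr(cl, position, position))
    al <- .alignClone(consChars, strsplit(cl, "")[[1L]])
    if (is.null(al)) return(NA_character_)
    idx <- which(cumsum(al$a != "-") == position & al$a != "-")[1L]
    al$b[idx]
  }, character(1))
  frac <- mean(cloneBase == consAllele)
  list(pass = frac > 0.5, majorityFraction = frac,
       consensusAllele = consAllele, tie = frac == 0.5)
}

## ---------------------------------------------------------------------------
## qPCR quantitation
## ---------------------------------------------------------------------------

#' Fit a qPCR standard curve
#'
#' Least-squares regression of threshold cycle on log10 template copies over
#' a serial dilution; amplification efficiency is
#' \eqn{E = 10^{-1/slope} - 1} (perfect doubling gives slope
#' \eqn{-1/\log_{10} 2 \approx -3.3219} and \eqn{E = 1}).
#'
#' @param series data.frame with columns \code{copies_per_ul} and \code{ct}
#'   (a \code{replicate} column is allowed and ignored by the fit). At least
#'   3 distinct concentrations are required.
#' @return A [StandardCurve-class].
#' @examples
#' s <- data.frame(copies_per_ul = rep(c(1.4e4, 1.4e5, 1.4e6), each = 4))
#' s$ct <- 30 - log10(s$copies_per_ul) / log10(2)
#' fitStandardCurve(s)
#' @export
fitStandardCurve <- function(series) {
  if (!all(c("copies_per_ul", "ct") %in% names(series)))
    stop("'series' must have columns copies_per_ul and ct")
  if (any(series$copies_per_ul <= 0)) stop("copy numbers must be positive")
  lc <- log10(series$copies_per_ul)
  if (length(unique(lc)) < 3L)
    stop("need at least 3 distinct concentrations to fit a standard curve")
  fit <- stats::lm(ct ~ lc, data = data.frame(ct = series$ct, lc = lc))
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope == 0) stop("degenerate fit: zero slope")
  r2 <- summary(fit)$r.squared
  new("StandardCurve", slope = slope,
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = min(1, max(0, r2)),
      efficiency = 10^(-1 / slope) - 1, n = nrow(series))
}

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: slope %.4f, intercept %.2f, r^2 = %.4f\n",
              object@slope, object@intercept, object@rSquared))
  cat(sprintf("  efficiency = %.1f%% (n = %d)\n", 100 * object@efficiency,
              object@n))
})

#' Predicted Ct at a template quantity
#'
#' @param curve a [StandardCurve-class].
#' @param copies template copies per microlitre.
#' @return Predicted threshold cycle.
#' @export
predictCt <- function(curve, copies) {
  stopifnot(is(curve, "StandardCurve"), all(copies > 0))
  curve@intercept + curve@slope * log10(copies)
}

#' Quantify an extract from its Ct
#'
#' Inverts the standard curve: \eqn{copies = 10^{(Ct - intercept)/slope}}.
#'
#' @param ct observed threshold cycle.
#' @param curve a [StandardCurve-class].
#' @return Template copies per microlitre.
#' @export
quantifyExtract <- function(ct, curve) {
  stopifnot(is(curve, "StandardCurve"))
  if (curve@slope == 0) stop("degenerate curve: zero slope")
  10^((ct - curve@intercept) / curve@slope)
}
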