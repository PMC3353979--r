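# shared fixtures and independent oracles

# single constant-size population model
constantModel <- function(N = 500, tEnd = 0.01) {
  demographicModel(list(N0 = N, t_end = tEnd, populations = list("P")))
}

# do the 95% binomial CIs of two estimates (k1/n1 and a reference proportion
# assessed at the same design size) overlap?
ciOverlap <- function(k1, n1, pRef, nRef = n1) {
  ci1 <- stats::binom.test(k1, n1)$conf.int
  ci2 <- stats::binom.test(round(pRef * nRef), nRef)$conf.int
  ci1[1] <= ci2[2] && ci2[1] <= ci1[2]
}

# independent position-by-position damage counter for equal-length clones:
# tabulates consensus->clone base pairs, no shared code with the profiler
oracleDamageCounts <- function(consensus, clones) {
  a <- strsplit(consensus, "")[[1L]]
  types <- c("A>G", "G>A", "C>T", "T>C")
  out <- setNames(numeric(length(types) + 1L), c(types, "other"))
  for (cl in unique(clones)) {
    b <- strsplit(cl, "")[[1L]]
    stopifnot(length(a) == length(b))
    for (i in which(a != b)) {
      key <- paste0(a[i], ">", b[i])
      if (!key %in% types) key <- "other"
      out[key] <- out[key] + 1
    }
  }
  out
}

# random equal-length mutated clone set for oracle comparisons
randomCloneSet <- function(seed, len = 60, nClones = 8, pMut = 0.03) {
  withr::with_seed(seed, {
    cons <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    clones <- vapply(seq_len(nClones), function(i) {
      b <- strsplit(cons, "")[[1L]]
      hit <- which(runif(len) < pMut)
      for (p in hit) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
      paste(b, collapse = "")
    }, character(1))
    list(consensus = cons, clones = clones)
  })
}
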