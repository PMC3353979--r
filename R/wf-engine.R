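## Seeded single-locus forward Wright-Fisher simulator with selection,
## migration and the demographic timeline. Per generation and population the
## operator order is: migration (deterministic migrant-pool mixing of
## expected frequencies), selection (the deterministic recursion), then a
## single binomial draw of next-generation allele counts.

## ---------------------------------------------------------------------------
## generation plan
## ---------------------------------------------------------------------------

## Precompute per-generation sizes, founding generations/parents and
## per-transition migration-fraction matrices for a model.
.compilePlan <- function(model) {
  N0 <- model@N0
  G <- as.integer(round(model@tEnd * 2 * N0))
  pops <- model@populations
  np <- length(pops)
  founded <- .foundingTimes(model)
  foundGen <- vapply(pops, function(p)
    as.integer(round(founded[[p]] * 2 * N0)), integer(1))
  parent <- stats::setNames(rep(NA_character_, np), pops)
  sp <- model@events[model@events$kind == "split", , drop = FALSE]
  for (i in seq_len(nrow(sp))) parent[[sp$pop2[i]]] <- sp$pop[i]

  sizes <- matrix(NA_real_, nrow = G + 1L, ncol = np,
                  dimnames = list(NULL, pops))
  for (g in 0:G) {
    t <- g / (2 * N0)
    st <- .sizeState(model, t)
    for (k in seq_len(np)) {
      p <- pops[k]
      if (g >= foundGen[[p]]) sizes[g + 1L, k] <- max(2, round(st$size[[p]]))
    }
  }

  ## migration fractions for the transition g-1 -> g use the payloads in
  ## force at generation g-1 and (for the copies convention) the sizes at
  ## generation g-1
  migGens <- unique(c(0L, vapply(
    model@events$time[model@events$kind == "migration_change"],
    function(t) as.integer(round(t * 2 * N0)), integer(1))))
  frac <- array(0, dim = c(np, np, G + 1L))
  cur <- matrix(0, np, np)
  for (g in 0:G) {
    if (g %in% migGens || model@migrationConvention == "copies") {
      M <- .migrationPayloadAt(model, g / (2 * N0))
      cur <- switch(model@migrationConvention,
        "4N0m" = M / (4 * N0),
        "2N0m" = M / (2 * N0),
        copies = {
          m <- M / (2 * sizes[g + 1L, ])
          m[!is.finite(m)] <- 0
          m
        })
    }
    frac[, , g + 1L] <- cur
  }
  list(G = G, pops = pops, np = np, sizes = sizes, foundGen = foundGen,
       parent = parent, frac = frac,
       recordGens = vapply(model@recordTimes, function(t)
         as.integer(round(t * 2 * N0)), integer(1)))
}

## one transition of the vectorized engine: counts is np x R at generation g,
## returns np x R at generation g + 1
.advanceCounts <- function(counts, g, plan, w) {
  szNow <- plan$sizes[g + 1L, ]
  szNext <- plan$sizes[g + 2L, ]
  R <- ncol(counts)
  p <- counts / (2 * szNow)
  p[is.na(p)] <- 0
  m <- plan$frac[, , g + 1L, drop = FALSE]
  dim(m) <- dim(plan$frac)[1:2]
  Mop <- diag(1 - rowSums(m), plan$np) + m
  p <- Mop %*% p
  p <- .stepFreq(p, w)
  out <- matrix(NA_real_, plan$np, R)
  for (k in seq_len(plan$np)) {
    if (is.na(szNext[k])) next
    src <- if (is.na(szNow[k])) match(plan$parent[[plan$pops[k]]], plan$pops) else k
    out[k, ] <- stats::rbinom(R, 2 * szNext[k], p[src, ])
  }
  out
}

## ---------------------------------------------------------------------------
## exported state-level operations
## ---------------------------------------------------------------------------

#' Create an initial locus state
#'
#' All populations founded at time 0 start monomorphic ancestral (count 0);
#' unfounded populations carry \code{NA}.
#'
#' @param model a [DemographicModel-class].
#' @param nReplicates number of vectorized replicates carried in the state.
#' @return A [LocusState-class] at generation 0.
#' @export
newLocusState <- function(model, nReplicates = 1L) {
  stopifnot(is(model, "DemographicModel"))
  st <- .sizeState(model, 0)
  founded <- .foundingTimes(model)
  sizes <- vapply(model@populations, function(p)
    if (founded[[p]] == 0) max(2, round(st$size[[p]])) else NA_real_, numeric(1))
  counts <- matrix(ifelse(is.na(sizes), NA_real_, 0), nrow = length(sizes),
                   ncol = nReplicates,
                   dimnames = list(model@populations, NULL))
  new("LocusState", counts = counts, sizes = sizes, generation = 0L)
}

#' Inject a single derived mutation
#'
#' Places exactly one derived allele copy in the named population; all other
#' populations are untouched. The state must be monomorphic ancestral and its
#' generation must correspond to \code{t}.
#'
#' @param state a [LocusState-class].
#' @param model the [DemographicModel-class] the state evolves under.
#' @param pop population receiving the mutation.
#' @param t scaled time of origin; must round to the state's current
#'   generation.
#' @return The updated [LocusState-class].
#' @export
injectMutation <- function(state, model, pop, t) {
  stopifnot(is(state, "LocusState"), is(model, "DemographicModel"))
  if (!pop %in% model@populations) stop("unknown population: ", pop)
  i <- match(pop, model@populations)
  if (is.na(state@sizes[i]))
    stop(sprintf("population '%s' is not founded at the current generation", pop))
  if (scaledToGenerations(model, t) != state@generation)
    stop(sprintf("origin time %g does not correspond to the current generation %d",
                 t, state@generation))
  if (any(state@counts > 0, na.rm = TRUE))
    stop("locus already carries the derived allele; double injection")
  state@counts[i, ] <- 1
  validObject(state)
  state
}

#' Advance a locus state by one generation
#'
#' Applies, in order: deterministic migrant-pool mixing of expected
#' frequencies, the deterministic selection recursion, then a binomial draw
#' of next-generation counts at next-generation sizes. Populations founded at
#' the next generation draw their founding counts binomially at the parent's
#' post-migration, post-selection frequency.
#'
#' @param state a [LocusState-class].
#' @param model the [DemographicModel-class].
#' @param scheme a [FitnessScheme-class].
#' @return The state at the next generation.
#' @export
advanceGeneration <- function(state, model, scheme) {
  stopifnot(is(state, "LocusState"), is(model, "DemographicModel"),
            is(scheme, "FitnessScheme"))
  plan <- .compilePlan(model)
  g <- state@generation
  if (g >= plan$G) stop("state is already at the end of the timeline")
  counts <- .advanceCounts(state@counts, g, plan, .viabilities(scheme))
  rownames(counts) <- model@populations
  new("LocusState", counts = counts, sizes = plan$sizes[g + 2L, ],
      generation = g + 1L)
}

setMethod("show", "LocusState", function(object) {
  cat(sprintf("LocusState: generation %d, %d replicate(s)\n",
              object@generation, ncol(object@counts)))
  for (i in seq_len(nrow(object@counts))) {
    nm <- rownames(object@counts)[i]
    if (is.na(object@sizes[i])) {
      cat(sprintf("  %s: not founded\n", nm))
    } else {
      cat(sprintf("  %s: N = %d, mean frequency %.4g\n", nm, object@sizes[i],
                  mean(object@counts[i, ]) / (2 * object@sizes[i])))
    }
  }
})

## ---------------------------------------------------------------------------
## replicate-level simulation
## ---------------------------------------------------------------------------

#' Simulate forward Wright-Fisher replicates
#'
#' Runs \code{nReplicates} independent single-locus replicates from
#' generation 0 to the end of the timeline. Each replicate injects a single
#' derived allele copy into \code{originPop} at an independent uniform scaled
#' time in \code{originWindow}, then evolves under migration, selection and
#' binomial drift. Deterministic given \code{seed}.
#'
#' @param model a [DemographicModel-class].
#' @param scheme a [FitnessScheme-class].
#' @param nReplicates number of replicates.
#' @param seed integer seed.
#' @param originWindow scaled-time interval for the mutation origin
#'   (default \code{c(0.001, 0.003)}).
#' @param originPop population of origin (default the ancestral population).
#' @return A data.frame with one row per replicate: \code{origin_time},
#'   final \code{freq_<pop>} per population, \code{freq_<pop>_at_<label>} for
#'   every record time, and \code{fate} (\code{"lost"}, \code{"segregating"}
#'   or \code{"fixed_global"}).
#' @examples
#' m <- ooaScaledModel()
#' r <- simulateReplicates(m, neutralScheme(), nReplicates = 20, seed = 1)
#' table(r$fate)
#' @export
simulateReplicates <- function(model, scheme, nReplicates, seed,
                               originWindow = c(0.001, 0.003),
                               originPop = model@populations[1L]) {
  stopifnot(is(model, "DemographicModel"), is(scheme, "FitnessScheme"))
  if (length(originWindow) != 2L || originWindow[1] > originWindow[2] ||
      originWindow[1] < 0 || originWindow[2] > model@tEnd)
    stop("'originWindow' must be an interval within [0, tEnd]")
  plan <- .compilePlan(model)
  oi <- match(originPop, model@populations)
  if (is.na(oi)) stop("unknown population: ", originPop)
  if (plan$foundGen[[originPop]] > round(originWindow[1] * 2 * model@N0))
    stop(sprintf("population '%s' is not founded inside the origin window",
                 originPop))
  withr::with_seed(as.integer(seed), {
    .simulateBatch(plan, .viabilities(scheme), as.integer(nReplicates), oi,
                   originWindow, model@N0)
  })
}

## the actual engine; consumes the current RNG stream
.simulateBatch <- function(plan, w, R, originIdx, originWindow, N0) {
  G <- plan$G
  np <- plan$np
  originTime <- stats::runif(R, originWindow[1], originWindow[2])
  injGen <- pmax(1L, as.integer(round(originTime * 2 * N0)))
  counts <- matrix(NA_real_, np, R)
  for (k in seq_len(np))
    if (!is.na(plan$sizes[1L, k])) counts[k, ] <- 0
  recs <- vector("list", length(plan$recordGens))
  names(recs) <- names(plan$recordGens)
  for (g in 0:(G - 1L)) {
    counts <- .advanceCounts(counts, g, plan, w)
    gNext <- g + 1L
    if (gNext <= max(injGen)) {
      idx <- which(injGen == gNext)
      if (length(idx)) counts[originIdx, idx] <- 1
    }
    hit <- which(plan$recordGens == gNext)
    for (j in hit) recs[[j]] <- counts / (2 * plan$sizes[gNext + 1L, ])
  }
  szEnd <- plan$sizes[G + 1L, ]
  freq <- counts / (2 * szEnd)
  founded <- which(!is.na(szEnd))
  tot <- colSums(counts[founded, , drop = FALSE])
  full <- colSums(counts[founded, , drop = FALSE] ==
                  2 * szEnd[founded]) == length(founded)
  fate <- ifelse(tot == 0, "lost", ifelse(full, "fixed_global", "segregating"))
  out <- data.frame(origin_time = originTime)
  for (k in seq_len(np)) out[[paste0("freq_", plan$pops[k])]] <- freq[k, ]
  for (j in seq_along(recs)) {
    lab <- names(recs)[j]
    for (k in seq_len(np)) {
      v <- recs[[j]][k, ]
      if (!all(is.na(v)))
        out[[paste0("freq_", plan$pops[k], "_at_", lab)]] <- v
    }
  }
  out$fate <- fate
  out
}

#' Simulate a single replicate
#'
#' @inheritParams simulateReplicates
#' @return A one-row data.frame (see [simulateReplicates()]).
#' @export
simulateReplicate <- function(model, scheme, seed,
                              originWindow = c(0.001, 0.003),
                              originPop = model@populations[1L]) {
  simulateReplicates(model, scheme, nReplicates = 1L, seed = seed,
                     originWindow = originWindow, originPop = originPop)
}

#' Fate of new mutants in a constant-size population
#'
#' Light-weight Wright-Fisher runs in a single population of constant diploid
#' size \code{N}, starting from \code{initialCount} derived copies, iterated
#' until loss or fixation (or \code{maxGenerations}). Used for the classical
#' fixation-probability checks against diffusion theory.
#'
#' @param scheme a [FitnessScheme-class].
#' @param N constant diploid size.
#' @param nReplicates number of replicates.
#' @param seed integer seed.
#' @param initialCount starting derived-allele copies (default 1, a new
#'   mutant).
#' @param maxGenerations absorption guard.
#' @return Character vector of fates: \code{"lost"}, \code{"fixed"} or
#'   \code{"segregating"} (hit the guard).
#' @examples
#' f <- simulateFixation(neutralScheme(), N = 50, nReplicates = 500, seed = 1)
#' mean(f == "fixed")  # ~ 1/(2N)
#' @export
simulateFixation <- function(scheme, N, nReplicates, seed, initialCount = 1L,
                             maxGenerations = 200000L) {
  stopifnot(is(scheme, "FitnessScheme"), N >= 2)
  w <- .viabilities(scheme)
  withr::with_seed(as.integer(seed), {
    cnt <- rep(as.integer(initialCount), nReplicates)
    fate <- rep("segregating", nReplicates)
    active <- seq_len(nReplicates)
    twoN <- as.integer(2 * N)
    g <- 0L
    while (length(active) && g < maxGenerations) {
      p <- .stepFreq(cnt[active] / twoN, w)
      cnt[active] <- stats::rbinom(length(active), twoN, p)
      lost <- cnt[active] == 0L
      fixed <- cnt[active] == twoN
      fate[active[lost]] <- "lost"
      fate[active[fixed]] <- "fixed"
      active <- active[!(lost | fixed)]
      g <- g + 1L
    }
    fate
  })
}

#' Diffusion approximation to the fixation probability
#'
#' Kimura's formula \eqn{u(p) = (1 - e^{-4Nsp}) / (1 - e^{-4Ns})} for a
#' semidominant allele with per-copy advantage \code{s}; for a new mutant
#' (\eqn{p = 1/2N}) this is \eqn{(1 - e^{-2s}) / (1 - e^{-4Ns})}.
#'
#' @param N diploid population size.
#' @param s per-allele-copy selection coefficient.
#' @param p initial frequency (default a single new copy).
#' @return Fixation probability.
#' @export
diffusionFixationProb <- function(N, s, p = 1 / (2 * N)) {
  if (s == 0) return(p)
  (1 - exp(-4 * N * s * p)) / (1 - exp(-4 * N * s))
}
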