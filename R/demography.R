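## Scaled three-population Out-of-Africa demographic timeline: data model,
## YAML loader and size/migration queries. All times are in units of 2*N0
## generations, forward from the start of the simulation.

## founding time per population: the ancestral population (and any population
## never created by a split) exists from time 0; split daughters from the
## split time.
.foundingTimes <- function(model) {
  ev <- model@events
  out <- stats::setNames(rep(0, length(model@populations)), model@populations)
  if (nrow(ev)) {
    sp <- ev[ev$kind == "split", , drop = FALSE]
    for (i in seq_len(nrow(sp))) out[[sp$pop2[i]]] <- sp$time[i]
  }
  out
}

#' Construct a demographic model from a configuration list
#'
#' @param config list with elements \code{N0}, \code{t_end}, \code{populations},
#'   \code{events} (list of \code{time}, \code{kind}, \code{pop}, optional
#'   \code{pop2}, optional \code{value}), and optional \code{record_times}
#'   (named), \code{kappa}, \code{generation_time_years},
#'   \code{migration_convention}.
#' @return A validated [DemographicModel-class].
#' @seealso [loadDemographicModel()] to read the same structure from YAML,
#'   [ooaScaledModel()] for the packaged scaled Out-of-Africa fixture.
#' @export
demographicModel <- function(config) {
  needed <- c("N0", "t_end", "populations")
  missing <- setdiff(needed, names(config))
  if (length(missing))
    stop("configuration is missing field(s): ", paste(missing, collapse = ", "))
  evl <- config$events
  if (is.null(evl)) evl <- list()
  ev <- if (length(evl)) {
    do.call(rbind, lapply(seq_along(evl), function(i) {
      e <- evl[[i]]
      for (f in c("time", "kind", "pop"))
        if (is.null(e[[f]]))
          stop(sprintf("event %d is missing field '%s'", i, f))
      data.frame(time = as.numeric(e$time), kind = as.character(e$kind),
                 pop = as.character(e$pop),
                 pop2 = if (is.null(e$pop2)) NA_character_ else as.character(e$pop2),
                 value = if (is.null(e$value)) NA_real_ else as.numeric(e$value),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(time = numeric(), kind = character(), pop = character(),
               pop2 = character(), value = numeric(), stringsAsFactors = FALSE)
  }
  rt <- unlist(config$record_times)
  if (is.null(rt)) rt <- stats::setNames(numeric(), character())
  new("DemographicModel",
      N0 = as.integer(config$N0),
      populations = as.character(config$populations),
      events = ev,
      tEnd = as.numeric(config$t_end),
      recordTimes = rt,
      kappa = if (is.null(config$kappa)) 1 else as.numeric(config$kappa),
      generationTime = if (is.null(config$generation_time_years)) 25
                       else as.numeric(config$generation_time_years),
      migrationConvention = if (is.null(config$migration_convention)) "copies"
                            else as.character(config$migration_convention))
}

#' Load a demographic model from a YAML file
#'
#' @param file path to a YAML configuration (see [demographicModel()] for the
#'   expected keys).
#' @return A validated [DemographicModel-class].
#' @export
loadDemographicModel <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  demographicModel(yaml::read_yaml(file))
}

#' Serialize a demographic model back to YAML
#'
#' @param model a [DemographicModel-class].
#' @param file output path.
#' @return \code{file}, invisibly. Reloading reproduces an identical model.
#' @export
writeDemographicModel <- function(model, file) {
  ev <- model@events
  config <- list(
    N0 = model@N0,
    t_end = model@tEnd,
    generation_time_years = model@generationTime,
    kappa = model@kappa,
    migration_convention = model@migrationConvention,
    populations = as.list(model@populations),
    record_times = as.list(model@recordTimes),
    events = lapply(seq_len(nrow(ev)), function(i) {
      e <- list(time = ev$time[i], kind = ev$kind[i], pop = ev$pop[i])
      if (!is.na(ev$pop2[i])) e$pop2 <- ev$pop2[i]
      if (!is.na(ev$value[i])) e$value <- ev$value[i]
      e
    }))
  yaml::write_yaml(config, file, precision = 12L)
  invisible(file)
}

#' The packaged scaled Out-of-Africa model
#'
#' Three populations (AFR, EUR, ASN) scaled to an ancestral effective size of
#' 500 diploids: an African size reduction, re-expansion and growth to 841;
#' a European founding bottleneck at scaled time 0.211074; an Asian split
#' from Europe at 0.534772 with exponential growth in both daughters;
#' time-varying asymmetric migration; end of simulation at 0.607. A record
#' point at scaled time 0.5895 (= 0.607 - 0.0175) captures the European
#' frequency at approximately 7,000 years before present under the default
#' 25-year generation time.
#'
#' @param migrationConvention override the migration payload interpretation
#'   (default \code{"copies"}; see [DemographicModel-class]).
#' @return A [DemographicModel-class].
#' @examples
#' m <- ooaScaledModel()
#' populationSizeAt(m, "AFR", 0.6)
#' @export
ooaScaledModel <- function(migrationConvention = "copies") {
  f <- system.file("extdata", "ooa_scaled.yaml", package = "paleosweep",
                   mustWork = TRUE)
  m <- loadDemographicModel(f)
  m@migrationConvention <- migrationConvention
  validObject(m)
  m
}

#' Convert scaled time to a generation index
#'
#' @param model a [DemographicModel-class].
#' @param t scaled time in \code{[0, tEnd]} (units of \eqn{2 N_0}
#'   generations).
#' @return Integer generation index \code{round(t * 2 * N0)}.
#' @export
scaledToGenerations <- function(model, t) {
  stopifnot(is(model, "DemographicModel"))
  if (any(t < 0 | t > model@tEnd + 1e-12))
    stop("'t' must lie in [0, tEnd]")
  as.integer(round(t * 2 * model@N0))
}

#' Convert scaled time to years before present
#'
#' Real calendar time per scaled unit is \eqn{2 N_0 \kappa} generations:
#' the run is compressed by the size ratio \code{kappa}, so drift per scaled
#' step is faster and one scaled generation stands for \code{kappa} real
#' ones. \code{kappa} affects year conversions only, never the dynamics.
#'
#' @param model a [DemographicModel-class].
#' @param t scaled time.
#' @return Years before present of the scaled time point.
#' @export
scaledToYearsBP <- function(model, t) {
  (model@tEnd - t) * 2 * model@N0 * model@kappa * model@generationTime
}

## sequential scan of the event list up to (and including) time t, tracking
## continuous sizes and growth rates; events at equal time apply in listed
## order (split before same-time size changes).
.sizeState <- function(model, t) {
  pops <- model@populations
  np <- length(pops)
  size <- stats::setNames(rep(NA_real_, np), pops)
  growth <- stats::setNames(rep(0, np), pops)
  lastT <- stats::setNames(rep(0, np), pops)
  founded <- .foundingTimes(model)
  for (p in pops) if (founded[[p]] == 0) size[[p]] <- model@N0
  ev <- model@events
  grow <- function(p, to) {
    if (!is.na(size[[p]]) && growth[[p]] != 0 && to > lastT[[p]])
      size[[p]] <<- size[[p]] * exp(growth[[p]] * (to - lastT[[p]]))
    lastT[[p]] <<- to
  }
  for (i in seq_len(nrow(ev))) {
    if (ev$time[i] > t + 1e-12) break
    p <- ev$pop[i]
    grow(p, ev$time[i])
    switch(ev$kind[i],
      split = {
        d <- ev$pop2[i]
        if (is.na(size[[p]]))
          stop(sprintf("split daughter '%s' founded from unfounded population '%s'", d, p))
        size[[d] ] <- size[[p]]
        lastT[[d]] <- ev$time[i]
      },
      size_change = {
        if (is.na(size[[p]]))
          stop(sprintf("size change on unfounded population '%s'", p))
        size[[p]] <- size[[p]] * ev$value[i]
      },
      growth_rate_change = {
        growth[[p]] <- ev$value[i]
      },
      migration_change = NULL)
  }
  for (p in pops) grow(p, t)
  list(size = size, growth = growth)
}

#' Diploid population size at a scaled time
#'
#' Applies all size multipliers and exponential growth
#' \eqn{N(t) = N(t_g) e^{\alpha (t - t_g)}} up to \code{t}; events at exactly
#' \code{t} are included.
#'
#' @param model a [DemographicModel-class].
#' @param pop population label.
#' @param t scaled time.
#' @return Integer diploid size (rounded, at least 2).
#' @export
populationSizeAt <- function(model, pop, t) {
  stopifnot(is(model, "DemographicModel"))
  if (!pop %in% model@populations) stop("unknown population: ", pop)
  if (t < 0 || t > model@tEnd + 1e-12) stop("'t' must lie in [0, tEnd]")
  founded <- .foundingTimes(model)
  if (t < founded[[pop]] - 1e-12)
    stop(sprintf("population '%s' is not founded until scaled time %g",
                 pop, founded[[pop]]))
  st <- .sizeState(model, t)
  max(2L, as.integer(round(st$size[[pop]])))
}

## raw migration payload matrix (receiving pop x source pop) in force at
## scaled time t: latest migration_change per ordered pair wins.
.migrationPayloadAt <- function(model, t) {
  pops <- model@populations
  np <- length(pops)
  M <- matrix(0, np, np, dimnames = list(pops, pops))
  ev <- model@events
  mi <- which(ev$kind == "migration_change" & ev$time <= t + 1e-12)
  for (i in mi) M[ev$pop[i], ev$pop2[i]] <- ev$value[i]
  M
}

#' Per-generation migration fractions at a scaled time
#'
#' Converts the migration payloads in force at time \code{t} into
#' per-generation replacement fractions \eqn{m_{ij}} (fraction of population
#' \eqn{i} replaced by migrants from \eqn{j}), according to the model's
#' migration convention.
#'
#' @param model a [DemographicModel-class].
#' @param t scaled time.
#' @return Matrix of per-generation fractions, receiving population in rows.
#' @export
migrationRatesAt <- function(model, t) {
  M <- .migrationPayloadAt(model, t)
  switch(model@migrationConvention,
    "4N0m" = M / (4 * model@N0),
    "2N0m" = M / (2 * model@N0),
    copies = {
      st <- .sizeState(model, t)
      sz <- round(st$size)
      sz[!is.na(sz) & sz < 2] <- 2
      m <- M / (2 * sz[rownames(M)])
      m[is.na(m)] <- 0
      m
    })
}

setMethod("show", "DemographicModel", function(object) {
  cat(sprintf("DemographicModel: %d population(s) [%s], N0 = %d\n",
              length(object@populations),
              paste(object@populations, collapse = ", "), object@N0))
  cat(sprintf("  tEnd = %g (%d generations); %d event(s); convention '%s'\n",
              object@tEnd, round(object@tEnd * 2 * object@N0),
              nrow(object@events), object@migrationConvention))
  if (length(object@recordTimes))
    cat("  record times:",
        paste(sprintf("%s = %g", names(object@recordTimes), object@recordTimes),
              collapse = ", "), "\n")
})
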