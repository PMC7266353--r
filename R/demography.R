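#' Define a randomly-mating population
#'
#' Population size follows the backward exponential convention
#' `N(t) = N0 * exp(-growth_rate * t)`: with a positive growth rate the
#' population shrinks going into the past (i.e. it has been growing forward
#' in time). The Hudson engine uses `N(t)` as a continuous quantity; the
#' discrete-time Wright-Fisher engine rounds it to the nearest integer with a
#' floor of one diploid individual.
#'
#' @param size initial (time 0) diploid size `N0`, at least 1.
#' @param growth_rate per-generation exponential growth rate `alpha`.
#' @return A `population` object.
#' @examples
#' population(10000, growth_rate = 0.001)
#' @export
population <- function(size, growth_rate = 0) {
  if (!is.finite(size) || size < 1) stop("`size` must be >= 1", call. = FALSE)
  if (!is.finite(growth_rate)) stop("`growth_rate` must be finite", call. = FALSE)
  structure(list(size = as.numeric(size), growth_rate = as.numeric(growth_rate)),
            class = "population")
}

#' Population size t generations in the past
#'
#' @param pop a [population()].
#' @param t time in generations (>= 0); vectorised.
#' @param discrete round to the nearest integer with a floor of 1, as the
#'   DTWF engine does each generation.
#' @return Diploid size(s) at time `t`.
#' @examples
#' population_size_at(population(10000, 0.001), 1000) # 10000 * exp(-1)
#' @export
population_size_at <- function(pop, t, discrete = FALSE) {
  stopifnot(inherits(pop, "population"), all(t >= 0))
  n <- pop$size * exp(-pop$growth_rate * t)
  if (discrete) pmax(1, round(n)) else n
}

#' Demographic events
#'
#' Events are applied at a time `t` generations in the past. `size_change`
#' resets a population's initial size from that time backwards;
#' `growth_change` resets its growth rate (the size stays continuous);
#' `pulse_migration` is a one-generation admixture pulse in which each
#' lineage currently in `dest` derives its parent from `source` with
#' probability `fraction`, and a census node is recorded on every extant
#' lineage so that ancestry can be attributed afterwards (see
#' [ancestry_fractions()]).
#'
#' @param time event time in generations (>= 0). For the DTWF engine event
#'   times should be integers.
#' @param population,dest,source 1-based population indices.
#' @param size,growth_rate,fraction event parameters.
#' @return An event object usable in [demographic_model()].
#' @name demographic-events
NULL

#' @rdname demographic-events
#' @export
size_change <- function(time, population, size) {
  stopifnot(time >= 0, size >= 1)
  structure(list(time = time, kind = "size_change",
                 population = as.integer(population), value = as.numeric(size)),
            class = "demographic_event")
}

#' @rdname demographic-events
#' @export
growth_change <- function(time, population, growth_rate) {
  stopifnot(time >= 0, is.finite(growth_rate))
  structure(list(time = time, kind = "growth_change",
                 population = as.integer(population),
                 value = as.numeric(growth_rate)),
            class = "demographic_event")
}

#' @rdname demographic-events
#' @export
pulse_migration <- function(time, dest, source, fraction) {
  if (fraction < 0 || fraction > 1) {
    stop("pulse `fraction` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(time >= 0)
  structure(list(time = time, kind = "pulse", dest = as.integer(dest),
                 source = as.integer(source), fraction = as.numeric(fraction)),
            class = "demographic_event")
}

#' Assemble a demographic model
#'
#' @param populations a list of [population()] objects (or a single one).
#' @param migration square matrix of backward per-generation migration
#'   probabilities: `migration[i, j]` is the probability that a lineage in
#'   population `i` has its parent drawn from population `j`. Off-diagonal
#'   entries must lie in `[0, 1]` with row sums (excluding the diagonal) at
#'   most 1. The Hudson engine uses the same numbers as continuous rates.
#' @param events list of demographic events (see [size_change()],
#'   [growth_change()], [pulse_migration()]).
#' @return A `demographic_model`.
#' @examples
#' demographic_model(
#'   populations = list(population(80), population(80)),
#'   events = list(pulse_migration(time = 5, dest = 1, source = 2, fraction = 0.3))
#' )
#' @export
demographic_model <- function(populations, migration = NULL, events = list()) {
  if (inherits(populations, "population")) populations <- list(populations)
  stopifnot(length(populations) >= 1,
            all(vapply(populations, inherits, TRUE, "population")))
  np <- length(populations)
  if (is.null(migration)) migration <- matrix(0, np, np)
  migration <- as.matrix(migration)
  if (!all(dim(migration) == np)) {
    stop("`migration` must be a ", np, "x", np, " matrix", call. = FALSE)
  }
  off <- migration
  diag(off) <- 0
  if (any(off < 0 | off > 1) || any(rowSums(off) > 1)) {
    stop("off-diagonal migration entries must be in [0,1] with row sums <= 1",
         call. = FALSE)
  }
  if (inherits(events, "demographic_event")) events <- list(events)
  stopifnot(all(vapply(events, inherits, TRUE, "demographic_event")))
  for (e in events) {
    pops <- c(e$population, e$dest, e$source)
    if (any(pops < 1 | pops > np)) {
      stop("event refers to population outside the model", call. = FALSE)
    }
  }
  events <- events[order(vapply(events, `[[`, 0, "time"))]
  structure(list(populations = populations, migration = migration,
                 events = events),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("<demographic_model> %d population(s), %d event(s)\n",
              length(x$populations), length(x$events)))
  for (i in seq_along(x$populations)) {
    p <- x$populations[[i]]
    cat(sprintf("  pop %d: N0 = %g, growth = %g\n", i, p$size, p$growth_rate))
  }
  invisible(x)
}
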