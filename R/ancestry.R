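#' Per-sample migrant ancestry fractions after an admixture pulse
#'
#' A pulse migration event records a census node on every extant lineage at
#' the pulse generation (see [pulse_migration()]). Each sample's ancestry
#' fraction is the share of its genome (in map length, excluding spacer
#' gaps) whose ancestral lineage at the census sat in the migrant source
#' population. The across-sample variance of these fractions is the
#' statistic that separates diploid Wright-Fisher dynamics from the
#' coalescent in the first generations after admixture.
#'
#' @param sim a `genealogy` whose configuration included a
#'   [pulse_migration()] event and was run with census recording (see
#'   [admixture_config()]).
#' @param census_generation the pulse time in generations. Defaults to the
#'   single pulse event in the configuration.
#' @return A tibble with columns `sample` and `fraction`, with the
#'   across-sample variance attached as attribute `"variance"` (also
#'   available via [ancestry_variance()]).
#' @export
ancestry_fractions <- function(sim, census_generation = NULL) {
  stopifnot(inherits(sim, "genealogy"))
  events <- sim$config$demography$events
  pulses <- Filter(function(e) e$kind == "pulse", events)
  if (is.null(census_generation)) {
    if (length(pulses) != 1) {
      stop("specify `census_generation`: the configuration does not have ",
           "exactly one pulse event", call. = FALSE)
    }
    census_generation <- pulses[[1]]$time
  }
  pulse <- Filter(function(e) e$time == census_generation, pulses)
  if (length(pulse) == 0) {
    stop("no pulse event at generation ", census_generation, call. = FALSE)
  }
  source_pop <- pulse[[1]]$source
  ct <- sim$nodes$time[sim$nodes$is_census]
  # DTWF census nodes sit at g - 0.5 (between child and parent integer
  # times); Hudson census nodes sit at g exactly
  cand <- unique(ct[abs(ct - census_generation) <= 0.5 + 1e-9])
  if (length(cand) == 0) {
    stop("no census nodes found at generation ", census_generation,
         "; re-run the simulation with pulse recording enabled ",
         "(record_tables = TRUE, keep_coalesced = TRUE, stop_time >= pulse time)",
         call. = FALSE)
  }
  census_time <- cand[which.min(abs(cand - census_generation))]
  frac <- cpp_census_fractions(
    sim$nodes$time, sim$nodes$population - 1L, sim$nodes$flags,
    sim$edges$left, sim$edges$right, sim$edges$parent, sim$edges$child,
    census_time, source_pop - 1L,
    sim$map$chrom_start, sim$map$chrom_end
  )
  out <- tibble::tibble(sample = sim$nodes$id[sim$nodes$is_sample],
                        fraction = frac)
  attr(out, "variance") <- stats::var(out$fraction)
  out
}

#' Across-sample variance of ancestry fractions
#'
#' @param fractions output of [ancestry_fractions()].
#' @return The sample variance of the per-sample migrant fractions.
#' @export
ancestry_variance <- function(fractions) {
  stats::var(fractions$fraction)
}

#' Configuration for a single-pulse admixture experiment
#'
#' Builds the two-population setup used throughout the admixture analyses:
#' samples are drawn from population 1, and a single pulse `g` generations
#' ago makes each lineage derive its parent from population 2 with
#' probability `f`. The run stops right after the pulse census (the
#' genealogy above the census does not affect ancestry fractions), and
#' fully-coalesced intervals are retained so that every genomic point can be
#' attributed to a census ancestor.
#'
#' @param model `"hudson"`, `"dtwf"` or `"hybrid"`.
#' @param samples haploid sample count (population 1).
#' @param N diploid size of both populations.
#' @param g pulse time, generations before sampling.
#' @param f admixture fraction in `[0, 1]`.
#' @param map a [genetic_map()].
#' @param seed RNG seed.
#' @param ... further arguments passed to [sim_config()].
#' @return A [sim_config()].
#' @examples
#' cfg <- admixture_config("dtwf", samples = 20, N = 20, g = 2, f = 0.3,
#'                         map = genetic_map(1), seed = 1)
#' v <- ancestry_variance(ancestry_fractions(simulate_genealogy(cfg)))
#' @export
admixture_config <- function(model, samples, N, g, f, map, seed, ...) {
  dem <- demographic_model(
    populations = list(population(N), population(N)),
    events = list(pulse_migration(time = g, dest = 1, source = 2,
                                  fraction = f))
  )
  sim_config(model, samples = c(samples, 0L), map = map, demography = dem,
             seed = seed, stop_time = g + 1, keep_coalesced = TRUE,
             record_lineage_counts = FALSE, ...)
}
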