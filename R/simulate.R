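#' Simulate a whole-genome genealogy
#'
#' Runs the configured engine backwards in time from the sampled haploid
#' genomes until every position of the genome has found its most recent
#' common ancestor (or until `stop_time`). Three models are available:
#'
#' * `hudson`: Hudson's coalescent with recombination. Waiting times are
#'   exponential; recombination occurs at a rate equal to the total map
#'   distance spanned by ancestral material (including trapped gaps), and
#'   each event splits a lineage into two independent lineages, so the
#'   number of lineages can greatly exceed the haploid population size.
#' * `dtwf`: a backwards discrete-time Wright-Fisher model. Generations are
#'   iterated one by one; every lineage chooses a single uniform diploid
#'   parent, a meiosis with Poisson(`span` in Morgans) crossovers and
#'   independent chromosome assortment splits its material between the
#'   parent's two haplotypes, and everything landing on the same parental
#'   haplotype coalesces. Lineage counts can therefore never exceed `2N(t)`.
#' * `hybrid`: DTWF for the first `switch_time` generations, Hudson after.
#'
#' @param config a [sim_config()].
#' @return A `genealogy` object: a list with tibbles `nodes` (id, time in
#'   generations, population, flags -- bit 1 marks samples, bit 2 census
#'   nodes), `edges` (left/right in Morgans on the map axis, parent, child),
#'   and `trace` (generation, surviving lineage count), plus the map and
#'   run metadata.
#' @examples
#' cfg <- sim_config("dtwf", samples = 4, map = genetic_map(0.1),
#'                   demography = demographic_model(population(50)), seed = 1)
#' g <- simulate_genealogy(cfg)
#' g$nodes
#' @export
simulate_genealogy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dem <- config$demography
  cfg <- list(
    chrom_start = config$map$chrom_start,
    chrom_end = config$map$chrom_end,
    N0 = vapply(dem$populations, `[[`, 0, "size"),
    alpha = vapply(dem$populations, `[[`, 0, "growth_rate"),
    migration = dem$migration,
    events = lapply(dem$events, function(e) {
      e <- unclass(e)
      # C++ population indices are 0-based
      for (f in c("population", "dest", "source")) {
        if (!is.null(e[[f]])) e[[f]] <- e[[f]] - 1L
      }
      e
    }),
    record_tables = isTRUE(config$record_tables),
    keep_coalesced = isTRUE(config$keep_coalesced),
    record_trace = isTRUE(config$record_lineage_counts),
    stop_time = config$stop_time,
    model = match(config$model, c("hudson", "dtwf", "hybrid")) - 1L,
    switch_time = as.numeric(config$switch_time),
    samples = config$samples
  )
  set.seed(config$seed)
  res <- cpp_simulate(cfg)
  new_genealogy(res, config)
}

new_genealogy <- function(res, config) {
  nodes <- tibble::tibble(
    id = seq_along(res$node_time) - 1L,
    time = res$node_time,
    population = res$node_population + 1L,
    flags = res$node_flags,
    is_sample = bitwAnd(res$node_flags, 1L) > 0,
    is_census = bitwAnd(res$node_flags, 2L) > 0
  )
  edges <- tibble::tibble(
    left = res$edge_left, right = res$edge_right,
    parent = res$edge_parent, child = res$edge_child
  )
  trace <- tibble::tibble(
    generation = res$trace_gen, lineages = res$trace_count
  )
  structure(
    list(nodes = nodes, edges = edges, trace = trace,
         map = config$map, config = config,
         fully_coalesced = res$fully_coalesced,
         end_time = res$end_time, n_extant = res$n_extant,
         event_counts = c(recomb = res$n_recomb_events %||% NA_real_,
                          ca = res$n_ca_events %||% NA_real_,
                          migration = res$n_migration_events %||% NA_real_)),
    class = "genealogy"
  )
}

#' Run a specific engine
#'
#' Thin wrappers over [simulate_genealogy()] that force the model choice of
#' an existing configuration.
#'
#' @param config a [sim_config()].
#' @param switch_time hybrid switch time in generations (see [sim_config()]).
#' @return A `genealogy`.
#' @export
run_hudson <- function(config) {
  config$model <- "hudson"
  simulate_genealogy(config)
}

#' @rdname run_hudson
#' @export
run_dtwf <- function(config) {
  config$model <- "dtwf"
  simulate_genealogy(config)
}

#' @rdname run_hudson
#' @export
run_hybrid <- function(config, switch_time = config$switch_time) {
  config$model <- "hybrid"
  config$switch_time <- switch_time
  simulate_genealogy(config)
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf(
    "<genealogy> %s model: %d samples, %d nodes, %d edges, %s at t = %g\n",
    x$config$model, sum(x$nodes$is_sample), nrow(x$nodes), nrow(x$edges),
    if (x$fully_coalesced) "fully coalesced" else
      sprintf("%g lineages left", x$n_extant),
    x$end_time
  ))
  invisible(x)
}

#' Node table of a genealogy, one row per node
#'
#' @param x a `genealogy`.
#' @param ... unused.
#' @return The node tibble (id, time, population, flags).
#' @method tidy genealogy
#' @export
tidy.genealogy <- function(x, ...) x$nodes

#' One-row summary of a simulated genealogy
#'
#' @param x a `genealogy`.
#' @param ... unused.
#' @return A one-row tibble: model, sample count, node/edge counts, whether
#'   the run fully coalesced, the final time and the peak lineage count.
#' @method glance genealogy
#' @export
glance.genealogy <- function(x, ...) {
  tibble::tibble(
    model = x$config$model,
    n_samples = sum(x$nodes$is_sample),
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    fully_coalesced = x$fully_coalesced,
    end_time = x$end_time,
    peak_lineages = if (nrow(x$trace)) max(x$trace$lineages) else NA_real_
  )
}

#' Surviving-lineage counts through time
#'
#' One row per integer generation, from generation 0 (the sample size) until
#' full coalescence or the recorded horizon. Under the DTWF model the count
#' may grow at first (a lineage's material can land on both of its parent's
#' haplotypes, at most doubling per generation) but can never exceed the
#' haploid population size `2N(t)`; under the Hudson model it typically
#' shoots far above `2N` for large samples of long genomes, because every
#' recombination event creates an independent new lineage.
#'
#' @param sim a `genealogy` simulated with `record_lineage_counts = TRUE`.
#' @return A tibble with columns `generation` and `lineages`.
#' @export
lineage_counts <- function(sim) {
  stopifnot(inherits(sim, "genealogy"))
  if (nrow(sim$trace) == 0) {
    stop("no lineage trace was recorded; set `record_lineage_counts = TRUE`",
         call. = FALSE)
  }
  sim$trace
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
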