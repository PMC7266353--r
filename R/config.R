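#' Simulation configuration
#'
#' Bundles everything a run needs: the model, per-population haploid sample
#' counts, the genetic map, the demographic model, and the RNG seed.
#' Identical configurations with identical seeds produce identical node and
#' edge tables.
#'
#' @param model one of `"hudson"`, `"dtwf"`, `"hybrid"`.
#' @param samples integer vector of haploid sample counts, one per population.
#' @param map a [genetic_map()].
#' @param demography a [demographic_model()].
#' @param seed integer RNG seed.
#' @param switch_time hybrid only: number of Wright-Fisher generations before
#'   switching to the coalescent (`T >= 0`; `Inf` degenerates to pure DTWF,
#'   `0` to pure Hudson).
#' @param mutation_rate optional mutation rate, per Morgan per generation,
#'   stored for [drop_mutations()].
#' @param stop_time optional time horizon (generations): the run stops once
#'   this time is reached even if lineages remain uncoalesced.
#' @param record_tables record node/edge tables (disable for lineage-count
#'   traces of very large runs, where the tables would dominate memory).
#' @param record_lineage_counts record the surviving-lineage trace at every
#'   integer generation.
#' @param keep_coalesced retain fully-coalesced intervals on their MRCA
#'   lineage instead of pruning them. Required (and enabled automatically)
#'   when a pulse census must attribute every genomic point; only meaningful
#'   together with a finite `stop_time`.
#' @return A `sim_config`.
#' @examples
#' cfg <- sim_config("dtwf", samples = 10, map = genetic_map(1),
#'                   demography = demographic_model(population(100)), seed = 1)
#' @export
sim_config <- function(model = c("hudson", "dtwf", "hybrid"),
                       samples, map, demography, seed,
                       switch_time = 0, mutation_rate = NULL,
                       stop_time = Inf, record_tables = TRUE,
                       record_lineage_counts = TRUE,
                       keep_coalesced = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(map, "genetic_map"),
            inherits(demography, "demographic_model"))
  np <- length(demography$populations)
  samples <- as.integer(samples)
  if (length(samples) == 1 && np > 1) samples <- c(samples, rep(0L, np - 1))
  if (length(samples) != np || any(samples < 0)) {
    stop("`samples` must give a non-negative count per population",
         call. = FALSE)
  }
  if (sum(samples) < 1) stop("at least one sample is required", call. = FALSE)
  if (sum(samples) == 1 && !is.finite(stop_time)) {
    stop("a single sample is trivially its own MRCA; set a finite ",
         "`stop_time` to step such a configuration", call. = FALSE)
  }
  if (model == "hybrid" && (!is.numeric(switch_time) || switch_time < 0)) {
    stop("`switch_time` must be >= 0 for the hybrid model", call. = FALSE)
  }
  if (keep_coalesced && !is.finite(stop_time)) {
    stop("`keep_coalesced = TRUE` requires a finite `stop_time`",
         call. = FALSE)
  }
  structure(
    list(model = model, samples = samples, map = map, demography = demography,
         seed = as.integer(seed), switch_time = switch_time,
         mutation_rate = mutation_rate, stop_time = stop_time,
         record_tables = record_tables,
         record_lineage_counts = record_lineage_counts,
         keep_coalesced = keep_coalesced),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> model = %s, n = %d haploid sample(s), seed = %d\n",
              x$model, sum(x$samples), x$seed))
  print(x$map)
  print(x$demography)
  invisible(x)
}

#' Write / read a simulation configuration
#'
#' A flat `key = value` text dialect with one `[chromosomes]` table listing
#' per-chromosome genetic lengths, one `[population.i]` block per population
#' and one `[event.i]` block per demographic event. Configurations round-trip
#' bit-exactly: values are printed with full double precision (`%.17g`).
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   [sim_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  num <- function(x) sprintf("%.17g", x)
  ln <- c(
    "# wfcoal config v1",
    paste0("model = ", config$model),
    paste0("seed = ", config$seed),
    paste0("samples = ", paste(config$samples, collapse = ",")),
    paste0("switch_time = ", num(config$switch_time)),
    paste0("stop_time = ", num(config$stop_time)),
    paste0("mutation_rate = ",
           if (is.null(config$mutation_rate)) "none" else num(config$mutation_rate)),
    paste0("record_tables = ", config$record_tables),
    paste0("record_lineage_counts = ", config$record_lineage_counts),
    paste0("keep_coalesced = ", config$keep_coalesced),
    paste0("spacer = ", num(config$map$spacer)),
    paste0("bp_per_morgan = ", num(config$map$bp_per_morgan)),
    "[chromosomes]",
    paste0("lengths = ", paste(num(config$map$lengths), collapse = ","))
  )
  for (i in seq_along(config$demography$populations)) {
    p <- config$demography$populations[[i]]
    ln <- c(ln, sprintf("[population.%d]", i),
            paste0("size = ", num(p$size)),
            paste0("growth_rate = ", num(p$growth_rate)))
  }
  mg <- config$demography$migration
  ln <- c(ln, "[migration]",
          paste0("matrix = ", paste(num(as.vector(mg)), collapse = ",")))
  for (i in seq_along(config$demography$events)) {
    e <- config$demography$events[[i]]
    ln <- c(ln, sprintf("[event.%d]", i),
            paste0("time = ", num(e$time)), paste0("kind = ", e$kind))
    if (e$kind == "pulse") {
      ln <- c(ln, paste0("dest = ", e$dest), paste0("source = ", e$source),
              paste0("fraction = ", num(e$fraction)))
    } else {
      ln <- c(ln, paste0("population = ", e$population),
              paste0("value = ", num(e$value)))
    }
  }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  section <- ""
  kv <- list()
  for (l in ln) {
    if (grepl("^\\[", l)) {
      section <- gsub("\\[|\\]", "", l)
      next
    }
    m <- regmatches(l, regexec("^\\s*([^=\\s]+)\\s*=\\s*(.*)$", l,
                               perl = TRUE))[[1]]
    if (length(m) != 3) stop("malformed config line: ", l, call. = FALSE)
    key <- if (section == "") m[2] else paste(section, m[2], sep = ".")
    kv[[key]] <- m[3]
  }
  nums <- function(x) as.numeric(strsplit(x, ",")[[1]])
  lengths <- nums(kv[["chromosomes.lengths"]])
  map <- genetic_map(lengths, spacer = as.numeric(kv[["spacer"]]),
                     bp_per_morgan = as.numeric(kv[["bp_per_morgan"]]))
  pops <- list()
  i <- 1
  while (!is.null(kv[[sprintf("population.%d.size", i)]])) {
    pops[[i]] <- population(as.numeric(kv[[sprintf("population.%d.size", i)]]),
                            as.numeric(kv[[sprintf("population.%d.growth_rate", i)]]))
    i <- i + 1
  }
  mg <- matrix(nums(kv[["migration.matrix"]]), length(pops), length(pops))
  events <- list()
  i <- 1
  while (!is.null(kv[[sprintf("event.%d.kind", i)]])) {
    pre <- function(f) kv[[sprintf("event.%d.%s", i, f)]]
    events[[i]] <- switch(pre("kind"),
      pulse = pulse_migration(as.numeric(pre("time")), as.integer(pre("dest")),
                              as.integer(pre("source")),
                              as.numeric(pre("fraction"))),
      size_change = size_change(as.numeric(pre("time")),
                                as.integer(pre("population")),
                                as.numeric(pre("value"))),
      growth_change = growth_change(as.numeric(pre("time")),
                                    as.integer(pre("population")),
                                    as.numeric(pre("value")))
    )
    i <- i + 1
  }
  mu <- kv[["mutation_rate"]]
  sim_config(
    model = kv[["model"]],
    samples = as.integer(nums(kv[["samples"]])),
    map = map,
    demography = demographic_model(pops, mg, events),
    seed = as.integer(kv[["seed"]]),
    switch_time = as.numeric(kv[["switch_time"]]),
    mutation_rate = if (identical(mu, "none")) NULL else as.numeric(mu),
    stop_time = as.numeric(kv[["stop_time"]]),
    record_tables = as.logical(kv[["record_tables"]]),
    record_lineage_counts = as.logical(kv[["record_lineage_counts"]]),
    keep_coalesced = as.logical(kv[["keep_coalesced"]])
  )
}
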