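# shared fixtures: tiny maps and configs built in code

tiny_map <- function(n = 1, l = 0.1, spacer = 0) genetic_map(rep(l, n), spacer)

point_map <- function() genetic_map(1e-9)

const_pop <- function(N) demographic_model(population(N))

quick_config <- function(model = "dtwf", n = 4, N = 50, map = tiny_map(),
                         seed = 1, ...) {
  sim_config(model, samples = n, map = map, demography = const_pop(N),
             seed = seed, ...)
}

# brute-force per-point count of extant-lineage coverage used to check the
# engines' conservation bookkeeping
coverage_at <- function(edges, nodes, x, max_time = Inf) {
  ed <- edges[edges$left <= x & x < edges$right, ]
  parent_of <- stats::setNames(ed$parent, ed$child)
  samples <- nodes$id[nodes$is_sample]
  vapply(samples, function(s) {
    cur <- s
    while (as.character(cur) %in% names(parent_of)) {
      cur <- parent_of[[as.character(cur)]]
    }
    cur
  }, 0L)
}
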