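# Hudson coalescent engine: waiting-time laws, growth, and the
# lineage-explosion pathology that motivates the DTWF model.

test_that("pairwise TMRCA at a point locus is exponential with mean 2N", {
  N <- 100
  tm <- vapply(1:600, function(i) {
    g <- simulate_genealogy(quick_config("hudson", n = 2, N = N,
                                         map = point_map(), seed = 1000 + i))
    max(g$nodes$time)
  }, 0)
  expect_equal(mean(tm), 2 * N, tolerance = 0.1)
  ks <- suppressWarnings(stats::ks.test(tm, stats::pexp, rate = 1 / (2 * N)))
  expect_gt(ks$p.value, 0.001)
})

test_that("coalescence times under growth follow the inverse-CDF transform", {
  # numeric oracle: with N(t) = N0 exp(-alpha t) the pair-coalescence CDF is
  # F(t) = 1 - exp(-(exp(alpha t) - 1) / (2 N0 alpha))
  N0 <- 1000
  alpha <- 0.001
  tm <- vapply(1:600, function(i) {
    cfg <- sim_config("hudson", samples = 2, map = point_map(),
                      demography = demographic_model(population(N0, alpha)),
                      seed = 5000 + i)
    max(simulate_genealogy(cfg)$nodes$time)
  }, 0)
  cdf <- function(t) 1 - exp(-(exp(alpha * t) - 1) / (2 * N0 * alpha))
  ks <- suppressWarnings(stats::ks.test(tm, cdf))
  expect_gt(ks$p.value, 0.001)
})

test_that("same seed gives identical tables; different seeds differ", {
  cfg <- quick_config("hudson", n = 5, N = 30, map = tiny_map(2, 0.3), seed = 9)
  g1 <- simulate_genealogy(cfg)
  g2 <- simulate_genealogy(cfg)
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges, g2$edges)
  cfg$seed <- 10L
  g3 <- simulate_genealogy(cfg)
  expect_false(identical(g3$edges, g1$edges))
})

test_that("lineage counts can exceed the haploid population size", {
  # small-scale version of the whole-genome pathology: many samples on a
  # multi-chromosome map push the count well beyond 2N
  cfg <- sim_config("hudson", samples = 60, map = genetic_map(rep(1, 4), 0.5),
                    demography = demographic_model(population(30)),
                    seed = 4, stop_time = 50)
  tr <- lineage_counts(simulate_genealogy(cfg))
  expect_gt(max(tr$lineages), 2 * 30)
})

test_that("migration moves lineages so split populations can coalesce", {
  dem <- demographic_model(list(population(50), population(50)),
                           migration = matrix(c(0, 0.05, 0.05, 0), 2,
                                              byrow = TRUE))
  cfg <- sim_config("hudson", samples = c(2, 2), map = point_map(),
                    demography = dem, seed = 11)
  g <- simulate_genealogy(cfg)
  expect_true(g$fully_coalesced)
  # without migration the two demes can never find a common ancestor and the
  # run stops at the horizon with one uncoalesced lineage per deme
  dem0 <- demographic_model(list(population(50), population(50)))
  g0 <- simulate_genealogy(sim_config("hudson", samples = c(2, 2),
                                      map = point_map(), demography = dem0,
                                      seed = 11, stop_time = 1e5,
                                      record_lineage_counts = FALSE))
  expect_false(g0$fully_coalesced)
  expect_equal(g0$n_extant, 2)
})

test_that("event counts in small-rho regimes match the naive R oracle", {
  # the compiled engine and a from-scratch R implementation built on the
  # exported lineage algebra must agree on the expected number of
  # recombination events for tiny instances (n <= 4, short maps)
  N <- 50
  map <- genetic_map(0.01)
  n_rep <- 200
  eng <- vapply(1:n_rep, function(i) {
    cfg <- quick_config("hudson", n = 4, N = N, map = map, seed = 30000 + i)
    simulate_genealogy(cfg)$event_counts[["recomb"]]
  }, 0)
  set.seed(77)
  ora <- vapply(1:n_rep, function(i) naive_hudson(4, map, N)$event_counts[["recomb"]],
                0)
  # Poisson-scale means: compare with a two-sample t test
  tt <- stats::t.test(eng, ora)
  expect_gt(tt$p.value, 0.001)
})
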