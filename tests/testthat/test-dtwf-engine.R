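# Backwards discrete-time Wright-Fisher engine: meiosis model, lineage cap,
# geometric coalescence, and the hybrid switch.

test_that("meiosis draws Poisson crossovers and a fair phase", {
  map <- genetic_map(2)
  set.seed(1)
  zero <- wfcoal:::cpp_draw_meiosis(map$chrom_start, map$chrom_end, 0.5, 0.5)
  expect_length(zero$breakpoints, 0)
  draws <- replicate(4000, {
    d <- wfcoal:::cpp_draw_meiosis(map$chrom_start, map$chrom_end, 0, 2)
    c(length(d$breakpoints), d$phase)
  })
  counts <- draws[1, ]
  expect_equal(mean(counts), 2, tolerance = 0.05)
  cs <- suppressWarnings(stats::chisq.test(
    table(factor(pmin(counts, 7), levels = 0:7)),
    p = c(stats::dpois(0:6, 2), 1 - stats::ppois(6, 2))
  ))
  expect_gt(cs$p.value, 0.001)
  # fair phase coin
  bt <- stats::binom.test(sum(draws[2, ]), ncol(draws))
  expect_gt(bt$p.value, 0.001)
  # breakpoint positions are uniform over the span
  set.seed(2)
  pos <- unlist(replicate(3000, wfcoal:::cpp_draw_meiosis(
    map$chrom_start, map$chrom_end, 0, 2)$breakpoints))
  ks <- suppressWarnings(stats::ks.test(pos, "punif", 0, 2))
  expect_gt(ks$p.value, 0.001)
})

test_that("meiosis splits alternate and assort chromosomes independently", {
  # single chromosome, no crossovers likely on a tiny map: all to one side
  m <- genetic_map(1e-6)
  set.seed(3)
  sp <- wfcoal:::cpp_split_meiosis(m$chrom_start, m$chrom_end, 0, 1e-6, 5L)
  expect_equal(nrow(sp$A) + nrow(sp$B), 1)
  # explicit breakpoint behaviour via repeated splitting of [0, 1):
  # alternation means A and B partition the input exactly
  m1 <- genetic_map(1)
  for (i in 1:20) {
    sp <- wfcoal:::cpp_split_meiosis(m1$chrom_start, m1$chrom_end, 0, 1, 9L)
    tot <- sum(sp$A$right - sp$A$left) + sum(sp$B$right - sp$B$left)
    expect_equal(tot, 1)
    if (nrow(sp$A) && nrow(sp$B)) {
      # no overlap between the two outputs
      ints <- rbind(cbind(sp$A$left, sp$A$right), cbind(sp$B$left, sp$B$right))
      o <- order(ints[, 1])
      expect_true(all(ints[o, 1][-1] >= ints[o, 2][-nrow(ints)]))
    }
  }
  # two tiny chromosomes, no crossovers: the four assortment outcomes are
  # equally likely
  m2 <- genetic_map(c(1e-6, 1e-6), spacer = 1)
  mid <- (m2$chrom_start + m2$chrom_end) / 2
  set.seed(4)
  outcomes <- replicate(4000, {
    sp <- wfcoal:::cpp_split_meiosis(m2$chrom_start, m2$chrom_end,
                                     m2$chrom_start, m2$chrom_end, c(1L, 1L))
    inA <- vapply(mid, function(x) any(sp$A$left <= x & x < sp$A$right), TRUE)
    paste(as.integer(inA), collapse = "")
  })
  cs <- suppressWarnings(stats::chisq.test(table(outcomes)))
  expect_gt(cs$p.value, 0.0005)
  expect_length(unique(outcomes), 4)
})

test_that("with N = 1 two lineages coalesce geometrically at rate 1/2", {
  tm <- vapply(1:800, function(i) {
    g <- simulate_genealogy(quick_config("dtwf", n = 2, N = 1,
                                         map = point_map(), seed = 100 + i))
    g$end_time
  }, 0)
  expect_equal(mean(tm), 2, tolerance = 0.1)
  expect_true(all(tm == round(tm)))
})

test_that("pairwise DTWF TMRCA is geometric with success probability 1/(2N)", {
  N <- 25
  tm <- vapply(1:800, function(i) {
    simulate_genealogy(quick_config("dtwf", n = 2, N = N, map = point_map(),
                                    seed = 9000 + i))$end_time
  }, 0)
  expect_true(all(tm == round(tm)))
  p <- 1 / (2 * N)
  brk <- unique(stats::qgeom(seq(0.125, 0.875, 0.125), prob = p))
  obs <- table(cut(tm - 1, breaks = c(-1, brk, Inf)))
  pr <- diff(c(0, stats::pgeom(brk, p), 1))
  cs <- suppressWarnings(stats::chisq.test(obs, p = pr))
  expect_gt(cs$p.value, 0.001)
})

test_that("DTWF and Hudson TMRCA distributions agree for small n, short L", {
  N <- 30
  tm_d <- vapply(1:400, function(i) {
    simulate_genealogy(quick_config("dtwf", n = 2, N = N,
                                    map = genetic_map(0.001),
                                    seed = 300 + i))$end_time
  }, 0)
  tm_h <- vapply(1:400, function(i) {
    simulate_genealogy(quick_config("hudson", n = 2, N = N,
                                    map = genetic_map(0.001),
                                    seed = 800000 + i))$end_time
  }, 0)
  ks <- suppressWarnings(stats::ks.test(tm_d + stats::runif(400), tm_h))
  expect_gt(ks$p.value, 0.001)
})

test_that("lineage counts never exceed 2N(t) under the DTWF model", {
  # the hard cap holds for any sample size; counts may initially grow (each
  # lineage can split onto its parent's two haplotypes, so at most doubling
  # per generation) but never beyond the haploid population size
  set.seed(5)
  for (rep in 1:6) {
    N <- sample(5:40, 1)
    n <- sample(2:(2 * N), 1)
    alpha <- sample(c(0, 0.01), 1)
    nchrom <- sample(1:3, 1)
    cfg <- sim_config("dtwf", samples = n,
                      map = genetic_map(runif(nchrom, 0.2, 2), spacer = 0.5),
                      demography = demographic_model(population(N, alpha)),
                      seed = 600 + rep, stop_time = 300)
    tr <- lineage_counts(simulate_genealogy(cfg))
    cap <- 2 * pmax(1, round(N * exp(-alpha * tr$generation)))
    expect_true(all(tr$lineages <= cap))
    expect_true(all(tr$lineages[-1] <= 2 * tr$lineages[-nrow(tr)]))
  }
})

test_that("a single lineage without recombination just steps through time", {
  cfg <- sim_config("dtwf", samples = 1, map = point_map(),
                    demography = const_pop(10), seed = 1, stop_time = 7)
  g <- simulate_genealogy(cfg)
  expect_equal(g$end_time, 7)
  expect_equal(g$n_extant, 1)
  expect_equal(nrow(g$nodes), 1)  # no coalescence nodes
  expect_equal(nrow(g$edges), 0)
})

test_that("DTWF node times are integers and runs are seed-reproducible", {
  cfg <- quick_config("dtwf", n = 10, N = 40, map = tiny_map(2, 0.5), seed = 21)
  g1 <- simulate_genealogy(cfg)
  g2 <- simulate_genealogy(cfg)
  expect_identical(g1$edges, g2$edges)
  expect_true(all(g1$nodes$time == round(g1$nodes$time)))
})

test_that("DTWF statistics are invariant to the Hudson spacer", {
  # same seeds, two spacer values: identical genealogies up to coordinates
  t_a <- vapply(1:60, function(i) {
    simulate_genealogy(quick_config("dtwf", n = 4, N = 20,
                                    map = genetic_map(c(0.5, 0.5), 0),
                                    seed = 40 + i))$end_time
  }, 0)
  t_b <- vapply(1:60, function(i) {
    simulate_genealogy(quick_config("dtwf", n = 4, N = 20,
                                    map = genetic_map(c(0.5, 0.5), 3),
                                    seed = 40 + i))$end_time
  }, 0)
  expect_identical(t_a, t_b)
})

test_that("hybrid runs switch seamlessly between the engines", {
  # T = 0 degenerates to pure Hudson (real-valued times from the start)
  cfg <- quick_config("hybrid", n = 4, N = 20, map = tiny_map(), seed = 31,
                      switch_time = 0)
  g0 <- run_hybrid(cfg, switch_time = 0)
  expect_false(all(g0$nodes$time == round(g0$nodes$time)))
  # T = Inf is pure DTWF (integer times throughout)
  ginf <- run_hybrid(cfg, switch_time = Inf)
  expect_true(all(ginf$nodes$time == round(ginf$nodes$time)))
  # intermediate T: child edges below T integer-timed, above T real-timed
  cfg2 <- quick_config("hybrid", n = 8, N = 15, map = tiny_map(1, 0.5),
                       seed = 32, switch_time = 3)
  g <- simulate_genealogy(cfg2)
  internal <- g$nodes$time[!g$nodes$is_sample]
  below <- internal[internal <= 3]
  above <- internal[internal > 3]
  expect_true(all(below == round(below)))
  expect_gt(length(above), 0)
  expect_true(g$fully_coalesced)
})

test_that("hybrid recent-past TMRCAs match pure DTWF (two-sample KS)", {
  N <- 15
  recent <- function(model, T, seedbase) {
    vapply(1:250, function(i) {
      cfg <- quick_config(model, n = 10, N = N, map = point_map(),
                         seed = seedbase + i, switch_time = T)
      g <- simulate_genealogy(cfg)
      # first coalescence time (the most recent event)
      min(g$nodes$time[!g$nodes$is_sample])
    }, 0)
  }
  hy <- recent("hybrid", T = 20, seedbase = 70000)
  dt <- recent("dtwf", T = 0, seedbase = 90000)
  # compare the distributions truncated to the Wright-Fisher window
  ks <- suppressWarnings(stats::ks.test(hy[hy <= 20], dt[dt <= 20]))
  expect_gt(ks$p.value, 0.001)
})
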